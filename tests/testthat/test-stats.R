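test_that("Mann-Whitney U matches small-sample enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  # all 6 orderings of ranks: the two-sided p of the extreme table is 2/6
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)
  # identical samples: null exactly true
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  # U via midranks agrees with a direct midrank computation under ties
  a <- c(1, 2, 2, 5); b <- c(2, 3, 3)
  rr <- rank(c(a, b))
  expect_equal(mann_whitney_u(a, b)$statistic,
               sum(rr[1:4]) - 4 * 5 / 2)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Kendall tau matches the brute-force pair-count oracle", {
  x <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  expect_equal(kendall_tau(x, x)$statistic, 1)
  expect_equal(kendall_tau(x, -x)$statistic, -1)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
  # tau-b on the published property table: count all 190 pairs by hand
  p <- load_property_table()
  hx <- p$hydrophobicity; hy <- p$molecular_mass
  conc <- disc <- tx <- ty <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    sx <- sign(hx[i] - hx[j]); sy <- sign(hy[i] - hy[j])
    if (sx == 0 && sy == 0) next
    if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- choose(20, 2)
  tau_b <- (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  expect_equal(kendall_tau(hx, hy)$statistic, tau_b, tolerance = 1e-12)
})

test_that("null rejection rates sit at the nominal level (quick check)", {
  withr::with_seed(1, {
    mw <- mean(replicate(800, mann_whitney_u(rnorm(40),
                                             rnorm(40))$p_value < 0.05))
    kt <- mean(replicate(800, kendall_tau(rnorm(20),
                                          rnorm(20))$p_value < 0.05))
  })
  expect_gt(mw, 0.03); expect_lt(mw, 0.07)
  expect_gt(kt, 0.03); expect_lt(kt, 0.07)
})

test_that("residue scores are row/column means under the chosen transform", {
  I4 <- diag(4)
  sc <- residue_scores(I4)
  expect_equal(sc$target_score, rep(0.25, 4))
  expect_equal(sc$source_score, rep(0.25, 4))
  Xc <- matrix(2.5, 3, 3)
  scc <- residue_scores(Xc)
  expect_equal(scc$target_score, rep(2.5, 3))
  X <- withr::with_seed(2, matrix(rnorm(25), 5, 5))
  sc2 <- residue_scores(X, "absolute")
  for (i in 1:5) {
    expect_identical(sc2$target_score[i], mean(abs(X[i, ])))
    expect_identical(sc2$source_score[i], mean(abs(X[, i])))
  }
})

test_that("per-amino-acid mean scores pool correctly across proteins", {
  scores <- tibble::tibble(
    letter = c("A", "A", "C", "A", "D"),
    target_score = c(1, 1, 0, 1, 0),
    source_score = c(2, 4, 0, 6, 0)
  )
  v <- amino_acid_mean_scores(scores, "target")
  expect_equal(nrow(v), 20)
  expect_equal(v$mean_score[v$letter == "A"], 1)
  expect_equal(v$mean_score[v$letter == "C"], 0)
  expect_true(is.na(v$mean_score[v$letter == "W"]))
  # pooled mean oracle over two "proteins" worth of rows
  v2 <- amino_acid_mean_scores(scores, "source")
  expect_equal(v2$mean_score[v2$letter == "A"], mean(c(2, 4, 6)))
  expect_error(amino_acid_mean_scores(scores[0, ], "target"), "empty")
})

test_that("property tests split categories as defined", {
  # craft one protein whose matrix gives residue i source score i
  lets <- c("D", "E", "H", "K", "R", "F", "W", "A", "G", "Y")
  n <- length(lets)
  X <- matrix(0, n, n)
  for (j in 1:n) X[, j] <- j
  grid <- tibble::tibble(model = "m", method = "saliency",
                         mode = "embedding", protein_id = "p",
                         X = list(X), sequence = paste(lets, collapse = ""),
                         labels = list(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)))
  res <- run_property_tests(grid)
  expect_equal(nrow(res), 14)
  # acidic-vs-basic uses only D,E vs H,K,R source scores
  ab <- res[res$property == "acid_base" & res$role == "source", ]
  oracle <- mann_whitney_u(c(1, 2), c(3, 4, 5))
  expect_equal(ab$statistic, oracle$statistic)
  expect_equal(ab$p_value, oracle$p_value)
  # aromatic group is F, W, Y
  ar <- res[res$property == "aromaticity" & res$role == "source", ]
  oracle2 <- mann_whitney_u(c(6, 7, 10), c(1:5, 8, 9))
  expect_equal(ar$statistic, oracle2$statistic)
  # interactivity uses the labels
  it <- res[res$property == "interactivity" & res$role == "source", ]
  oracle3 <- mann_whitney_u(c(1, 2, 3, 10), c(4:9))
  expect_equal(it$statistic, oracle3$statistic)
  # passed flags are a pure function of p-value and alpha
  expect_identical(res$passed, ifelse(is.na(res$p_value), NA,
                                      res$p_value < 0.05))
})

test_that("missing labels mark interactivity as not evaluable", {
  X <- withr::with_seed(3, matrix(rnorm(36), 6, 6))
  grid <- tibble::tibble(model = "m", method = "saliency",
                         mode = "embedding", protein_id = "p",
                         X = list(X),
                         sequence = paste(random_letters(6, 4),
                                          collapse = ""))
  res <- run_property_tests(grid)
  inter <- res[res$property == "interactivity", ]
  expect_true(all(is.na(inter$p_value)))
  expect_true(all(is.na(inter$passed)))
  expect_false(any(inter$passed %in% TRUE))
})

test_that("distance profiles summarize separation classes", {
  D <- diag(3)
  dp <- distance_profile(D, max_distance = 4)
  expect_equal(dp$mean_impact[1], 1)
  expect_equal(dp$mean_impact[2], 0)
  expect_true(all(is.na(dp$mean_impact[dp$distance >= 3])))
  expect_equal(dp$n_pairs[dp$distance >= 3], c(0L, 0L))
  Xc <- matrix(4, 5, 5)
  dpc <- distance_profile(Xc, max_distance = 4)
  expect_true(all(dpc$mean_impact == 4))
  # pooled two-matrix oracle at distance 1
  A <- matrix(1:9, 3, 3); B <- matrix(2, 4, 4)
  dp2 <- distance_profile(list(A, B), max_distance = 2)
  vals <- c(abs(A[abs(outer(1:3, 1:3, "-")) == 1]),
            abs(B[abs(outer(1:4, 1:4, "-")) == 1]))
  expect_equal(dp2$mean_impact[2], mean(vals))
})

test_that("locality in the model yields a decreasing distance profile", {
  emb <- build_toy_embedder(e = 8, lambda = 1, seed = 41)
  prots <- generate_synthetic_proteins(6, c(30, 40), 0.3, seed = 42)
  grid <- toy_grid(emb, proteins = prots)
  dp <- distance_profile(grid$X, max_distance = 20)
  expect_true(all(diff(dp$mean_impact[1:11]) < 0))
})
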