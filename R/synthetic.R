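#' Generate synthetic labelled protein records
#'
#' Emulates the kind of corpus the published analysis ran on: short protein
#' chains (the real set spans 30-44 residues) with per-residue binary
#' interaction-site labels. Residues are drawn uniformly over the 20
#' canonical letters unless a composition bias is supplied; labels are
#' i.i.d. Bernoulli draws at `interaction_rate`, roughly the site density of
#' curated interaction-site datasets.
#'
#' @param count Number of records to generate.
#' @param length_range Integer vector of length 2, inclusive bounds on the
#'   sequence length. Must lie within `[5, 44]`.
#' @param interaction_rate Probability that a residue is an interaction site.
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @param composition Optional named numeric vector of residue sampling
#'   weights (names must be amino-acid letters); defaults to uniform.
#' @return A tibble with columns `protein_id`, `chain_id`, `sequence`,
#'   `length`, and `labels` (list-column of integer 0/1 vectors).
#' @examples
#' prots <- generate_synthetic_proteins(3, c(30, 44), 0.3, seed = 1)
#' prots$length
#' @export
generate_synthetic_proteins <- function(count,
                                        length_range = c(30, 44),
                                        interaction_rate = 0.3,
                                        seed = 1,
                                        composition = NULL) {
  stopifnot(length(count) == 1, count >= 1)
  if (length(length_range) != 2 || length_range[1] > length_range[2]) {
    abort("`length_range` must be a non-empty integer interval")
  }
  if (length_range[1] < 5 || length_range[2] > 44) {
    abort("`length_range` must lie within [5, 44]")
  }
  if (interaction_rate <= 0 || interaction_rate >= 1) {
    abort("`interaction_rate` must be in (0, 1)")
  }
  prob <- rep(1 / 20, 20)
  if (!is.null(composition)) {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% AA_ALPHABET)) {
      abort("`composition` must be named with amino-acid letters")
    }
    prob <- rep(0, 20)
    names(prob) <- AA_ALPHABET
    prob[names(composition)] <- composition
    if (sum(prob) <= 0) abort("`composition` weights must sum to > 0")
    prob <- prob / sum(prob)
  }
  withr::with_seed(as.integer(seed), {
    lens <- sample(seq(length_range[1], length_range[2]), count,
                   replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(AA_ALPHABET, n, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    labels <- lapply(lens, function(n) {
      as.integer(rbinom(n, 1, interaction_rate))
    })
    tibble(
      protein_id = sprintf("SYN%04d", seq_len(count)),
      chain_id = "A",
      sequence = seqs,
      length = as.integer(lens),
      labels = labels
    )
  })
}

#' Generate a seeded Gaussian random matrix
#'
#' I.i.d. Gaussian entries; used as the "random matrix" null class in the
#' real-versus-random separability check.
#'
#' @param n_rows,n_cols Positive dimensions.
#' @param mean,std Entry mean and standard deviation (`std > 0`).
#' @param seed Integer seed.
#' @return An `n_rows x n_cols` numeric matrix.
#' @export
generate_random_matrix <- function(n_rows, n_cols, mean = 0, std = 1,
                                   seed = 1) {
  if (n_rows < 1 || n_cols < 1) abort("matrix dimensions must be positive")
  if (std <= 0) abort("`std` must be > 0")
  withr::with_seed(as.integer(seed), {
    matrix(rnorm(n_rows * n_cols, mean, std), n_rows, n_cols)
  })
}

#' Write protein records as FASTA plus a companion label file
#'
#' The label file convention mirrors the FASTA layout: for each record a
#' header line `>id_chain` followed by a same-length string of 0/1
#' characters marking interaction sites.
#'
#' @param proteins Tibble as produced by [generate_synthetic_proteins()].
#' @param fasta_path Output FASTA path.
#' @param labels_path Optional output path for the 0/1 label file.
#' @return `fasta_path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, fasta_path, labels_path = NULL) {
  stopifnot(is.data.frame(proteins))
  ids <- paste0(proteins$protein_id, "_", proteins$chain_id)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::AAStringSet(proteins$sequence)
    names(aa) <- ids
    Biostrings::writeXStringSet(aa, fasta_path)
  } else {
    writeLines(as.vector(rbind(paste0(">", ids), proteins$sequence)),
               fasta_path)
  }
  if (!is.null(labels_path)) {
    if (!"labels" %in% names(proteins) || any(vapply(proteins$labels, is.null,
                                                    logical(1)))) {
      abort("`proteins` must carry labels to write a label file")
    }
    lab <- vapply(proteins$labels, function(l) paste(l, collapse = ""),
                  character(1))
    writeLines(as.vector(rbind(paste0(">", ids), lab)), labels_path)
  }
  invisible(fasta_path)
}

#' Read protein records from FASTA plus optional label file
#'
#' @param fasta_path FASTA input path; headers must be `id_chain`.
#' @param labels_path Optional label file (see [write_protein_fasta()]).
#' @return A tibble in the layout of [generate_synthetic_proteins()]; the
#'   `labels` column holds `NULL` entries when no label file is given.
#' @export
read_protein_fasta <- function(fasta_path, labels_path = NULL) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(fasta_path)
    headers <- names(aa)
    seqs <- as.character(aa)
  } else {
    lines <- readLines(fasta_path)
    hidx <- grep("^>", lines)
    headers <- sub("^>", "", lines[hidx])
    ends <- c(hidx[-1] - 1, length(lines))
    seqs <- vapply(seq_along(hidx), function(i) {
      paste(lines[(hidx[i] + 1):ends[i]], collapse = "")
    }, character(1))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(bad)) {
    abort(sprintf("non-canonical residue letters in record '%s'",
                  headers[which(bad)[1]]))
  }
  parts <- strsplit(headers, "_")
  labels <- vector("list", length(seqs))
  if (!is.null(labels_path)) {
    lab_lines <- readLines(labels_path)
    lidx <- grep("^>", lab_lines)
    lab_ids <- sub("^>", "", lab_lines[lidx])
    lab_str <- lab_lines[lidx + 1]
    m <- match(headers, lab_ids)
    if (anyNA(m)) abort("label file is missing records present in the FASTA")
    labels <- lapply(seq_along(seqs), function(i) {
      l <- as.integer(strsplit(lab_str[m[i]], "")[[1]])
      if (length(l) != nchar(seqs[i]) || any(!l %in% c(0L, 1L))) {
        abort(sprintf("label string for '%s' malformed", headers[i]))
      }
      l
    })
  }
  tibble(
    protein_id = vapply(parts, `[`, character(1), 1),
    chain_id = vapply(parts, function(p) if (length(p) > 1) p[2] else "A",
                      character(1)),
    sequence = unname(seqs),
    length = nchar(seqs),
    labels = labels
  )
}

# split a sequence string into a letter vector, validating the alphabet
seq_letters <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  if (!all(letters %in% AA_ALPHABET)) {
    abort("sequence contains non-canonical residue letters")
  }
  letters
}
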