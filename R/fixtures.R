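#' Load the packaged test-protein manifest
#'
#' Returns the manifest of the 34 short protein chains (30 to 44 residues) on
#' which the published residue-level explainability analysis was run. The
#' manifest carries identifiers and declared lengths only: the sequences and
#' per-residue interaction labels of these chains come from an external
#' interaction-site dataset and are deliberately not redistributed here.
#' Synthetic corpora with labels are produced by
#' [generate_synthetic_proteins()].
#'
#' @param path Path to a manifest TSV. Defaults to the packaged fixture.
#' @return A tibble with columns `protein_id`, `chain_id`, `length`.
#' @examples
#' manifest <- load_protein_manifest()
#' nrow(manifest) # 34
#' @export
load_protein_manifest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "protein_manifest.tsv",
                                package = "protexplain", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("protein_id", "chain_id", "length")
  if (!all(required %in% names(df))) {
    abort(paste0("manifest fixture must have columns ",
                 paste(required, collapse = ", ")))
  }
  len <- suppressWarnings(as.integer(df$length))
  bad <- which(is.na(len) | len <= 0 | is.na(df$protein_id) |
                 nchar(df$chain_id) != 1)
  if (length(bad) > 0) {
    abort(sprintf("malformed manifest row at line %d (after header)", bad[1]))
  }
  tibble(protein_id = df$protein_id, chain_id = df$chain_id, length = len)
}

#' Load the amino-acid property table
#'
#' Twenty rows (one per canonical amino acid, alphabetical order) with four
#' numerical physicochemical properties -- hydrophobicity (Kyte-Doolittle
#' style, dimensionless), molecular mass (Da), van der Waals volume
#' (cubic Angstrom), dipole moment (dimensionless, as tabulated) -- and two
#' categorical ones: aromaticity (F, Y, W) and acid/base character
#' (acidic: D, E; basic: H, K, R; neither otherwise).
#'
#' @param path Path to a property TSV. Defaults to the packaged fixture.
#' @return A tibble with columns `letter`, `hydrophobicity`, `molecular_mass`,
#'   `vdw_volume`, `dipole_moment`, `aromatic` (logical), `acid_base`
#'   (one of `"acidic"`, `"basic"`, `"neither"`).
#' @examples
#' props <- load_property_table()
#' props[props$letter == "W", ]
#' @export
load_property_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "amino_acid_properties.tsv",
                                package = "protexplain", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("letter", "hydrophobicity", "molecular_mass", "vdw_volume",
                "dipole_moment", "aromatic", "acid_base")
  if (!all(required %in% names(df))) {
    abort("property fixture is missing required columns")
  }
  if (!setequal(df$letter, AA_ALPHABET)) {
    missing <- setdiff(AA_ALPHABET, df$letter)
    abort(paste0("property table must cover the 20 canonical amino acids; ",
                 "missing: ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(df) %>%
    mutate(aromatic = as.logical(.data$aromatic)) %>%
    arrange(.data$letter)
  stopifnot(
    identical(out$letter[out$aromatic], c("F", "W", "Y")),
    identical(out$letter[out$acid_base == "acidic"], c("D", "E")),
    identical(out$letter[out$acid_base == "basic"], c("H", "K", "R"))
  )
  out
}

#' Numerical property names
#'
#' @return Character vector of the four numerical property column names in
#'   the table returned by [load_property_table()].
#' @export
numerical_properties <- function() {
  c("hydrophobicity", "molecular_mass", "vdw_volume", "dipole_moment")
}

#' Categorical property names
#'
#' @return Character vector of the three categorical property identifiers:
#'   interactivity (dataset-dependent per-residue interaction labels),
#'   aromaticity, and acid/base character.
#' @export
categorical_properties <- function() {
  c("interactivity", "aromaticity", "acid_base")
}

#' Load the transcribed published p-value grid
#'
#' The published evaluation reported one statistical test per combination of
#' embedding model (ProtBERT, ProtT5, Ankh), attribution method (nine), mode
#' (embedding vs prediction), role (target vs source) and amino-acid property
#' (three categorical, four numerical): 324 Mann-Whitney and 432 Kendall
#' results, 756 rows total. This loads the packaged verbatim transcription.
#' P-values are stored both as printed text (`p_text`, so values like
#' `"0.00 x 10^0"` threshold unambiguously) and as parsed doubles
#' (`p_value`); numerical rows also carry the signed Kendall correlation
#' (`tau`).
#'
#' @param path_categorical,path_numerical Optional paths overriding the
#'   packaged fixtures.
#' @return A tibble with columns `model`, `method`, `mode`, `role`,
#'   `property`, `test_type` (`"categorical"` or `"numerical"`), `tau`
#'   (NA for categorical rows), `p_text`, `p_value`.
#' @examples
#' pv <- load_reported_pvalues()
#' nrow(pv) # 756
#' @export
load_reported_pvalues <- function(path_categorical = NULL,
                                  path_numerical = NULL) {
  path_categorical <- path_categorical %||%
    system.file("extdata", "reported_pvalues_categorical.tsv",
                package = "protexplain", mustWork = TRUE)
  path_numerical <- path_numerical %||%
    system.file("extdata", "reported_pvalues_numerical.tsv",
                package = "protexplain", mustWork = TRUE)
  cat_df <- as_tibble(read.delim(path_categorical, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 colClasses = c(p_text = "character")))
  num_df <- as_tibble(read.delim(path_numerical, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 colClasses = c(p_text = "character")))
  if (nrow(cat_df) != 324) {
    abort(sprintf("expected 324 categorical rows, found %d", nrow(cat_df)))
  }
  if (nrow(num_df) != 432) {
    abort(sprintf("expected 432 numerical rows, found %d", nrow(num_df)))
  }
  out <- bind_rows(
    cat_df %>% mutate(test_type = "categorical", tau = NA_real_),
    num_df %>% mutate(test_type = "numerical")
  ) %>%
    select(all_of(c("model", "method", "mode", "role", "property",
                    "test_type", "tau", "p_text", "p_value")))
  if (any(out$p_value < 0 | out$p_value > 1)) {
    abort("transcribed p-values must lie in [0, 1]")
  }
  dup <- out %>%
    count(.data$model, .data$method, .data$mode, .data$role, .data$property) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) abort("duplicate keys in transcribed p-value table")
  out
}
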