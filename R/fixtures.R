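## Bundled fixtures: the published consensus ("Kern") gene table and the
## tissue-expression examples table, transcribed verbatim from print.
## They exercise validation and reporting without requiring the deposited
## array series.

#' Path to a bundled fixture
#'
#' @param name `"table1_kern"` or `"table2_tissue"`.
#' @return File path inside the installed package.
#' @export
fixture_path <- function(name = c("table1_kern", "table2_tissue")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".tsv"), package = "symbiokern",
              mustWork = TRUE)
}

#' Load the consensus gene-set fixture
#' @return data.frame with `kern_id`, `av_cluster`, `protein_name`, `role`,
#'   `array_fold`, `qpcr_fold` (NA where the table prints none).
#' @export
load_kern_fixture <- function() {
  d <- read_tsv(fixture_path("table1_kern"))
  d$qpcr_fold <- suppressWarnings(as.numeric(d$qpcr_fold))
  d
}

#' Load the tissue-expression examples fixture
#' @return data.frame; `dual_deg` is `"#"` for genes differentially
#'   expressed both between states and between tissues.
#' @export
load_tissue_fixture <- function() {
  d <- read_tsv(fixture_path("table2_tissue"))
  for (col in c("qpcr_fold", "kern_id"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  d
}

#' Validate the consensus gene-set fixture
#'
#' Checks the published set composition: 39 genes partitioned 19 symbiotic
#' (positive array fold) / 20 aposymbiotic (negative), a known role
#' vocabulary, 8 cell-adhesion genes and 7 metabolism genes (4 symbiotic
#' fatty-acid metabolism + 3 aposymbiotic), and the printed qPCR folds.
#'
#' @param path fixture TSV path; defaults to the bundled table.
#' @return list of class `fixture_validation`: `ok`, `n_genes`, `n_sy`,
#'   `n_apo`, `role_tallies` (named list), `problems` (character).
#' @export
validate_fixture <- function(path = fixture_path("table1_kern")) {
  problems <- character()
  d <- read_tsv(path)
  need <- c("kern_id", "av_cluster", "protein_name", "role", "array_fold")
  if (!all(need %in% names(d)))
    return(structure(list(ok = FALSE, n_genes = nrow(d), n_sy = NA,
                          n_apo = NA, role_tallies = list(),
                          problems = paste("missing columns:",
                                           paste(setdiff(need, names(d)),
                                                 collapse = ", "))),
                     class = "fixture_validation"))
  n <- nrow(d)
  if (n != 39) problems <- c(problems, sprintf("expected 39 rows, found %d", n))
  if (anyNA(d$array_fold) || any(d$array_fold == 0))
    problems <- c(problems, "array_fold must be nonzero for every row")
  n_sy <- sum(d$array_fold > 0)
  n_apo <- sum(d$array_fold < 0)
  if (n_sy != 19) problems <- c(problems,
                                sprintf("expected 19 SY rows, found %d", n_sy))
  if (n_apo != 20) problems <- c(problems,
                                 sprintf("expected 20 APO rows, found %d",
                                         n_apo))
  known_roles <- c(role_vocabulary(), "Collagen processing", "ion chanel",
                   "transposon")
  bad <- setdiff(unique(d$role), known_roles)
  if (length(bad) > 0)
    problems <- c(problems, paste("unknown roles:", paste(bad, collapse = ", ")))
  is_metab <- startsWith(d$role, "metabolism")
  tallies <- list(cell_adhesion = sum(d$role == "cell adhesion"),
                  metabolism = sum(is_metab),
                  metabolism_sy = sum(is_metab & d$array_fold > 0),
                  metabolism_apo = sum(is_metab & d$array_fold < 0))
  if (anyDuplicated(d$av_cluster))
    problems <- c(problems, "duplicated cluster ids")
  structure(list(ok = length(problems) == 0, n_genes = n, n_sy = n_sy,
                 n_apo = n_apo, role_tallies = tallies, problems = problems),
            class = "fixture_validation")
}

#' @export
print.fixture_validation <- function(x, ...) {
  cat("fixture validation:", if (x$ok) "OK" else "FAILED", "\n")
  cat(sprintf("  %d genes: %d SY / %d APO\n", x$n_genes, x$n_sy, x$n_apo))
  if (length(x$role_tallies) > 0)
    cat(sprintf("  roles: %d cell adhesion, %d metabolism (%d SY + %d APO)\n",
                x$role_tallies$cell_adhesion, x$role_tallies$metabolism,
                x$role_tallies$metabolism_sy, x$role_tallies$metabolism_apo))
  for (p in x$problems) cat("  problem:", p, "\n")
  invisible(x)
}
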