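## GO-term enrichment of the symbiotic gene set against the aposymbiotic
## set by Fisher's exact test, Gossip-style: terms are used flat, exactly as
## annotated (no ancestor propagation), and the two-sided p is the sum of
## the probabilities of all 2x2 tables with the observed margins that are no
## more probable than the observed table.

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Hypergeometric point-probability summation over the table's support.
#'
#' @param a,b test-set genes with / without the term.
#' @param c_,d reference-set genes with / without the term.
#' @return Two-sided p value.
#' @export
fisher_exact_p <- function(a, b, c_, d) {
  if (min(a, b, c_, d) < 0) stop_arg("counts must be non-negative")
  m <- a + c_          # genes with the term
  n <- b + d           # genes without
  k <- a + b           # test-set size
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' GO-term enrichment between two gene sets
#'
#' For every term annotated to either set, builds the 2x2 table (test
#' with/without, reference with/without), computes the two-sided Fisher
#' exact p, the odds ratio (Haldane 0.5 correction when a cell is zero),
#' and BH-adjusted p values.
#'
#' @param test_genes,reference_genes disjoint probe-id vectors.
#' @param annotation annotation data.frame with `probe_id` and `go_terms`
#'   (semicolon-separated), or a long data.frame with `probe_id` and `term`.
#' @return data.frame of class `enrichment_result`, one row per term:
#'   `term`, `test_with`, `test_without`, `ref_with`, `ref_without`,
#'   `odds_ratio`, `p`, `p_adj`, ordered by p.
#' @export
fisher_term_enrichment <- function(test_genes, reference_genes, annotation) {
  if (length(test_genes) == 0 || length(reference_genes) == 0)
    stop_arg("test and reference sets must be non-empty")
  if (length(intersect(test_genes, reference_genes)) > 0)
    stop_arg("test and reference sets must be disjoint")
  long <- if ("term" %in% names(annotation)) annotation
          else annotation_go_long(annotation)
  n_test <- length(test_genes); n_ref <- length(reference_genes)
  long <- long[long$probe_id %in% c(test_genes, reference_genes), ,
               drop = FALSE]
  terms <- unique(long$term)
  if (length(terms) == 0)
    return(structure(data.frame(term = character(), test_with = integer(),
                                test_without = integer(),
                                ref_with = integer(),
                                ref_without = integer(),
                                odds_ratio = numeric(), p = numeric(),
                                p_adj = numeric()),
                     class = c("enrichment_result", "data.frame")))
  rows <- lapply(terms, function(tm) {
    with_term <- long$probe_id[long$term == tm]
    a <- sum(test_genes %in% with_term)
    c_ <- sum(reference_genes %in% with_term)
    b <- n_test - a; d <- n_ref - c_
    cells <- c(a, b, c_, d)
    or <- if (any(cells == 0)) ((a + 0.5) * (d + 0.5)) /
      ((b + 0.5) * (c_ + 0.5)) else (a * d) / (b * c_)
    data.frame(term = tm, test_with = a, test_without = b, ref_with = c_,
               ref_without = d, odds_ratio = or,
               p = fisher_exact_p(a, b, c_, d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, "benjamini_hochberg")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_test = n_test, n_ref = n_ref,
            class = c("enrichment_result", "data.frame"))
}

#' Multiple-testing adjustment
#'
#' `benjamini_hochberg` applies the BH step-up procedure; `none` returns the
#' input.
#'
#' @param p p values in `[0, 1]`.
#' @param method `"none"` or `"benjamini_hochberg"`.
#' @return Adjusted p values in input order.
#' @export
adjust_pvalues <- function(p, method = c("none", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_arg("p values must be in [0, 1]")
  if (method == "none" || length(p) == 0) return(p)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
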