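## Epidermis/gastroderm tissue-specificity from the dual experimental
## design: a direct gastroderm-vs-epidermis hybridization, and the same
## contrast obtained by transitivity through the common reference. A gene is
## assigned to a tissue only when both experiments agree beyond the fold
## threshold.

#' Direct gastroderm-vs-epidermis contrast
#'
#' Uses the arrays that hybridize a specimen's two tissues against each
#' other. M is oriented gastroderm-minus-epidermis.
#'
#' @param ma an `ma_set`.
#' @param tissue_samples data.frame with `sample`, `specimen`, `tissue`
#'   (`"G"`/`"E"`).
#' @return list with `per_specimen` (matrix probes x specimens) and
#'   `m_direct` (cross-specimen mean).
#' @export
direct_tissue_contrast <- function(ma, tissue_samples) {
  des <- ma$design
  g_of <- setNames(tissue_samples$tissue, tissue_samples$sample)
  sp_of <- setNames(tissue_samples$specimen, tissue_samples$sample)
  direct <- !is.na(g_of[des$cy5_sample]) & !is.na(g_of[des$cy3_sample]) &
    sp_of[des$cy5_sample] == sp_of[des$cy3_sample]
  if (!any(direct)) stop_arg("no direct tissue-vs-tissue arrays in design")
  sub <- des[direct, , drop = FALSE]
  samples <- array_samples(sub)      # orientation sample after swap negation
  specs <- unique(sp_of[samples])
  P <- matrix(NA_real_, nrow(ma$M), length(specs),
              dimnames = list(rownames(ma$M), specs))
  for (sp in specs) {
    arr <- sub$array_id[sp_of[samples] == sp]
    ## orientation: compute_ma leaves M as sample-vs-other; flip arrays whose
    ## orientation sample is the epidermis so positive always means
    ## gastroderm-higher
    sgn <- ifelse(g_of[samples[sp_of[samples] == sp]] == "G", 1, -1)
    P[, sp] <- rowMeans(sweep(ma$M[, arr, drop = FALSE], 2, sgn, `*`),
                        na.rm = TRUE)
  }
  list(per_specimen = P, m_direct = rowMeans(P, na.rm = TRUE))
}

#' Tissue contrast by transitivity through the common reference
#'
#' M_trans = M(G vs reference) - M(E vs reference), per specimen, averaged
#' across specimens. Genes missing one side in every specimen are flagged
#' `NA` and excluded from assignment.
#'
#' @inheritParams direct_tissue_contrast
#' @return list with `per_specimen` and `m_trans`.
#' @export
transitive_tissue_contrast <- function(ma, tissue_samples) {
  des <- ma$design
  samples <- array_samples(des)
  specs <- unique(tissue_samples$specimen)
  P <- matrix(NA_real_, nrow(ma$M), length(specs),
              dimnames = list(rownames(ma$M), specs))
  found <- logical(length(specs)); names(found) <- specs
  for (sp in specs) {
    gsample <- tissue_samples$sample[tissue_samples$specimen == sp &
                                       tissue_samples$tissue == "G"]
    esample <- tissue_samples$sample[tissue_samples$specimen == sp &
                                       tissue_samples$tissue == "E"]
    ## tissue-vs-reference arrays only: the partner channel is not a tissue
    ## sample of the same specimen
    is_ref_array <- function(smp) {
      arr <- des$array_id[samples == smp]
      other <- ifelse(samples[match(arr, des$array_id)] ==
                        des$cy5_sample[match(arr, des$array_id)],
                      des$cy3_sample[match(arr, des$array_id)],
                      des$cy5_sample[match(arr, des$array_id)])
      arr[!other %in% tissue_samples$sample]
    }
    garr <- is_ref_array(gsample)
    earr <- is_ref_array(esample)
    if (length(garr) == 0 || length(earr) == 0) next
    found[sp] <- TRUE
    mg <- rowMeans(ma$M[, garr, drop = FALSE], na.rm = TRUE)
    me <- rowMeans(ma$M[, earr, drop = FALSE], na.rm = TRUE)
    P[, sp] <- mg - me
  }
  if (!any(found))
    stop_arg("no tissue-vs-reference arrays found for any specimen")
  list(per_specimen = P[, found, drop = FALSE],
       m_trans = rowMeans(P[, found, drop = FALSE], na.rm = TRUE))
}

#' Assign tissue-preferential expression
#'
#' Intersection rule with strict inequalities: gastroderm iff both the
#' direct and the transitive M exceed `thresh`; epidermis iff both are below
#' `-thresh`; anything else (including discordant signs) is unassigned.
#'
#' @param m_direct,m_trans named per-gene contrast vectors on the same
#'   probe set.
#' @param thresh log2 threshold, default 0.59 (1.5-fold).
#' @return data.frame of class `tissue_call`: `probe_id`, `m_direct`,
#'   `m_trans`, `call` in `Ga`/`Ep`/`none`.
#' @export
assign_tissue <- function(m_direct, m_trans, thresh = 0.59) {
  if (length(m_direct) != length(m_trans))
    stop_arg("m_direct and m_trans must cover the same probe set")
  if (!is.null(names(m_direct)) && !is.null(names(m_trans)) &&
      !identical(names(m_direct), names(m_trans)))
    stop_arg("m_direct and m_trans must cover the same probe set")
  call <- rep("none", length(m_direct))
  ok <- !is.na(m_direct) & !is.na(m_trans)
  call[ok & m_direct > thresh & m_trans > thresh] <- "Ga"
  call[ok & m_direct < -thresh & m_trans < -thresh] <- "Ep"
  structure(data.frame(probe_id = names(m_direct) %||%
                         as.character(seq_along(m_direct)),
                       m_direct = as.numeric(m_direct),
                       m_trans = as.numeric(m_trans), call = call,
                       row.names = NULL, stringsAsFactors = FALSE),
            thresh = thresh, class = c("tissue_call", "data.frame"))
}

#' Cross-classify tissue and state calls (Venn regions)
#'
#' Restricts to cnidarian-origin probes, then counts the disjoint regions of
#' the tissue (Ga/Ep/none) by state (SY/APO/none) cross-classification.
#' Region counts sum to the number of cnidarian probes considered.
#'
#' @param tissue_calls a `tissue_call` table.
#' @param sy_genes,apo_genes probe ids called up in the symbiotic /
#'   aposymbiotic state (must be disjoint).
#' @param annotation probe annotation with `probe_id` and `origin`.
#' @return list of class `venn_counts`: `counts` (3x3 table tissue x state),
#'   `n_cnidarian`, `ga_fraction` (gastroderm share among tissue-assigned
#'   genes).
#' @export
venn_cross_classification <- function(tissue_calls, sy_genes, apo_genes,
                                      annotation) {
  if (length(intersect(sy_genes, apo_genes)) > 0)
    stop_arg("SY and APO gene sets must be disjoint")
  cnid <- annotation$probe_id[annotation$origin == "cnidarian"]
  tc <- tissue_calls[tissue_calls$probe_id %in% cnid, , drop = FALSE]
  state <- rep("none", nrow(tc))
  state[tc$probe_id %in% sy_genes] <- "SY"
  state[tc$probe_id %in% apo_genes] <- "APO"
  counts <- table(tissue = factor(tc$call, c("Ga", "Ep", "none")),
                  state = factor(state, c("SY", "APO", "none")))
  assigned <- sum(counts[c("Ga", "Ep"), ])
  structure(list(counts = counts, n_cnidarian = nrow(tc),
                 ga_fraction = if (assigned > 0)
                   sum(counts["Ga", ]) / assigned else NA_real_),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Cnidarian genes considered:", x$n_cnidarian, "\n")
  print(x$counts)
  if (!is.na(x$ga_fraction))
    cat(sprintf("Gastroderm fraction among tissue-assigned genes: %.1f%%\n",
                100 * x$ga_fraction))
  invisible(x)
}
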