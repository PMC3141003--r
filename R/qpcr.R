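## qPCR analysis: standard curves and amplification efficiencies,
## curve-based copy quantification, symbiont:host nuclei ratios with
## calibrator normalization, within-organism locus-ratio diagnostics,
## geNorm-style reference-gene stability, normalization factors, relative
## expression against a calibrator specimen, and heat-stress time-course
## folds.

#' Summarize technical replicate wells
#'
#' Replicate Cq values are averaged per sample x assay; a standard deviation
#' above `sd_flag` cycles is flagged.
#'
#' @param qpcr long-format data.frame with `sample`, `assay`, `cq` (and
#'   optionally `replicate`, `role`, `time`, ...).
#' @param sd_flag flag threshold in cycles, default 0.5.
#' @return data.frame with one row per sample x assay (plus any of `role`,
#'   `log10_copies`, `time` carried through): mean `cq`, `cq_sd`, `flagged`.
#' @export
summarize_replicates <- function(qpcr, sd_flag = 0.5) {
  keys <- intersect(c("sample", "specimen", "assay", "time"), names(qpcr))
  if (length(keys) == 0 || !"cq" %in% names(qpcr))
    stop_arg("qPCR table needs a cq column and at least one of ",
             "sample/specimen plus assay")
  extra <- setdiff(names(qpcr), c(keys, "replicate", "cq"))
  key <- interaction(qpcr[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(qpcr)), key)
  rows <- lapply(idx, function(i) {
    out <- qpcr[i[1], c(keys, extra), drop = FALSE]
    out$cq <- mean(qpcr$cq[i])
    out$cq_sd <- if (length(i) > 1) sd(qpcr$cq[i]) else 0
    out
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$cq_sd > sd_flag
  rownames(out) <- NULL
  out
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq on log10(copies) over a dilution series. The
#' amplification efficiency is E = 10^(-1/slope); a perfect doubling assay
#' has slope -1/log10(2) = -3.3219 and E = 2.
#'
#' @param log10_copies,cq dilution-series coordinates (>= 3 distinct
#'   points).
#' @param locus assay label.
#' @param r2_warn r-squared below which the fit is flagged, default 0.98.
#' @return list of class `standard_curve`: `locus`, `slope`, `intercept`
#'   (Cq at 1 copy), `r2`, `efficiency`, `flagged`, `range` (log10 copies).
#' @export
fit_standard_curve <- function(log10_copies, cq, locus = "locus",
                               r2_warn = 0.98) {
  if (length(log10_copies) != length(cq))
    stop_arg("log10_copies and cq must have equal length")
  if (length(unique(log10_copies)) < 3)
    stop_arg("need at least 3 distinct dilution points")
  x <- log10_copies; yv <- cq
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (yv - mean(yv))) / sxx
  intercept <- mean(yv) - slope * mean(x)
  if (!is.finite(slope) || slope >= 0)
    stop_arg("standard-curve fit failed: slope must be negative (locus ",
             locus, ")")
  ss_tot <- sum((yv - mean(yv))^2)
  ss_res <- sum((yv - intercept - slope * x)^2)
  r2 <- if (ss_tot <= 0) 1 else max(0, 1 - ss_res / ss_tot)
  eff <- 10^(-1 / slope)
  flagged <- r2 < r2_warn
  if (flagged)
    warning("standard curve for '", locus, "' has r2 = ",
            formatC(r2, digits = 4), call. = FALSE)
  structure(list(locus = locus, slope = slope, intercept = intercept,
                 r2 = r2, efficiency = eff, flagged = flagged,
                 range = range(log10_copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve %s: slope %.4f, intercept %.2f, E = %.3f, r2 = %.4f\n",
              x$locus, x$slope, x$intercept, x$efficiency, x$r2))
  invisible(x)
}

#' Fit standard curves for every assay in a qPCR table
#'
#' @param qpcr long-format table; rows with `role == "standard"` and a
#'   `log10_copies` column are used.
#' @return named list of `standard_curve` objects.
#' @export
fit_standard_curves <- function(qpcr) {
  std <- summarize_replicates(qpcr[qpcr$role == "standard", , drop = FALSE])
  lapply(split(std, std$assay), function(d)
    fit_standard_curve(d$log10_copies, d$cq, locus = d$assay[1]))
}

#' Convert Cq to copy number through a standard curve
#'
#' copies = 10^((cq - intercept)/slope). Values outside the fitted dilution
#' range are returned with an `extrapolated` attribute.
#'
#' @param cq Cq value(s).
#' @param curve a `standard_curve`.
#' @return Copy numbers (with attribute `extrapolated`, logical).
#' @export
quantify_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  lg <- (cq - curve$intercept) / curve$slope
  copies <- 10^lg
  attr(copies, "extrapolated") <- !is.na(lg) &
    (lg < curve$range[1] | lg > curve$range[2])
  copies
}

cq_lookup <- function(cq_table, sample, assay) {
  i <- which(cq_table$sample == sample & cq_table$assay == assay)
  if (length(i) == 0) return(NA_real_)
  cq_table$cq[i[1]]
}

#' Symbiont:host copy-number ratios with calibrator normalization
#'
#' For each specimen and each (symbiont locus, host locus) pair, computes
#' the copy ratio through the standard curves and the ratio relative to the
#' calibrator specimen. An undetermined symbiont Cq (NA) is reported as
#' below detection, with the detection-limit ratio implied by
#' `detection_cq`, never silently as 0.
#'
#' @param cq_table replicate-summarized table (`sample`, `assay`, `cq`).
#' @param curves named list of `standard_curve`s covering every locus.
#' @param symbiont_loci,host_loci locus labels per organism.
#' @param calibrator specimen the relative ratios are scaled to (ratio_rel
#'   = 1 there by construction).
#' @param detection_cq Cq treated as the detection limit for undetermined
#'   reactions, default 40.
#' @return list of class `copy_ratio_table`: `pairs` (per specimen x locus
#'   pair: `ratio`, `ratio_rel`, `below_detection`, `detection_limit`) and
#'   `consensus` (per specimen geometric mean of `ratio_rel` over fully
#'   detected pairs).
#' @export
symbiont_host_ratio <- function(cq_table, curves, symbiont_loci, host_loci,
                                calibrator, detection_cq = 40) {
  loci <- c(symbiont_loci, host_loci)
  miss <- setdiff(loci, names(curves))
  if (length(miss) > 0)
    stop_arg("no standard curve for: ", paste(miss, collapse = ", "))
  specimens <- unique(cq_table$sample)
  if (!calibrator %in% specimens)
    stop_arg("calibrator '", calibrator, "' not present")
  rows <- list()
  for (sp in specimens) for (sl in symbiont_loci) for (hl in host_loci) {
    cq_s <- cq_lookup(cq_table, sp, sl)
    cq_h <- cq_lookup(cq_table, sp, hl)
    host <- quantify_copies(cq_h, curves[[hl]])
    below <- is.na(cq_s) && !is.na(cq_h)
    sym <- if (below) NA_real_ else quantify_copies(cq_s, curves[[sl]])
    limit <- if (below)
      as.numeric(quantify_copies(detection_cq, curves[[sl]])) / host
      else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      specimen = sp, symbiont_locus = sl, host_locus = hl,
      ratio = as.numeric(sym) / as.numeric(host),
      below_detection = below, detection_limit = limit,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  ## calibrator-relative ratio per locus pair
  pairs$ratio_rel <- NA_real_
  for (sl in symbiont_loci) for (hl in host_loci) {
    sel <- pairs$symbiont_locus == sl & pairs$host_locus == hl
    cal <- pairs$ratio[sel & pairs$specimen == calibrator]
    if (length(cal) == 1 && !is.na(cal) && cal > 0)
      pairs$ratio_rel[sel] <- pairs$ratio[sel] / cal
  }
  consensus <- vapply(specimens, function(sp) {
    r <- pairs$ratio_rel[pairs$specimen == sp & !pairs$below_detection]
    r <- r[!is.na(r) & r > 0]
    if (length(r) == 0) NA_real_ else geometric_mean(r)
  }, numeric(1))
  structure(list(pairs = pairs,
                 consensus = data.frame(specimen = specimens,
                                        ratio_rel = unname(consensus),
                                        stringsAsFactors = FALSE),
                 calibrator = calibrator),
            class = "copy_ratio_table")
}

#' Pairwise locus-ratio diagnostics within one organism
#'
#' Checks that loci of one genome sit in a ~1:1 copy ratio per specimen
#' (deviations flag locus-specific amplification).
#'
#' @param cq_table replicate-summarized table.
#' @param curves named list of standard curves.
#' @param loci >= 2 locus labels of one organism.
#' @param flag_factor flag ratios deviating from 1 by more than this factor
#'   (default 2).
#' @return data.frame: specimen, locus_a, locus_b, ratio, flagged.
#' @export
locus_ratio_diagnostics <- function(cq_table, curves, loci, flag_factor = 2) {
  if (length(loci) < 2) stop_arg("need at least 2 loci")
  specimens <- unique(cq_table$sample)
  rows <- list()
  for (sp in specimens) {
    copies <- vapply(loci, function(l)
      as.numeric(quantify_copies(cq_lookup(cq_table, sp, l), curves[[l]])),
      numeric(1))
    for (i in seq_along(loci)) for (j in seq_along(loci)) {
      if (j <= i) next
      r <- copies[i] / copies[j]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sp, locus_a = loci[i], locus_b = loci[j], ratio = r,
        flagged = !is.na(r) & (r > flag_factor | r < 1 / flag_factor),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative quantities from Cq values
#'
#' Conventional geNorm input: per assay, q = E^(min Cq - Cq), so the
#' best-expressed sample has quantity 1.
#'
#' @param cq_matrix samples x genes matrix of Cq values.
#' @param efficiencies per-gene amplification factors (recycled scalar
#'   allowed), in (1, 2.2].
#' @return samples x genes matrix of relative quantities.
#' @export
relative_quantities <- function(cq_matrix, efficiencies = 2) {
  efficiencies <- rep_len(efficiencies, ncol(cq_matrix))
  if (any(efficiencies <= 1)) stop_arg("efficiencies must exceed 1")
  q <- cq_matrix
  for (j in seq_len(ncol(q)))
    q[, j] <- efficiencies[j]^(min(cq_matrix[, j], na.rm = TRUE) -
                                 cq_matrix[, j])
  q
}

#' geNorm-style reference-gene stability
#'
#' For candidate gene j, the stability measure M_j is the mean over partner
#' genes k != j of the standard deviation across samples of
#' log2(q_j / q_k). The least stable gene (largest M) is excluded
#' iteratively down to a panel of `panel_size` genes; ties break by gene
#' label.
#'
#' @param quantities samples x genes matrix of strictly positive relative
#'   quantities (>= 3 genes, >= 2 samples).
#' @param panel_size size of the retained panel, default 3.
#' @return list of class `stability_ranking`: `m_values` (initial M per
#'   gene), `exclusion_order`, `panel`, `m_history` (list of named M vectors
#'   per iteration).
#' @export
gene_stability <- function(quantities, panel_size = 3) {
  q <- as.matrix(quantities)
  if (ncol(q) < 3) stop_arg("need at least 3 candidate genes")
  if (nrow(q) < 2) stop_arg("need at least 2 samples")
  if (any(q <= 0)) stop_arg("quantities must be strictly positive")
  genes <- colnames(q) %||% sprintf("g%d", seq_len(ncol(q)))
  colnames(q) <- genes
  m_of <- function(sub) {
    g <- colnames(sub)
    vapply(g, function(j) {
      mean(vapply(setdiff(g, j), function(k)
        sd(log2(sub[, j] / sub[, k])), numeric(1)))
    }, numeric(1))
  }
  m_values <- m_of(q)
  history <- list(m_values)
  excluded <- character()
  cur <- q
  while (ncol(cur) > max(panel_size, 2)) {
    m <- m_of(cur)
    worst <- names(m)[order(-m, names(m))][1]
    excluded <- c(excluded, worst)
    cur <- cur[, setdiff(colnames(cur), worst), drop = FALSE]
    history[[length(history) + 1L]] <- m_of(cur)
  }
  structure(list(m_values = m_values, exclusion_order = excluded,
                 panel = colnames(cur), m_history = history),
            class = "stability_ranking")
}

#' Normalization factor per sample
#'
#' Geometric mean of the selected reference genes' relative quantities.
#'
#' @param quantities samples x genes matrix restricted to the selected
#'   panel; strictly positive.
#' @return Named per-sample normalization factors.
#' @export
normalization_factor <- function(quantities) {
  q <- as.matrix(quantities)
  if (ncol(q) < 1) stop_arg("panel must be non-empty")
  if (any(q <= 0)) stop_arg("quantities must be strictly positive")
  apply(q, 1, geometric_mean)
}

#' Relative expression against a calibrator specimen
#'
#' Quantity per sample from the assay efficiency (or standard curve),
#' divided by the sample's normalization factor, scaled to the calibrator.
#'
#' @param target_cq named per-sample Cq vector for the target assay.
#' @param nf named per-sample normalization factors (see
#'   [normalization_factor()]).
#' @param efficiency amplification factor of the target assay (ignored when
#'   `curve` is given).
#' @param curve optional `standard_curve` for curve-based quantities.
#' @param calibrator sample the folds are relative to, default `"AS6"`.
#' @return Named fold vector; the calibrator maps to 1.
#' @export
relative_expression <- function(target_cq, nf, efficiency = 2, curve = NULL,
                                calibrator = "AS6") {
  if (!calibrator %in% names(target_cq))
    stop_arg("calibrator '", calibrator, "' missing from target_cq")
  if (!all(names(target_cq) %in% names(nf)))
    stop_arg("normalization factors missing for some samples")
  q <- if (!is.null(curve)) {
    as.numeric(quantify_copies(target_cq, curve))
  } else {
    if (efficiency <= 1) stop_arg("efficiency must exceed 1")
    efficiency^(min(target_cq, na.rm = TRUE) - target_cq)
  }
  names(q) <- names(target_cq)
  norm <- q / nf[names(q)]
  norm / norm[calibrator]
}

#' Time-course expression folds relative to t0
#'
#' Per specimen, target quantities are normalized by the geometric mean of
#' the reference genes at each time point, then expressed relative to t0;
#' the cross-specimen geometric mean and its standard error are reported.
#'
#' @param cq long-format table with `specimen`, `assay`, `time`, `cq`
#'   (replicate-summarized; `time` numeric, t0 must be present per
#'   specimen).
#' @param targets target assay labels.
#' @param reference_genes reference assay labels (default `RCC2`, `COP-g`).
#' @param efficiency amplification factor used for all assays (default 2).
#' @return list of class `timecourse_folds`: `per_specimen` (specimen,
#'   assay, time, fold) and `summary` (assay, time, mean fold, se).
#' @export
timecourse_fold <- function(cq, targets,
                            reference_genes = c("RCC2", "COP-g"),
                            efficiency = 2) {
  need <- c("specimen", "assay", "time", "cq")
  if (!all(need %in% names(cq)))
    stop_arg("cq table must have columns: ", paste(need, collapse = ", "))
  specimens <- unique(cq$specimen)
  rows <- list()
  for (sp in specimens) {
    d <- cq[cq$specimen == sp, , drop = FALSE]
    times <- sort(unique(d$time))
    if (!0 %in% times) {
      warning("specimen '", sp, "' has no t0; dropped", call. = FALSE)
      next
    }
    qty <- function(assay, tm) {
      i <- which(d$assay == assay & d$time == tm)
      if (length(i) == 0) return(NA_real_)
      efficiency^(-d$cq[i[1]])
    }
    nf <- vapply(times, function(tm)
      geometric_mean(vapply(reference_genes, qty, numeric(1), tm = tm)),
      numeric(1))
    names(nf) <- as.character(times)
    for (tg in targets) {
      q0 <- qty(tg, 0) / nf["0"]
      for (tm in times) {
        rows[[length(rows) + 1L]] <- data.frame(
          specimen = sp, assay = tg, time = tm,
          fold = (qty(tg, tm) / nf[as.character(tm)]) / q0,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop_arg("no specimen with a t0 measurement")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  agg <- lapply(split(per, list(per$assay, per$time), drop = TRUE),
                function(d) {
                  lf <- log(d$fold)
                  data.frame(assay = d$assay[1], time = d$time[1],
                             fold = exp(mean(lf)),
                             se = if (nrow(d) > 1)
                               exp(mean(lf)) * sd(lf) / sqrt(nrow(d)) else 0,
                             stringsAsFactors = FALSE)
                })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  structure(list(per_specimen = per, summary = summary),
            class = "timecourse_folds")
}
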