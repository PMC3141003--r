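## Synthetic qPCR datasets with planted ground truth: per-locus dilution
## series (six 10-fold points by default), genomic-DNA unknowns implied by
## planted symbiont:host nuclei ratios, a reference-gene panel with one
## deliberately unstable gene, calibrator-relative target expression, and a
## heat-stress time course with a planted fold drop.
##
## Cq model: Cq = intercept + slope * log10(copies) + noise, with
## slope = -1/log10(E). The same curve maps planted copy numbers to
## unknown-sample Cq values, so noiseless configurations close exactly
## through the quantification module.

#' Configuration for a synthetic qPCR dataset
#'
#' Defaults state the emulated study: symbiont loci EF2/SPS/APX vs host loci
#' COP-g/RCC2/NPC1 on genomic DNA of 5 symbiotic + 6 aposymbiotic
#' specimens with symbiont:host ratios spanning 1 down to ~1e-4 of the
#' calibrator (Sy1), locus efficiencies in [1.8, 2], six-point 10-fold
#' dilution series, a reference panel whose selected trio is
#' RPLP0/RCC2/COP-g plus one unstable candidate, target genes with planted
#' symbiotic-state folds, and a 3-fold expression drop at 24/48 h of heat
#' stress.
#'
#' @param symbiont_loci,host_loci locus labels per organism.
#' @param planted_ratio named symbiont:host nuclei ratio per specimen.
#' @param planted_efficiency named amplification factor per genomic locus,
#'   each in (1, 2].
#' @param locus_scale named per-locus copy multiplier (models
#'   locus-specific gene amplification, e.g. tandem-repeated EF2); default
#'   all 1.
#' @param reference_genes candidate reference panel (first three are the
#'   stable trio).
#' @param unstable_gene the deliberately unstable candidate.
#' @param target_folds named planted expression folds (symbiotic specimens
#'   vs the AS6 calibrator).
#' @param timecourse_targets,timecourse_drop heat-stress targets and their
#'   planted fold drop at 24 h and 48 h.
#' @param cq_noise_sd Cq noise standard deviation in cycles.
#' @param dilution_points points per 10-fold dilution series, default 6.
#' @param replicates technical replicate wells, default 3.
#' @param seed integer seed.
#' @return list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(
    symbiont_loci = c("EF2", "SPS", "APX"),
    host_loci = c("COP-g", "RCC2", "NPC1"),
    planted_ratio = c(Sy1 = 1, Sy2 = 0.9, Sy3 = 0.7, Sy4 = 0.8, Sy5 = 0.6,
                      AS1 = 1e-2, AS2 = 5e-3, AS3 = 1e-3, AS4 = 8.2e-2,
                      AS5 = 2e-3, AS6 = 6e-5),
    planted_efficiency = c(EF2 = 1.9, SPS = 1.85, APX = 1.95,
                           `COP-g` = 2, RCC2 = 1.9, NPC1 = 1.8),
    locus_scale = NULL,
    reference_genes = c("RPLP0", "RCC2", "COP-g", "EF1a", "GAPDH"),
    unstable_gene = "GAPDH",
    target_folds = c(`NPC2-D` = 4.6, Sym32 = 47.8, `CA2-c` = 13.2,
                     `CA2-m` = 8.6),
    timecourse_targets = c("CA2-c", "CA2-m", "NPC2-D"),
    timecourse_drop = 3,
    cq_noise_sd = 0.1, dilution_points = 6, replicates = 3, seed = 1) {
  if (any(planted_ratio < 0))
    stop_arg("planted ratios must be positive (or zero, flagged)")
  loci <- c(symbiont_loci, host_loci)
  if (!all(loci %in% names(planted_efficiency)))
    stop_arg("planted_efficiency must cover every locus")
  eff <- planted_efficiency[loci]
  if (any(eff <= 1)) stop_arg("efficiencies must exceed 1")
  if (any(eff > 2)) stop_arg("efficiencies must not exceed 2")
  if (is.null(locus_scale)) locus_scale <- setNames(rep(1, length(loci)), loci)
  if (cq_noise_sd < 0) stop_arg("cq_noise_sd must be >= 0")
  check_counts(dilution_points = dilution_points, replicates = replicates)
  if (dilution_points < 3) stop_arg("need at least 3 dilution points")
  if (!unstable_gene %in% reference_genes)
    stop_arg("unstable_gene must be one of reference_genes")
  structure(list(symbiont_loci = symbiont_loci, host_loci = host_loci,
                 planted_ratio = planted_ratio,
                 planted_efficiency = planted_efficiency,
                 locus_scale = locus_scale,
                 reference_genes = reference_genes,
                 unstable_gene = unstable_gene,
                 target_folds = target_folds,
                 timecourse_targets = timecourse_targets,
                 timecourse_drop = timecourse_drop,
                 cq_noise_sd = cq_noise_sd,
                 dilution_points = dilution_points,
                 replicates = replicates, seed = seed),
            class = "qpcr_sim_config")
}

## Cq at 1 copy, per assay; fixed plausible values around 38 cycles.
assay_intercept <- function(assay) {
  36 + (utf8ToInt(substr(assay, 1, 1)) %% 5)
}

cq_from_copies <- function(copies, efficiency, intercept, noise_sd) {
  slope <- -1 / log10(efficiency)
  intercept + slope * log10(copies) +
    if (noise_sd > 0) rnorm(length(copies), 0, noise_sd) else 0
}

#' Generate a synthetic qPCR dataset with planted truth
#'
#' @param cfg a [qpcr_sim_config()].
#' @return list with `qpcr` (long-format table: sample, assay, role,
#'   log10_copies, replicate, cq), `timecourse` (specimen, assay, time,
#'   replicate, cq), and `truth` (class `qpcr_truth`: planted ratios,
#'   efficiencies, intercepts, target fold matrix, unstable gene, planted
#'   time-course drop).
#' @export
generate_qpcr_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  loci <- c(cfg$symbiont_loci, cfg$host_loci)
  specimens <- names(cfg$planted_ratio)
  reps <- seq_len(cfg$replicates)
  with_seed(sub_seed(cfg$seed, 53L), {
    rows <- list()
    add <- function(sample, assay, role, log10_copies, cq) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, assay = assay, role = role,
        log10_copies = log10_copies, replicate = reps, cq = cq,
        stringsAsFactors = FALSE)
    }
    ## dilution series per genomic locus
    for (l in loci) {
      E <- cfg$planted_efficiency[[l]]
      for (d in seq_len(cfg$dilution_points)) {
        lg <- cfg$dilution_points + 1 - d   # 10^6 .. 10^1 by default
        cq <- cq_from_copies(rep(10^lg, cfg$replicates), E,
                             assay_intercept(l), cfg$cq_noise_sd)
        add(paste0("std", d), l, "standard", lg, cq)
      }
    }
    ## genomic-DNA unknowns implied by planted ratios
    host_nuclei <- setNames(10^runif(length(specimens), 3.5, 4.5), specimens)
    for (sp in specimens) {
      for (l in cfg$host_loci) {
        copies <- host_nuclei[[sp]] * cfg$locus_scale[[l]]
        add(sp, l, "unknown", NA,
            cq_from_copies(rep(copies, cfg$replicates),
                           cfg$planted_efficiency[[l]],
                           assay_intercept(l), cfg$cq_noise_sd))
      }
      for (l in cfg$symbiont_loci) {
        copies <- host_nuclei[[sp]] * cfg$planted_ratio[[sp]] *
          cfg$locus_scale[[l]]
        if (copies <= 0) {
          add(sp, l, "unknown", NA, rep(NA_real_, cfg$replicates))
        } else {
          add(sp, l, "unknown", NA,
              cq_from_copies(rep(copies, cfg$replicates),
                             cfg$planted_efficiency[[l]],
                             assay_intercept(l), cfg$cq_noise_sd))
        }
      }
    }
    ## expression panel on cDNA: common per-sample loading factor, stable
    ## references proportional to it, one unstable candidate, targets with
    ## planted symbiotic folds (E = 2 for all cDNA assays)
    loading <- setNames(2^rnorm(length(specimens), 0, 0.5), specimens)
    base_q <- 1e4
    sy_specimens <- grep("^Sy", specimens, value = TRUE)
    fold_matrix <- matrix(1, length(specimens), length(cfg$target_folds),
                          dimnames = list(specimens,
                                          names(cfg$target_folds)))
    fold_matrix[sy_specimens, ] <- rep(cfg$target_folds,
                                       each = length(sy_specimens))
    for (sp in specimens) {
      for (g in cfg$reference_genes) {
        q <- base_q * loading[[sp]]
        if (g == cfg$unstable_gene) q <- q * 2^rnorm(1, 0, 1)
        add(sp, g, "reference", NA,
            cq_from_copies(rep(q, cfg$replicates), 2, assay_intercept(g),
                           cfg$cq_noise_sd))
      }
      for (g in names(cfg$target_folds)) {
        q <- base_q * loading[[sp]] * fold_matrix[sp, g]
        add(sp, g, "target", NA,
            cq_from_copies(rep(q, cfg$replicates), 2, assay_intercept(g),
                           cfg$cq_noise_sd))
      }
    }
    qpcr <- do.call(rbind, rows)

    ## heat-stress time course on Sy3-5: planted drop at 24 h and 48 h,
    ## stable references
    tc_rows <- list()
    tc_specimens <- intersect(c("Sy3", "Sy4", "Sy5"), specimens)
    for (sp in tc_specimens) for (tm in c(0, 24, 48)) {
      tload <- 2^rnorm(1, 0, 0.3)
      for (g in c("RCC2", "COP-g")) {
        cq <- cq_from_copies(rep(base_q * tload, cfg$replicates), 2,
                             assay_intercept(g), cfg$cq_noise_sd)
        tc_rows[[length(tc_rows) + 1L]] <- data.frame(
          specimen = sp, assay = g, time = tm, replicate = reps, cq = cq,
          stringsAsFactors = FALSE)
      }
      for (g in cfg$timecourse_targets) {
        q <- base_q * tload * if (tm == 0) 1 else 1 / cfg$timecourse_drop
        cq <- cq_from_copies(rep(q, cfg$replicates), 2, assay_intercept(g),
                             cfg$cq_noise_sd)
        tc_rows[[length(tc_rows) + 1L]] <- data.frame(
          specimen = sp, assay = g, time = tm, replicate = reps, cq = cq,
          stringsAsFactors = FALSE)
      }
    }
    truth <- structure(list(
      planted_ratio = cfg$planted_ratio,
      planted_efficiency = cfg$planted_efficiency,
      intercepts = setNames(vapply(loci, assay_intercept, numeric(1)), loci),
      target_folds = fold_matrix,
      unstable_gene = cfg$unstable_gene,
      timecourse_drop = cfg$timecourse_drop), class = "qpcr_truth")
    list(qpcr = qpcr, timecourse = do.call(rbind, tc_rows), truth = truth)
  })
}
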