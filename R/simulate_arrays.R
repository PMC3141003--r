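## Synthetic two-color array experiments with planted ground truth.
##
## The generator emulates the structure the downstream stages assume: a set
## of symbiotic (Sy*) and aposymbiotic (AS*) specimens, each hybridized as a
## dye-swap pair against one common reference sample, heterogeneous
## per-individual activity of the planted state genes (the phenomenon the
## consensus "Kern" rule is designed to absorb), a smooth intensity-dependent
## dye bias per print-tip group, additive background, and symbiont-origin
## probes whose signal collapses to background wherever no symbionts are
## present (aposymbiotic animals, epidermis, reference).
##
## Intensity model: per-probe baseline log2 intensity ~ Normal(10, 1.5);
## channel foreground = background draw + 2^(expression + dye-bias half +
## noise); the background draw (Normal(bg_mean, bg_mean/10) truncated at 0)
## is also what is written to the scan's background columns, so noiseless
## configurations close exactly under background subtraction.

#' Configuration for a synthetic symbiotic-state experiment
#'
#' Defaults state the emulated study design: 5 symbiotic + 6 aposymbiotic
#' specimens, dye-swap pairs against a common reference, and per-individual
#' Bernoulli activity of the planted genes.
#'
#' @param n_probes number of probes (must match the annotation used).
#' @param n_sy_specimens,n_apo_specimens specimens per state.
#' @param n_planted_sy,n_planted_apo planted differentially expressed genes
#'   per direction (drawn among cnidarian probes).
#' @param effect_log2 planted absolute log2 fold change.
#' @param activity_prob probability that a planted gene is active in a given
#'   individual (models inter-individual heterogeneity).
#' @param noise_sd per-probe log2 noise standard deviation on the M scale
#'   (each channel receives noise_sd/sqrt(2)).
#' @param dye_bias_amplitude amplitude of the smooth cubic intensity-dependent
#'   dye bias (log2 units on M); 0 disables.
#' @param n_print_tips number of print-tip groups.
#' @param bg_mean mean additive background intensity.
#' @param replicate_spots spots printed per probe (replicates are collapsed
#'   by per-channel median at read time).
#' @param seed integer seed.
#' @return A list of class `state_sim_config`.
#' @export
state_sim_config <- function(n_probes = 2000, n_sy_specimens = 5,
                             n_apo_specimens = 6, n_planted_sy = 60,
                             n_planted_apo = 80, effect_log2 = 1.5,
                             activity_prob = 0.9, noise_sd = 0.3,
                             dye_bias_amplitude = 0.3, n_print_tips = 16,
                             bg_mean = 50, replicate_spots = 1, seed = 1) {
  check_counts(n_probes = n_probes, n_sy_specimens = n_sy_specimens,
               n_apo_specimens = n_apo_specimens,
               n_planted_sy = n_planted_sy, n_planted_apo = n_planted_apo,
               n_print_tips = n_print_tips, replicate_spots = replicate_spots)
  if (n_planted_sy + n_planted_apo > n_probes)
    stop_arg("n_planted_sy + n_planted_apo must not exceed n_probes")
  if (activity_prob < 0 || activity_prob > 1)
    stop_arg("activity_prob must be in [0, 1]")
  if (noise_sd < 0) stop_arg("noise_sd must be >= 0")
  structure(list(n_probes = n_probes, n_sy_specimens = n_sy_specimens,
                 n_apo_specimens = n_apo_specimens,
                 n_planted_sy = n_planted_sy, n_planted_apo = n_planted_apo,
                 effect_log2 = effect_log2, activity_prob = activity_prob,
                 noise_sd = noise_sd,
                 dye_bias_amplitude = dye_bias_amplitude,
                 n_print_tips = n_print_tips, bg_mean = bg_mean,
                 replicate_spots = replicate_spots, seed = seed),
            class = "state_sim_config")
}

## log2 expression a probe of symbiont origin shows where no symbionts are
## present: essentially background-level signal.
.ZOOX_ABSENT_LOG2 <- 1

print_tip_assignment <- function(n_probes, n_print_tips) {
  per <- ceiling(n_probes / max(n_print_tips, 1L))
  ((seq_len(n_probes) - 1L) %/% per) + 1L
}

## Smooth cubic dye bias as a function of baseline intensity A, mildly
## modulated per print-tip group. Attached to the red channel, so its sign
## flips on the dye-swap member of a pair.
dye_bias_curve <- function(A, amplitude, tip, n_tips) {
  u <- (A - 10) / 3
  tipmod <- 1 + 0.3 * (tip - (n_tips + 1) / 2) / max(n_tips, 1)
  amplitude * tipmod * (0.4 + 0.5 * u - 0.3 * u^2 + 0.2 * u^3)
}

## Build one scan data frame from per-channel true log2 expression vectors.
make_scan <- function(expr_red, expr_green, baseline, tip, cfg, rng_offset) {
  n <- length(baseline)
  half <- dye_bias_curve(baseline, cfg$dye_bias_amplitude, tip,
                         cfg$n_print_tips) / 2
  chan_sd <- cfg$noise_sd / sqrt(2)
  rep_one <- function() {
    noise_r <- if (chan_sd > 0) rnorm(n, 0, chan_sd) else 0
    noise_g <- if (chan_sd > 0) rnorm(n, 0, chan_sd) else 0
    bg_r <- pmax(rnorm(n, cfg$bg_mean, cfg$bg_mean / 10), 0)
    bg_g <- pmax(rnorm(n, cfg$bg_mean, cfg$bg_mean / 10), 0)
    if (cfg$bg_mean == 0) bg_r <- bg_g <- rep(0, n)
    data.frame(fg_red = bg_r + 2^(expr_red + half + noise_r),
               bg_red = bg_r,
               fg_green = bg_g + 2^(expr_green - half + noise_g),
               bg_green = bg_g)
  }
  reps <- do.call(rbind, lapply(seq_len(cfg$replicate_spots),
                                function(i) rep_one()))
  data.frame(probe_id = rep(names(baseline) %||%
                              sprintf("p%05d", seq_len(n)),
                            cfg$replicate_spots),
             print_tip_group = rep(tip, cfg$replicate_spots),
             reps, stringsAsFactors = FALSE)
}

## Dye-swap pair of scans for sample-vs-reference (or sample-vs-sample).
make_pair <- function(id, sample_expr, ref_expr, sample_name, ref_name,
                      baseline, tip, cfg) {
  a1 <- make_scan(sample_expr, ref_expr, baseline, tip, cfg)
  a2 <- make_scan(ref_expr, sample_expr, baseline, tip, cfg)
  list(scans = setNames(list(a1, a2), paste0(id, c(".1", ".2"))),
       design = data.frame(array_id = paste0(id, c(".1", ".2")),
                           cy3_sample = c(ref_name, sample_name),
                           cy5_sample = c(sample_name, ref_name),
                           dye_swap_of = c(NA, paste0(id, ".1")),
                           stringsAsFactors = FALSE))
}

new_scan_set <- function(scans, design) {
  structure(list(scans = scans, design = design), class = "array_scan_set")
}

#' @export
print.array_scan_set <- function(x, ...) {
  cat("array_scan_set:", length(x$scans), "arrays,",
      nrow(x$scans[[1]]), "spots each\n")
  invisible(x)
}

#' Simulate a symbiotic vs aposymbiotic hybridization experiment
#'
#' Generates one dye-swap pair of arrays per specimen against a common
#' reference sample, with planted state-direction genes whose activity is
#' drawn per individual, and records the ground truth.
#'
#' The reference channel carries a neutral baseline profile (a reference
#' RNA pool); every specimen, including all aposymbiotic ones, is hybridized
#' against it so that all individuals carry measurable profiles. Probes of
#' zooxanthella origin collapse to background-level signal in aposymbiotic
#' specimens and in the reference.
#'
#' @param cfg a [state_sim_config()].
#' @param annotation probe annotation table with `cfg$n_probes` rows.
#' @return list with `scans` (an `array_scan_set`), `specimens`
#'   (data.frame specimen/state), and `truth` (class `state_truth`:
#'   `direction` per probe, logical `activity` matrix probes x specimens,
#'   `true_log2fc` on the SY-minus-APO orientation).
#' @export
generate_state_experiment <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "state_sim_config"))
  if (nrow(annotation) != cfg$n_probes)
    stop_arg("annotation has ", nrow(annotation),
             " rows but cfg$n_probes is ", cfg$n_probes)
  specimens <- data.frame(
    specimen = c(sprintf("Sy%d", seq_len(cfg$n_sy_specimens)),
                 sprintf("AS%d", seq_len(cfg$n_apo_specimens))),
    state = rep(c("SY", "APO"),
                c(cfg$n_sy_specimens, cfg$n_apo_specimens)),
    stringsAsFactors = FALSE)
  n <- cfg$n_probes
  probes <- annotation$probe_id
  with_seed(sub_seed(cfg$seed, 23L), {
    baseline <- setNames(rnorm(n, 10, 1.5), probes)
    tip <- print_tip_assignment(n, cfg$n_print_tips)

    cnid <- which(annotation$origin == "cnidarian")
    if (length(cnid) < cfg$n_planted_sy + cfg$n_planted_apo)
      stop_arg("not enough cnidarian probes to plant the requested genes")
    planted <- sample(cnid, cfg$n_planted_sy + cfg$n_planted_apo)
    sy_genes <- planted[seq_len(cfg$n_planted_sy)]
    apo_genes <- setdiff(planted, sy_genes)
    direction <- rep("null", n)
    direction[sy_genes] <- "SY"
    direction[apo_genes] <- "APO"

    nspec <- nrow(specimens)
    activity <- matrix(NA, n, nspec,
                       dimnames = list(probes, specimens$specimen))
    activity[planted, ] <- matrix(
      rbinom(length(planted) * nspec, 1, cfg$activity_prob) == 1,
      length(planted), nspec)

    true_log2fc <- rep(0, n)
    true_log2fc[sy_genes] <- cfg$effect_log2
    true_log2fc[apo_genes] <- -cfg$effect_log2

    zoox <- annotation$origin == "zooxanthella"
    ref_expr <- baseline
    ref_expr[zoox] <- .ZOOX_ABSENT_LOG2

    scans <- list(); design <- NULL
    for (i in seq_len(nspec)) {
      sp <- specimens$specimen[i]; st <- specimens$state[i]
      e <- baseline
      if (st == "APO") e[zoox] <- .ZOOX_ABSENT_LOG2
      ## a planted gene is elevated in the individuals of its own state that
      ## are active, and in individuals of the opposite state that are
      ## inactive (an inactive individual has not switched its expression
      ## to its state's profile -- the modelled source of inter-individual
      ## heterogeneity)
      act <- !is.na(activity[, i]) & activity[, i]
      own <- if (st == "SY") sy_genes else apo_genes
      other <- if (st == "SY") apo_genes else sy_genes
      up <- c(intersect(which(act), own), intersect(which(!act), other))
      e[up] <- e[up] + cfg$effect_log2
      pr <- make_pair(sp, e, ref_expr, sp, "REF", baseline, tip, cfg)
      scans <- c(scans, pr$scans)
      design <- rbind(design, pr$design)
    }
    truth <- structure(list(direction = setNames(direction, probes),
                            activity = activity,
                            true_log2fc = setNames(true_log2fc, probes),
                            specimens = specimens),
                       class = "state_truth")
    list(scans = new_scan_set(scans, design), specimens = specimens,
         truth = truth)
  })
}

#' Configuration for a synthetic tissue (epidermis/gastroderm) experiment
#'
#' The emulated design uses at least three symbiotic specimens, each with a
#' direct gastroderm-vs-epidermis dye-swap pair and one pair per tissue
#' against the common reference. The default gastroderm/epidermis split of
#' planted tissue-preferential genes is 71/29.
#'
#' @param n_probes,noise_sd,dye_bias_amplitude,n_print_tips,bg_mean,replicate_spots,seed
#'   as in [state_sim_config()].
#' @param n_specimens number of specimens with separated tissues.
#' @param n_planted_ga,n_planted_ep planted gastroderm- and
#'   epidermis-preferential genes.
#' @param tissue_effect_log2 planted absolute tissue log2 fold.
#' @param n_planted_sy,n_planted_apo planted state-direction labels recorded
#'   in the truth (for cross-classification); drawn partly among the planted
#'   tissue genes.
#' @return A list of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(n_probes = 2000, n_specimens = 3,
                              n_planted_ga = 71, n_planted_ep = 29,
                              tissue_effect_log2 = 2,
                              n_planted_sy = 40, n_planted_apo = 40,
                              noise_sd = 0.3, dye_bias_amplitude = 0.3,
                              n_print_tips = 16, bg_mean = 50,
                              replicate_spots = 1, seed = 1) {
  check_counts(n_probes = n_probes, n_specimens = n_specimens,
               n_planted_ga = n_planted_ga, n_planted_ep = n_planted_ep,
               n_planted_sy = n_planted_sy, n_planted_apo = n_planted_apo)
  if (n_planted_ga + n_planted_ep > n_probes)
    stop_arg("planted tissue genes exceed n_probes")
  structure(list(n_probes = n_probes, n_specimens = n_specimens,
                 n_planted_ga = n_planted_ga, n_planted_ep = n_planted_ep,
                 tissue_effect_log2 = tissue_effect_log2,
                 n_planted_sy = n_planted_sy, n_planted_apo = n_planted_apo,
                 noise_sd = noise_sd,
                 dye_bias_amplitude = dye_bias_amplitude,
                 n_print_tips = n_print_tips, bg_mean = bg_mean,
                 replicate_spots = replicate_spots, seed = seed),
            class = "tissue_sim_config")
}

#' Simulate the dual tissue-contrast experiment
#'
#' Emits both designs used for tissue assignment: direct
#' gastroderm-vs-epidermis hybridizations, and each tissue hybridized against
#' the common reference (tissue contrast by transitivity). Zooxanthella
#' probes are expressed in the gastroderm only.
#'
#' @param cfg a [tissue_sim_config()].
#' @param annotation probe annotation table with `cfg$n_probes` rows.
#' @return list with `scans` (an `array_scan_set` covering both designs),
#'   `tissue_samples` (data.frame sample/specimen/tissue), and `truth`
#'   (class `tissue_truth`: per-probe `tissue_direction` (Ga/Ep/null),
#'   `state_direction` (SY/APO/null), `true_tissue_log2fc` on the
#'   gastroderm-minus-epidermis orientation).
#' @export
generate_tissue_experiment <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "tissue_sim_config"))
  if (nrow(annotation) != cfg$n_probes)
    stop_arg("annotation has ", nrow(annotation),
             " rows but cfg$n_probes is ", cfg$n_probes)
  n <- cfg$n_probes
  probes <- annotation$probe_id
  with_seed(sub_seed(cfg$seed, 37L), {
    baseline <- setNames(rnorm(n, 10, 1.5), probes)
    tip <- print_tip_assignment(n, cfg$n_print_tips)
    cnid <- which(annotation$origin == "cnidarian")
    n_t <- cfg$n_planted_ga + cfg$n_planted_ep
    if (length(cnid) < n_t)
      stop_arg("not enough cnidarian probes to plant the requested genes")
    planted <- sample(cnid, n_t)
    ga_genes <- planted[seq_len(cfg$n_planted_ga)]
    ep_genes <- setdiff(planted, ga_genes)
    tissue_direction <- rep("null", n)
    tissue_direction[ga_genes] <- "Ga"
    tissue_direction[ep_genes] <- "Ep"
    fc <- rep(0, n)
    fc[ga_genes] <- cfg$tissue_effect_log2
    fc[ep_genes] <- -cfg$tissue_effect_log2

    ## State-direction labels for cross-classification. Half of each state
    ## set is drawn among planted tissue genes (dual-status genes), the rest
    ## among unplanted cnidarian probes.
    state_direction <- rep("null", n)
    pick <- function(pool, k) if (k <= 0) integer() else
      pool[seq_len(min(k, length(pool)))]
    avail_t <- sample(planted)
    avail_0 <- sample(setdiff(cnid, planted))
    sy_pick <- c(pick(avail_t, cfg$n_planted_sy %/% 2),
                 pick(avail_0, cfg$n_planted_sy - cfg$n_planted_sy %/% 2))
    avail_t <- setdiff(avail_t, sy_pick); avail_0 <- setdiff(avail_0, sy_pick)
    apo_pick <- c(pick(avail_t, cfg$n_planted_apo %/% 2),
                  pick(avail_0, cfg$n_planted_apo - cfg$n_planted_apo %/% 2))
    state_direction[sy_pick] <- "SY"
    state_direction[apo_pick] <- "APO"

    zoox <- annotation$origin == "zooxanthella"
    e_ref <- baseline; e_ref[zoox] <- .ZOOX_ABSENT_LOG2

    scans <- list(); design <- NULL; tissue_samples <- NULL
    for (i in seq_len(cfg$n_specimens)) {
      sp <- sprintf("Sy%d", i + 2)   # separated tissues come from Sy3, Sy4, ...
      e_g <- baseline; e_e <- baseline
      e_g[ga_genes] <- e_g[ga_genes] + cfg$tissue_effect_log2
      e_e[ep_genes] <- e_e[ep_genes] + cfg$tissue_effect_log2
      e_e[zoox] <- .ZOOX_ABSENT_LOG2
      gs <- paste0(sp, "_G"); es <- paste0(sp, "_E")
      p1 <- make_pair(paste0(sp, ".GE"), e_g, e_e, gs, es, baseline, tip, cfg)
      p2 <- make_pair(paste0(sp, ".G"), e_g, e_ref, gs, "REF", baseline, tip, cfg)
      p3 <- make_pair(paste0(sp, ".E"), e_e, e_ref, es, "REF", baseline, tip, cfg)
      scans <- c(scans, p1$scans, p2$scans, p3$scans)
      design <- rbind(design, p1$design, p2$design, p3$design)
      tissue_samples <- rbind(tissue_samples,
                              data.frame(sample = c(gs, es), specimen = sp,
                                         tissue = c("G", "E"),
                                         stringsAsFactors = FALSE))
    }
    truth <- structure(list(
      tissue_direction = setNames(tissue_direction, probes),
      state_direction = setNames(state_direction, probes),
      true_tissue_log2fc = setNames(fc, probes)), class = "tissue_truth")
    list(scans = new_scan_set(scans, design),
         tissue_samples = tissue_samples, truth = truth)
  })
}
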