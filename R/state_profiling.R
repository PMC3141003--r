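## Batch and per-individual state contrasts, the support histogram, and the
## consensus ("Kern") gene-set rule.
##
## All contrasts are run on specimen profiles: each specimen's
## reference-normalized M profile (mean over its dye-swap arrays)
## contributes one observation. Every contrast is oriented
## symbiotic-minus-aposymbiotic, so a positive M always means higher in the
## symbiotic state and direction consistency across contrasts is simply
## sign agreement.

#' Collapse arrays to per-specimen profiles
#'
#' Each specimen's profile is the mean of the orientation-corrected M of its
#' arrays (normally a dye-swap pair). Specimens listed without any array
#' (e.g. the reference individual itself) get an all-zero profile with a
#' warning, since their expression relative to the reference is identically
#' zero.
#'
#' @param ma an `ma_set`.
#' @param specimens data.frame with columns `specimen` and `state`
#'   (`"SY"`/`"APO"`).
#' @return matrix probes x specimens.
#' @export
specimen_profiles <- function(ma, specimens) {
  stopifnot(inherits(ma, "ma_set"))
  samples <- array_samples(ma$design)
  P <- matrix(NA_real_, nrow(ma$M), nrow(specimens),
              dimnames = list(rownames(ma$M), specimens$specimen))
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens$specimen[i]
    arr <- ma$design$array_id[samples == sp]
    arr <- intersect(arr, colnames(ma$M))
    if (length(arr) == 0) {
      warning("specimen '", sp, "' has no arrays; using a zero profile ",
              "(reference individual)", call. = FALSE)
      P[, i] <- 0
    } else {
      if (length(arr) == 1)
        warning("specimen '", sp, "' has a single array (no dye-swap pair)",
                call. = FALSE)
      P[, i] <- rowMeans(ma$M[, arr, drop = FALSE], na.rm = TRUE)
    }
  }
  P
}

#' Run the batch and per-individual state contrasts
#'
#' One batch contrast (all symbiotic vs all aposymbiotic specimens) plus one
#' contrast per specimen against the opposing pooled batch, all oriented
#' symbiotic-minus-aposymbiotic. Variance-moderation hyperparameters are
#' estimated per contrast and the DE rule applied.
#'
#' @param ma an `ma_set` of reference-design arrays.
#' @param specimens data.frame with `specimen`, `state` in `"SY"`/`"APO"`.
#' @param prior_p,v0 passed to [moderated_stats()]. The default prior
#'   proportion of differentially expressed genes is 0.1 here (not the
#'   generic 0.01): a symbiosis-dedicated platform is enriched by design
#'   for genes that respond to the state contrast.
#' @param m_thresh,b_thresh passed to [call_de()].
#' @return list of class `state_contrasts`: `batch` and `individual` (named
#'   list per specimen), each with `fit`, `stats`, `call`; plus `profiles`
#'   and `specimens`.
#' @export
run_state_contrasts <- function(ma, specimens, prior_p = 0.1, v0 = "auto",
                                m_thresh = 0.59, b_thresh = 0) {
  if (!all(specimens$state %in% c("SY", "APO")))
    stop_arg("specimen states must be 'SY' or 'APO'")
  if (length(unique(specimens$state)) < 2)
    stop_arg("need at least one specimen per state")
  P <- suppressWarnings(specimen_profiles(ma, specimens))
  ## array-level observation matrix with specimen blocks; specimens without
  ## arrays (the reference individual) contribute one exact-zero pseudo
  ## observation
  samples <- array_samples(ma$design)
  obs <- ma$M[, ma$design$array_id[samples %in% specimens$specimen],
              drop = FALSE]
  obs_block <- samples[match(colnames(obs), ma$design$array_id)]
  missing_sp <- setdiff(specimens$specimen, obs_block)
  if (length(missing_sp) > 0) {
    zero <- matrix(0, nrow(obs), length(missing_sp),
                   dimnames = list(rownames(obs),
                                   paste0(missing_sp, "__ref")))
    obs <- cbind(obs, zero)
    obs_block <- c(obs_block, missing_sp)
  }
  arrays_of <- function(sp) colnames(obs)[obs_block %in% sp]
  sy <- specimens$specimen[specimens$state == "SY"]
  apo <- specimens$specimen[specimens$state == "APO"]
  one <- function(a_specs, b_specs, label) {
    oa <- arrays_of(a_specs); ob <- arrays_of(b_specs)
    des <- contrast_design(c(oa, ob),
                           group = rep(c("A", "B"),
                                       c(length(oa), length(ob))),
                           block = obs_block[match(c(oa, ob),
                                                   colnames(obs))],
                           label = label)
    fit <- fit_gene_contrast(obs, des)
    st <- if (all(is.na(fit$s2) | fit$s2 < 1e-12)) {
      ## degenerate (noise-free) data: no residual variance anywhere, so
      ## the log-odds gate reduces to "any nonzero contrast"
      structure(data.frame(probe_id = fit$probe_id, m = fit$m,
                           s2_post = 0, t = sign(fit$m) * Inf,
                           df_total = fit$df,
                           b = ifelse(!is.na(fit$m) & fit$m != 0, Inf, -Inf),
                           stringsAsFactors = FALSE),
                label = label, class = c("moderated_stats", "data.frame"))
    } else {
      moderated_stats(fit, estimate_hyperparameters(fit),
                      prior_p = prior_p, v0 = v0)
    }
    list(fit = fit, stats = st,
         call = call_de(st, m_thresh = m_thresh, b_thresh = b_thresh))
  }
  batch <- one(sy, apo, "batch")
  indiv <- list()
  for (sp in specimens$specimen) {
    st <- specimens$state[specimens$specimen == sp]
    indiv[[sp]] <- if (st == "SY") one(sp, apo, sp) else one(sy, sp, sp)
  }
  structure(list(batch = batch, individual = indiv, profiles = P,
                 specimens = specimens),
            class = "state_contrasts")
}

#' Per-gene individual support counts and histogram
#'
#' For every batch-called gene, counts the individual contrasts in which the
#' gene is called with the same direction as the batch call
#' (opposite-direction individual calls do not count).
#'
#' @param contrasts a `state_contrasts` object (or a list with `batch` and
#'   `individual` de_call tables).
#' @return list of class `support_table`: `support` data.frame (`probe_id`,
#'   `batch_call` as `SY`/`APO`/`none`, `batch_m`, `batch_b`, `n_support`)
#'   and `histogram` (counts over 0..n individuals for batch-called genes).
#' @export
support_histogram <- function(contrasts) {
  bc <- if (is.data.frame(contrasts$batch)) contrasts$batch
        else contrasts$batch$call
  ind <- lapply(contrasts$individual, function(x)
    if (is.data.frame(x)) x else x$call)
  for (tab in ind)
    if (!identical(tab$probe_id, bc$probe_id))
      stop_arg("individual contrasts must share the batch probe set")
  calls <- vapply(ind, function(tab) tab$call, character(nrow(bc)))
  n_support <- rowSums(calls == bc$call) * (bc$call != "none")
  batch_call <- c(up = "SY", down = "APO", none = "none")[bc$call]
  support <- data.frame(probe_id = bc$probe_id, batch_call = batch_call,
                        batch_m = bc$m, batch_b = bc$b,
                        n_support = as.integer(n_support),
                        row.names = NULL, stringsAsFactors = FALSE)
  n_ind <- length(ind)
  hist <- table(factor(support$n_support[support$batch_call != "none"],
                       levels = 0:n_ind))
  structure(list(support = support, histogram = hist, n_individuals = n_ind),
            class = "support_table")
}

#' Select the consensus ("Kern") gene set
#'
#' Keeps the batch-called genes of cnidarian origin that are supported by at
#' least `min_support` of the `n_individuals` individual contrasts, sorted
#' by absolute batch M descending within direction (SY block first).
#'
#' @param support a `support_table` (or its `support` data.frame).
#' @param annotation probe annotation with `probe_id` and `origin`; genes
#'   missing from it are excluded with a warning.
#' @param min_support minimum direction-consistent individual calls,
#'   default 8.
#' @param n_individuals number of individual contrasts the support was
#'   computed over, default 11.
#' @return data.frame of class `kern_table`: `probe_id`, `direction`
#'   (`SY`/`APO`), `n_support`, `batch_m`, `batch_b`, plus `name`/`role`
#'   columns when the annotation carries them.
#' @export
select_kern <- function(support, annotation, min_support = 8,
                        n_individuals = 11) {
  s <- if (inherits(support, "support_table")) {
    if (support$n_individuals != n_individuals)
      stop_arg("support was computed over ", support$n_individuals,
               " individuals, not ", n_individuals)
    support$support
  } else support
  cand <- s[s$batch_call != "none" & s$n_support >= min_support, ,
            drop = FALSE]
  miss <- setdiff(cand$probe_id, annotation$probe_id)
  if (length(miss) > 0) {
    warning(length(miss), " candidate gene(s) missing from the annotation; ",
            "excluded", call. = FALSE)
    cand <- cand[!cand$probe_id %in% miss, , drop = FALSE]
  }
  ann <- annotation[match(cand$probe_id, annotation$probe_id), , drop = FALSE]
  keep <- !is.na(ann$origin) & ann$origin == "cnidarian"
  cand <- cand[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  out <- data.frame(probe_id = cand$probe_id, direction = cand$batch_call,
                    n_support = cand$n_support, batch_m = cand$batch_m,
                    batch_b = cand$batch_b, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (col in c("name", "role"))
    if (col %in% names(ann)) out[[col]] <- ann[[col]]
  out <- out[order(match(out$direction, c("SY", "APO")), -abs(out$batch_m)), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, min_support = min_support, n_individuals = n_individuals,
            class = c("kern_table", "data.frame"))
}
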