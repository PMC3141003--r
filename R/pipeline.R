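## End-to-end orchestration: simulate -> preprocess -> state contrasts ->
## consensus selection -> tissue assignment -> qPCR -> enrichment, with a
## run manifest recording seeds, parameters and output hashes.

#' Write / read a normalized MA table in long format
#'
#' Long TSV columns: array_id, probe_id, M, A, print_tip_group.
#'
#' @param ma an `ma_set`.
#' @param path TSV path.
#' @param design design data.frame to attach on read.
#' @return `write_ma_table` the path invisibly; `read_ma_table` an
#'   `ma_set`.
#' @export
write_ma_table <- function(ma, path) {
  long <- data.frame(
    array_id = rep(colnames(ma$M), each = nrow(ma$M)),
    probe_id = rep(rownames(ma$M), ncol(ma$M)),
    M = as.vector(ma$M), A = as.vector(ma$A),
    print_tip_group = rep(ma$print_tip, ncol(ma$M)),
    stringsAsFactors = FALSE)
  write_tsv(long, path)
}

#' @rdname write_ma_table
#' @export
read_ma_table <- function(path, design) {
  long <- read_tsv(path)
  arrays <- unique(long$array_id)
  probes <- unique(long$probe_id)
  M <- A <- matrix(NA_real_, length(probes), length(arrays),
                   dimnames = list(probes, arrays))
  i <- cbind(match(long$probe_id, probes), match(long$array_id, arrays))
  M[i] <- long$M; A[i] <- long$A
  tip <- long$print_tip_group[match(probes, long$probe_id)]
  structure(list(M = M, A = A, print_tip = tip, design = design),
            class = "ma_set")
}

#' Pipeline run configuration
#'
#' All tunable constants of the pipeline in one place: the DE rule
#' (|M| > 0.59 i.e. 1.5-fold, B > 0), the consensus support threshold
#' (8 of 11 individuals), the tissue threshold (0.59 in both designs), the
#' background offset (50), and the enrichment alpha (0.05).
#'
#' @param out_dir output directory.
#' @param seed global seed; stage substreams are derived by fixed offsets.
#' @param n_probes,n_planted_sy,n_planted_apo,effect_log2,activity_prob,noise_sd
#'   synthetic state-experiment parameters (see [state_sim_config()]).
#' @param m_thresh,b_thresh,min_support,tissue_thresh,alpha,offset analysis
#'   thresholds.
#' @param between between-array normalization method.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("symbiokern_run"), seed = 1,
                       n_probes = 600, n_planted_sy = 30, n_planted_apo = 40,
                       effect_log2 = 1.5, activity_prob = 0.9,
                       noise_sd = 0.3, m_thresh = 0.59, b_thresh = 0,
                       min_support = 8, tissue_thresh = 0.59, alpha = 0.05,
                       offset = 50, between = "aquantile") {
  structure(as.list(environment()), class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, preprocess, differential expression, consensus
#' selection, clustering, tissue assignment, qPCR quantification and GO
#' enrichment, writing every stage's table under `config$out_dir` together
#' with a run manifest. Reruns with identical seeds produce byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return list of class `run_result` with the in-memory stage results and
#'   the `manifest` data.frame.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))

  n_zoox <- max(round(config$n_probes * 0.1), 1)
  n_prok <- max(round(config$n_probes * 0.04), 1)
  n_cnid <- config$n_probes - n_zoox - n_prok
  annotation <- run_stage("simulate", generate_annotation(
    n_cnid, n_zoox, n_prok, go_terms_per_gene = 2, seed = config$seed))
  scfg <- state_sim_config(n_probes = config$n_probes,
                           n_planted_sy = config$n_planted_sy,
                           n_planted_apo = config$n_planted_apo,
                           effect_log2 = config$effect_log2,
                           activity_prob = config$activity_prob,
                           noise_sd = config$noise_sd, seed = config$seed)
  sim <- run_stage("simulate", generate_state_experiment(scfg, annotation))
  log_stage("simulate", config$n_probes, length(sim$scans$scans))

  host <- annotation$probe_id[annotation$origin == "cnidarian"]
  ma <- run_stage("preprocess", {
    bc <- background_correct(sim$scans, offset = config$offset)
    m <- compute_ma(bc)
    m <- normalize_within_array(m, fit_probes = host)
    normalize_between_arrays(m, method = config$between)
  })
  write_ma_table(ma, file.path(config$out_dir, "normalized_ma.tsv"))
  log_stage("preprocess", length(sim$scans$scans), ncol(ma$M))

  contrasts <- run_stage("de", run_state_contrasts(
    ma, sim$specimens, m_thresh = config$m_thresh,
    b_thresh = config$b_thresh))
  support <- run_stage("kern", support_histogram(contrasts))
  kern <- run_stage("kern", select_kern(
    support, annotation, min_support = config$min_support,
    n_individuals = nrow(sim$specimens)))
  if (nrow(kern) == 0)
    warning("consensus selection is empty at min_support = ",
            config$min_support, call. = FALSE)
  write_tsv(as.data.frame(kern), file.path(config$out_dir, "kern.tsv"))
  write_tsv(data.frame(n_support = names(support$histogram),
                       n_genes = as.integer(support$histogram)),
            file.path(config$out_dir, "support_histogram.tsv"))
  log_stage("kern", sum(support$support$batch_call != "none"), nrow(kern))

  called <- support$support$batch_call != "none"
  dendro <- if (sum(called) >= 2) {
    d <- run_stage("cluster", cluster_specimens(
      contrasts$profiles[called, , drop = FALSE], linkage = "average"))
    dendrogram_newick(d, file.path(config$out_dir, "dendrogram.nwk"))
    d
  } else NULL

  tcfg <- tissue_sim_config(n_probes = config$n_probes,
                            noise_sd = config$noise_sd, seed = config$seed)
  tsim <- run_stage("tissue", generate_tissue_experiment(tcfg, annotation))
  tma <- run_stage("tissue", {
    bc <- background_correct(tsim$scans, offset = config$offset)
    normalize_within_array(compute_ma(bc), fit_probes = host)
  })
  tissue <- run_stage("tissue", {
    dir_c <- direct_tissue_contrast(tma, tsim$tissue_samples)
    tr_c <- transitive_tissue_contrast(tma, tsim$tissue_samples)
    assign_tissue(dir_c$m_direct, tr_c$m_trans,
                  thresh = config$tissue_thresh)
  })
  sy_set <- support$support$probe_id[support$support$batch_call == "SY"]
  apo_set <- support$support$probe_id[support$support$batch_call == "APO"]
  venn <- run_stage("tissue", venn_cross_classification(
    tissue, sy_set, apo_set, annotation))
  write_tsv(as.data.frame(tissue), file.path(config$out_dir,
                                             "tissue_calls.tsv"))
  write_tsv(as.data.frame(venn$counts),
            file.path(config$out_dir, "venn_counts.tsv"))
  log_stage("tissue", nrow(tissue), sum(tissue$call != "none"))

  qres <- run_stage("qpcr", {
    qcfg <- qpcr_sim_config(seed = config$seed)
    qd <- generate_qpcr_dataset(qcfg)
    curves <- fit_standard_curves(qd$qpcr)
    cq <- summarize_replicates(qd$qpcr[qd$qpcr$role == "unknown", ,
                                       drop = FALSE])
    ratios <- symbiont_host_ratio(cq, curves, qcfg$symbiont_loci,
                                  qcfg$host_loci, calibrator = "Sy1")
    ref <- summarize_replicates(qd$qpcr[qd$qpcr$role == "reference", ,
                                        drop = FALSE])
    qm <- matrix(NA_real_, length(unique(ref$sample)),
                 length(unique(ref$assay)),
                 dimnames = list(unique(ref$sample), unique(ref$assay)))
    qm[cbind(match(ref$sample, rownames(qm)),
             match(ref$assay, colnames(qm)))] <- ref$cq
    quant <- relative_quantities(qm, 2)
    stab <- gene_stability(quant, panel_size = 3)
    nf <- normalization_factor(quant[, stab$panel, drop = FALSE])
    tg <- summarize_replicates(qd$qpcr[qd$qpcr$role == "target", ,
                                       drop = FALSE])
    expr <- lapply(split(tg, tg$assay), function(d)
      relative_expression(setNames(d$cq, d$sample), nf, efficiency = 2,
                          calibrator = "AS6"))
    tc <- timecourse_fold(summarize_replicates(qd$timecourse),
                          targets = qcfg$timecourse_targets)
    list(curves = curves, ratios = ratios, stability = stab, nf = nf,
         expression = expr, timecourse = tc, truth = qd$truth)
  })
  write_tsv(data.frame(locus = names(qres$curves),
                       slope = vapply(qres$curves, `[[`, 0, "slope"),
                       intercept = vapply(qres$curves, `[[`, 0, "intercept"),
                       efficiency = vapply(qres$curves, `[[`, 0,
                                           "efficiency"),
                       r2 = vapply(qres$curves, `[[`, 0, "r2")),
            file.path(config$out_dir, "curves.tsv"))
  write_tsv(qres$ratios$pairs, file.path(config$out_dir, "copy_ratios.tsv"))
  write_tsv(data.frame(gene = names(qres$stability$m_values),
                       m = qres$stability$m_values,
                       in_panel = names(qres$stability$m_values) %in%
                         qres$stability$panel),
            file.path(config$out_dir, "stability.tsv"))
  expr_df <- do.call(rbind, lapply(names(qres$expression), function(g)
    data.frame(assay = g, sample = names(qres$expression[[g]]),
               fold = as.numeric(qres$expression[[g]]),
               stringsAsFactors = FALSE)))
  write_tsv(expr_df, file.path(config$out_dir, "expression.tsv"))
  write_tsv(qres$timecourse$summary,
            file.path(config$out_dir, "timecourse.tsv"))
  log_stage("qpcr", nrow(qres$ratios$pairs), nrow(expr_df))

  enr <- run_stage("enrich", {
    sy_c <- intersect(sy_set,
                      annotation$probe_id[annotation$origin == "cnidarian"])
    apo_c <- intersect(apo_set,
                       annotation$probe_id[annotation$origin == "cnidarian"])
    if (length(sy_c) == 0 || length(apo_c) == 0) {
      warning("empty state gene set; skipping enrichment", call. = FALSE)
      NULL
    } else fisher_term_enrichment(sy_c, apo_c, annotation)
  })
  if (!is.null(enr))
    write_tsv(as.data.frame(enr), file.path(config$out_dir,
                                            "enrichment.tsv"))

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.tsv"]
  manifest <- data.frame(
    key = c("seed", "n_probes", "m_thresh", "b_thresh", "min_support",
            "tissue_thresh", "offset", basename(outputs)),
    value = c(config$seed, config$n_probes, config$m_thresh,
              config$b_thresh, config$min_support, config$tissue_thresh,
              config$offset, vapply(outputs, hash_file, character(1))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  structure(list(annotation = annotation, simulation = sim, ma = ma,
                 contrasts = contrasts, support = support, kern = kern,
                 dendrogram = dendro, tissue = tissue, venn = venn,
                 qpcr = qres, enrichment = enr, manifest = manifest,
                 config = config),
            class = "run_result")
}
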