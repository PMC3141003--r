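# Standard curves, quantification, ratios, stability, normalization and
# expression folds.

test_that("standard curves: closed forms, diagnostics and guards", {
  lg <- 6:1
  # perfect doubling: slope = -1/log10(2), E = 2
  curve <- fit_standard_curve(lg, 30 - lg / log10(2), "perfect")
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(curve$efficiency, 2, tolerance = 1e-12)
  expect_equal(curve$r2, 1)
  # slope -3.9 -> E = 10^(1/3.9)
  c2 <- fit_standard_curve(lg, 40 - 3.9 * lg, "slow")
  expect_equal(c2$efficiency, 10^(1 / 3.9), tolerance = 1e-12)

  expect_error(fit_standard_curve(c(1, 2), c(30, 28)), "3 distinct")
  expect_error(fit_standard_curve(lg, 20 + lg), "negative")
  expect_warning(fit_standard_curve(lg, 38 - 3.3 * lg + c(2, -2, 1, -1, 2, -2),
                                    "noisy"), "r2")
})

test_that("efficiency recovery from noisy series stays within 0.05", {
  set.seed(51)
  for (rep in 1:100) {
    E <- runif(1, 1.8, 2)
    slope <- -1 / log10(E)
    lg <- rep(6:1, each = 3)
    cq <- 38 + slope * lg + rnorm(length(lg), 0, 0.1)
    fit <- fit_standard_curve(lg, cq, "sim")
    expect_lt(abs(fit$efficiency - E), 0.05)
  }
})

test_that("copy quantification inverts the curve", {
  curve <- fit_standard_curve(6:1, 38 - (6:1) / log10(2), "c")
  expect_equal(as.numeric(quantify_copies(curve$intercept, curve)), 1,
               tolerance = 1e-9)
  expect_equal(as.numeric(quantify_copies(curve$intercept + curve$slope,
                                          curve)), 10, tolerance = 1e-9)
  for (copies in c(10, 1e4, 1e7)) {
    cq <- curve$intercept + curve$slope * log10(copies)
    expect_equal(as.numeric(quantify_copies(cq, curve)), copies,
                 tolerance = 1e-6 * copies)
  }
  out <- quantify_copies(curve$intercept, curve)  # 1 copy, below series
  expect_true(attr(out, "extrapolated"))
})

test_that("symbiont:host ratios are calibrator-normalized and exact", {
  qcfg <- qpcr_sim_config(planted_ratio = c(Sy1 = 1, AS4 = 8.2e-2,
                                            AS6 = 1e-4),
                          cq_noise_sd = 0, seed = 52)
  qd <- generate_qpcr_dataset(qcfg)
  curves <- fit_standard_curves(qd$qpcr)
  cq <- summarize_replicates(qd$qpcr[qd$qpcr$role == "unknown", ])
  res <- symbiont_host_ratio(cq, curves, qcfg$symbiont_loci,
                             qcfg$host_loci, calibrator = "Sy1")
  cal <- res$pairs[res$pairs$specimen == "Sy1", ]
  expect_true(all(abs(cal$ratio_rel - 1) < 1e-9))
  cons <- setNames(res$consensus$ratio_rel, res$consensus$specimen)
  expect_equal(unname(cons["AS4"]), 8.2e-2, tolerance = 1e-6)
  expect_equal(unname(cons["AS6"]), 1e-4, tolerance = 1e-6)
  expect_error(symbiont_host_ratio(cq, curves, qcfg$symbiont_loci,
                                   qcfg$host_loci, "nope"), "calibrator")
})

test_that("ratio scale behavior under one-sided copy rescaling", {
  qcfg <- qpcr_sim_config(cq_noise_sd = 0, seed = 53)
  qd <- generate_qpcr_dataset(qcfg)
  curves <- fit_standard_curves(qd$qpcr)
  cq <- summarize_replicates(qd$qpcr[qd$qpcr$role == "unknown", ])
  base <- symbiont_host_ratio(cq, curves, qcfg$symbiont_loci,
                              qcfg$host_loci, "Sy1")
  # tripling all host copies: every host Cq drops by log(3)/log(E)
  cq3 <- cq
  for (l in qcfg$host_loci) {
    sel <- cq3$assay == l
    cq3$cq[sel] <- cq3$cq[sel] - log(3) / log(curves[[l]]$efficiency)
  }
  scaled <- symbiont_host_ratio(cq3, curves, qcfg$symbiont_loci,
                                qcfg$host_loci, "Sy1")
  expect_equal(scaled$pairs$ratio, base$pairs$ratio / 3, tolerance = 1e-6)
  expect_equal(scaled$pairs$ratio_rel, base$pairs$ratio_rel,
               tolerance = 1e-6)
})

test_that("undetermined symbiont reactions report a detection limit", {
  qcfg <- qpcr_sim_config(planted_ratio = c(Sy1 = 1, AS9 = 0),
                          cq_noise_sd = 0, seed = 54)
  qd <- generate_qpcr_dataset(qcfg)
  curves <- fit_standard_curves(qd$qpcr)
  cq <- summarize_replicates(qd$qpcr[qd$qpcr$role == "unknown", ])
  res <- symbiont_host_ratio(cq, curves, qcfg$symbiont_loci,
                             qcfg$host_loci, "Sy1")
  blank <- res$pairs[res$pairs$specimen == "AS9", ]
  expect_true(all(blank$below_detection))
  expect_true(all(is.na(blank$ratio)))
  expect_true(all(blank$detection_limit > 0))
})

test_that("locus-ratio diagnostics flag planted amplification", {
  qcfg <- qpcr_sim_config(cq_noise_sd = 0, seed = 55,
                          locus_scale = c(EF2 = 5, SPS = 1, APX = 1,
                                          `COP-g` = 1, RCC2 = 1, NPC1 = 1))
  qd <- generate_qpcr_dataset(qcfg)
  curves <- fit_standard_curves(qd$qpcr)
  cq <- summarize_replicates(qd$qpcr[qd$qpcr$role == "unknown", ])
  diag <- locus_ratio_diagnostics(cq, curves, c("EF2", "SPS", "APX"))
  ef2 <- diag[diag$locus_a == "EF2", ]
  expect_true(all(ef2$flagged))
  expect_true(all(abs(ef2$ratio - 5) < 1e-6))
  other <- diag[diag$locus_a == "SPS" & diag$locus_b == "APX", ]
  expect_true(all(!other$flagged))
  expect_true(all(abs(other$ratio - 1) < 1e-6))
  # host loci sit at ~1:1
  hd <- locus_ratio_diagnostics(cq, curves, qcfg$host_loci)
  expect_true(all(!hd$flagged))
  expect_error(locus_ratio_diagnostics(cq, curves, "EF2"), "2 loci")
})

test_that("geNorm stability matches the naive pairwise oracle", {
  set.seed(56)
  q <- matrix(2^rnorm(8 * 5, 10, 1), 8, 5,
              dimnames = list(NULL, letters[1:5]))
  st <- gene_stability(q, panel_size = 3)
  # explicit double loop over gene pairs
  for (j in colnames(q)) {
    ms <- vapply(setdiff(colnames(q), j), function(k)
      sd(log2(q[, j] / q[, k])), numeric(1))
    expect_equal(unname(st$m_values[j]), mean(ms), tolerance = 1e-12)
  }
  # two proportional genes + one scattered: scattered excluded first
  base <- 2^rnorm(6, 8, 1)
  q2 <- cbind(s1 = base, s2 = base * 2, noisy = base * 2^rnorm(6, 0, 1))
  st2 <- gene_stability(q2, panel_size = 2)
  expect_equal(st2$exclusion_order[1], "noisy")
  expect_setequal(st2$panel, c("s1", "s2"))
  # all genes constant: all M = 0
  st3 <- gene_stability(matrix(1, 4, 3), panel_size = 3)
  expect_true(all(st3$m_values == 0))
  expect_error(gene_stability(q[, 1:2]), "3 candidate")
  expect_error(gene_stability(-q), "positive")
})

test_that("normalization factors are geometric means", {
  q <- rbind(s1 = c(1, 4, 16), s2 = c(2, 8, 32))
  expect_equal(unname(normalization_factor(q)), c(4, 8))
  expect_equal(unname(normalization_factor(q * 2)),
               c(8, 16))                      # homogeneity
  expect_equal(unname(normalization_factor(q[, 1, drop = FALSE])),
               c(1, 2))                       # single-gene panel
  expect_error(normalization_factor(q * 0), "positive")
})

test_that("relative expression recovers planted folds exactly", {
  qcfg <- qpcr_sim_config(cq_noise_sd = 0, seed = 57)
  qd <- generate_qpcr_dataset(qcfg)
  ref <- summarize_replicates(qd$qpcr[qd$qpcr$role == "reference", ])
  samples <- unique(ref$sample)
  qm <- matrix(NA_real_, length(samples), length(unique(ref$assay)),
               dimnames = list(samples, unique(ref$assay)))
  qm[cbind(match(ref$sample, rownames(qm)),
           match(ref$assay, colnames(qm)))] <- ref$cq
  quant <- relative_quantities(qm, 2)
  stab <- gene_stability(quant, panel_size = 3)
  expect_equal(stab$exclusion_order[1], qd$truth$unstable_gene)
  nf <- normalization_factor(quant[, stab$panel, drop = FALSE])
  tg <- summarize_replicates(qd$qpcr[qd$qpcr$role == "target" &
                                       qd$qpcr$assay == "NPC2-D", ])
  fold <- relative_expression(setNames(tg$cq, tg$sample), nf,
                              efficiency = 2, calibrator = "AS6")
  expect_equal(unname(fold["AS6"]), 1)
  expect_equal(unname(fold["Sy1"]), 4.6, tolerance = 1e-9)
  # one cycle is one doubling when the normalization is flat
  nf1 <- setNames(rep(1, 2), c("AS6", "x"))
  f2 <- relative_expression(c(AS6 = 25, x = 24), nf1, efficiency = 2)
  expect_equal(unname(f2["x"]), 2)
  expect_error(relative_expression(c(x = 24), nf1, calibrator = "AS6"),
               "calibrator")
})

test_that("time-course folds: identity, planted drop, and Cq-shift invariance", {
  qcfg <- qpcr_sim_config(cq_noise_sd = 0, timecourse_drop = 3, seed = 58)
  qd <- generate_qpcr_dataset(qcfg)
  cq <- summarize_replicates(qd$timecourse)
  tc <- timecourse_fold(cq, targets = qcfg$timecourse_targets)
  s <- tc$summary
  expect_true(all(abs(s$fold[s$time == 0] - 1) < 1e-9))
  expect_true(all(abs(s$fold[s$time > 0] - 1 / 3) < 1e-9))
  # a constant Cq shift on one sample's assays is absorbed by the NF
  cq2 <- cq
  sel <- cq2$specimen == "Sy3" & cq2$time == 24
  cq2$cq[sel] <- cq2$cq[sel] + 2.5
  tc2 <- timecourse_fold(cq2, targets = qcfg$timecourse_targets)
  expect_equal(tc2$summary$fold, tc$summary$fold, tolerance = 1e-9)
  # missing t0 drops the specimen with a warning
  expect_warning(
    timecourse_fold(cq[!(cq$specimen == "Sy3" & cq$time == 0), ],
                    targets = "CA2-c"), "t0")
})

test_that("noisy time course recovers the planted drop within 10%", {
  qcfg <- qpcr_sim_config(cq_noise_sd = 0.1, timecourse_drop = 3, seed = 59)
  qd <- generate_qpcr_dataset(qcfg)
  tc <- timecourse_fold(summarize_replicates(qd$timecourse),
                        targets = qcfg$timecourse_targets)
  s <- tc$summary
  expect_true(all(abs(s$fold[s$time > 0] * 3 - 1) < 0.1))
})

test_that("replicate summaries flag discordant wells", {
  q <- data.frame(sample = "s", assay = c("a", "a", "a", "b", "b", "b"),
                  role = "target",
                  replicate = rep(1:3, 2),
                  cq = c(25, 25.1, 24.9, 25, 26.4, 23.9))
  out <- summarize_replicates(q)
  expect_equal(out$flagged[out$assay == "a"], FALSE)
  expect_equal(out$flagged[out$assay == "b"], TRUE)
})
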