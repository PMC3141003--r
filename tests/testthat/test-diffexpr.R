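# Contrast fitting, empirical-Bayes hyperparameters, moderated t and B,
# and the DE call rule.

mk_fit <- function(m, s2, df, se_scale = 1) {
  structure(data.frame(probe_id = sprintf("g%03d", seq_along(m)),
                       m = m, s2 = s2, df = df, n_used = df + 1,
                       se_scale = se_scale, stringsAsFactors = FALSE),
            class = c("gene_fit", "data.frame"))
}

test_that("fit_gene_contrast matches hand-computed examples", {
  M <- rbind(g1 = c(1, 1, 1, 1),
             g2 = c(0.8, -0.8, 0.8, -0.8),
             g3 = c(0.5, 0.7, 0.9, NA))
  colnames(M) <- paste0("a", 1:4)

  fit <- fit_gene_contrast(M, contrast_design(paste0("a", 1:4)))
  expect_equal(fit$m[1], 1); expect_equal(fit$s2[1], 0)
  expect_equal(fit$df[1], 3)

  # dye-swap pair, raw signs uncorrected -> coef fixes orientation
  swp <- fit_gene_contrast(M[, 1:2], contrast_design(c("a1", "a2"),
                                                     coef = c(1, -1)))
  expect_equal(swp$m[2], 0.8)

  # mean / variance / df with a missing value dropped gene-wise
  expect_equal(fit$m[3], 0.7)
  expect_equal(fit$s2[3], 0.04)
  expect_equal(fit$df[3], 2)

  expect_error(fit_gene_contrast(M, contrast_design("zz")), "absent")
  expect_error(contrast_design("a1", coef = 0), "nonzero")
})

test_that("two-group and blocked fits use the right residuals", {
  # two specimens x dye-swap pairs per group; block residual = within-pair
  M <- rbind(g1 = c(2.1, 1.9, 1.2, 0.8, 0.1, -0.1, 0.05, -0.05))
  obs <- paste0("a", 1:8)
  colnames(M) <- obs
  block <- c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s4")
  grp <- rep(c("A", "B"), each = 4)
  fit <- fit_gene_contrast(M, contrast_design(obs, group = grp,
                                              block = block))
  expect_equal(fit$m[1], (2 + 1) / 2 - 0)          # block means: 2,1,0,0
  expect_equal(fit$df[1], 4)                        # 8 obs - 4 blocks
  within_ss <- 2 * 0.1^2 + 2 * 0.2^2 + 2 * 0.1^2 + 2 * 0.05^2
  expect_equal(fit$s2[1], within_ss / 4)
  expect_equal(fit$se_scale[1], sqrt(1 / 4 * (1 / 2 + 1 / 2) +
                                       1 / 4 * (1 / 2 + 1 / 2)))

  # unblocked two-group pooled variance
  fit2 <- fit_gene_contrast(M, contrast_design(obs, group = grp))
  expect_equal(fit2$df[1], 6)
  expect_equal(fit2$m[1], 1.5 - 0)
})

test_that("hyperparameter estimation recovers known variance priors", {
  set.seed(21)
  df <- 4
  # all genes share s0^2: chi-square draws, d0 -> large
  s2 <- 0.09 * rchisq(10000, df) / df
  h <- estimate_hyperparameters(mk_fit(0, s2, df))
  expect_lt(abs(h$s0_2 - 0.09) / 0.09, 0.05)
  expect_true(is.infinite(h$d0) || h$d0 > 20)

  # heterogeneous variances from a scaled inverse chi-square with d0 = 4
  d0 <- 4; s0_2 <- 0.05
  true_var <- d0 * s0_2 / rchisq(10000, d0)
  s2h <- true_var * rchisq(10000, df) / df
  h2 <- estimate_hyperparameters(mk_fit(0, s2h, df))
  expect_lt(abs(h2$d0 - 4) / 4, 0.25)
  expect_lt(abs(h2$s0_2 - s0_2) / s0_2, 0.2)

  expect_error(estimate_hyperparameters(mk_fit(0, rep(0.1, 10), 4)),
               "at least 50")
  expect_error(estimate_hyperparameters(mk_fit(0, rep(0, 100), 4)),
               "zero")
})

test_that("hyperparameters agree with the reference implementation", {
  set.seed(22)
  s2 <- (4 * 0.04 / rchisq(3000, 4)) * rchisq(3000, 6) / 6
  h <- estimate_hyperparameters(mk_fit(0, s2, 6))
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(h$d0, ref$df2, tolerance = 0.05)
  expect_equal(h$s0_2, ref$scale, tolerance = 0.05)
})

test_that("moderated t limits: no shrinkage at d0 = 0, full at d0 = Inf", {
  set.seed(23)
  fits <- mk_fit(rnorm(300), 0.05 * rchisq(300, 4) / 4, 4, se_scale = 0.5)
  inf <- moderated_stats(fits, list(d0 = Inf, s0_2 = 0.05), v0 = 1)
  expect_equal(inf$t, fits$m / (sqrt(0.05) * 0.5), tolerance = 1e-12)
  zero <- moderated_stats(fits, list(d0 = 0, s0_2 = 0.05), v0 = 1)
  expect_equal(zero$t, fits$m / (sqrt(fits$s2) * 0.5), tolerance = 1e-12)
  expect_error(moderated_stats(fits, list(d0 = 4, s0_2 = 0.05),
                               prior_p = 1.5), "prior_p")
})

test_that("B equals an independent density-ratio evaluation", {
  set.seed(24)
  fits <- mk_fit(rnorm(200, 0, 1), 0.06 * rchisq(200, 5) / 5, 5,
                 se_scale = 0.6)
  hyper <- estimate_hyperparameters(fits)
  st <- moderated_stats(fits, hyper, prior_p = 0.05, v0 = 2)
  # independent route: posterior odds as a ratio of scaled-t densities
  r <- (2 + 0.6^2) / 0.6^2
  nu <- st$df_total
  b_oracle <- log(0.05 / 0.95) +
    log(stats::dt(st$t / sqrt(r), nu) / sqrt(r)) - log(stats::dt(st$t, nu))
  expect_equal(st$b, b_oracle, tolerance = 1e-8)
})

test_that("moderated statistics match limma on a shared fit", {
  set.seed(25)
  fits <- mk_fit(rnorm(500, 0, 0.8), 0.07 * rchisq(500, 6) / 6, 6,
                 se_scale = 0.5)
  hyper <- estimate_hyperparameters(fits)
  st <- moderated_stats(fits, hyper, prior_p = 0.01, v0 = "auto")
  sq <- limma::squeezeVar(fits$s2, df = 6)
  expect_equal(st$s2_post,
               (hyper$d0 * hyper$s0_2 + 6 * fits$s2) / (hyper$d0 + 6),
               tolerance = 1e-12)
  expect_equal(st$s2_post, sq$var.post, tolerance = 0.02)
  expect_equal(cor(st$t, fits$m / (sqrt(sq$var.post) * 0.5)), 1,
               tolerance = 1e-4)
})

test_that("the DE call rule is strict on both gates", {
  st <- structure(
    data.frame(probe_id = c("irf1", "edge", "bgate", "up"),
               m = c(-0.63, 0.59, 2.0, 0.60),
               s2_post = 0.1, t = 1, df_total = 5,
               b = c(1.15, 5, -0.1, 0.2)),
    class = c("moderated_stats", "data.frame"))
  calls <- call_de(st)
  expect_equal(calls$call, c("down", "none", "none", "up"))
})

test_that("shrinkage and B-monotonicity invariants hold", {
  set.seed(26)
  s2 <- 0.08 * rchisq(400, 3) / 3
  fits <- mk_fit(rnorm(400), s2, 3)
  for (d0 in c(0, 2, 10)) {
    st <- moderated_stats(fits, list(d0 = d0, s0_2 = 0.08), v0 = 1)
    expect_true(all(abs(st$s2_post - 0.08) <= abs(fits$s2 - 0.08) + 1e-12))
    if (d0 == 0)
      expect_equal(st$s2_post, fits$s2, tolerance = 1e-12)
  }
  # B strictly increasing in t^2 at fixed df and v0
  tgrid <- seq(0.1, 30, length.out = 120)
  r <- (1 + 0.5^2) / 0.5^2
  bg <- symbiokern:::b_statistic(tgrid, rep(8, 120), r, 0.01)
  expect_true(all(diff(bg) > 0))
})

test_that("contrast fitting is linear in global M shifts", {
  set.seed(27)
  M <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("a", 1:6)))
  des <- contrast_design(paste0("a", 1:6),
                         group = rep(c("A", "B"), each = 3))
  f1 <- fit_gene_contrast(M, des)
  # shift only the A side so the contrast moves by exactly +c
  M2 <- M; M2[, 1:3] <- M2[, 1:3] + 0.7
  f2 <- fit_gene_contrast(M2, des)
  expect_equal(f2$m, f1$m + 0.7, tolerance = 1e-12)
  expect_equal(f2$s2, f1$s2, tolerance = 1e-12)
})

test_that("type-I control: null data yield < 1% batch calls", {
  nul <- null_state_experiment()
  frac <- mean(nul$contrasts$batch$call$call != "none")
  expect_lt(frac, 0.01)
})
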