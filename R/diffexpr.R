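## Per-gene contrast fitting and empirical-Bayes moderation.
##
## A contrast is fitted on an observation matrix (sign-corrected M values,
## one column per observation). Two layouts are supported:
##   * one-group: every observation estimates the same mean; Mhat is the
##     mean, the standard-error scale is 1/sqrt(n);
##   * two-group ("A" minus "B"): Mhat is the difference of group means with
##     pooled residual variance and scale sqrt(1/nA + 1/nB).
## Missing values are dropped gene-wise; genes left with fewer than 2 usable
## observations are flagged df = 0 rather than erroring.
##
## Moderation follows the standard hierarchical model for gene-wise
## variances: s2 ~ s0^2 * chisq_df/df given the true variance, with a
## scaled-inverse-chisq prior (d0, s0^2). The posterior variance
## s2_post = (d0 s0^2 + df s2)/(d0 + df) yields a moderated t on d0 + df
## degrees of freedom, and B is the log posterior odds of differential
## expression under a two-component normal model on the coefficient.

#' Build a contrast design
#'
#' @param obs observation (column) names of the contrast.
#' @param coef +1/-1 sign correction per observation (e.g. for dye-swap
#'   members whose M was not already orientation-corrected).
#' @param group optional `"A"`/`"B"` group labels; the contrast is A minus B.
#' @param block optional blocking factor (typically the specimen): each
#'   block's observations are technical replicates of one biological unit.
#'   With blocks, the contrast is computed on block means and the residual
#'   variance comes from within-block disagreement only (the dye-swap pair
#'   residual), so biological heterogeneity across a pooled batch does not
#'   inflate the per-gene variance.
#' @param label contrast label.
#' @return data.frame of class `contrast_design`.
#' @export
contrast_design <- function(obs, coef = 1, group = NULL, block = NULL,
                            label = "contrast") {
  coef <- rep_len(coef, length(obs))
  if (any(coef == 0)) stop_arg("contrast coefficients must be nonzero")
  d <- data.frame(obs = obs, coef = coef, stringsAsFactors = FALSE)
  if (!is.null(group)) {
    group <- rep_len(group, length(obs))
    if (!all(group %in% c("A", "B")))
      stop_arg("group labels must be 'A' or 'B'")
    d$group <- group
  }
  if (!is.null(block)) d$block <- rep_len(block, length(obs))
  attr(d, "label") <- label
  class(d) <- c("contrast_design", "data.frame")
  d
}

obs_matrix <- function(x) {
  if (inherits(x, "ma_set")) x$M
  else if (is.matrix(x)) x
  else stop_arg("expected an ma_set or a numeric matrix")
}

#' Fit a per-gene contrast
#'
#' @param x an `ma_set` (observations = arrays) or a probes-x-observations
#'   numeric matrix (e.g. specimen profiles).
#' @param design a [contrast_design()]; its `obs` must name columns of `x`.
#' @return data.frame of class `gene_fit`: `probe_id`, `m` (contrast
#'   estimate), `s2` (residual variance, NA when df = 0), `df`, `n_used`,
#'   `se_scale` (the c in se = s * c).
#' @export
fit_gene_contrast <- function(x, design) {
  M <- obs_matrix(x)
  if (!all(design$obs %in% colnames(M)))
    stop_arg("design refers to observations absent from the data: ",
             paste(setdiff(design$obs, colnames(M)), collapse = ", "))
  V <- sweep(M[, design$obs, drop = FALSE], 2, design$coef, `*`)
  ng <- nrow(V)
  blocks <- design$block %||% design$obs      # no blocking: 1 obs = 1 block
  group <- design$group %||% rep("A", nrow(design))
  ublk <- unique(blocks)
  ## per-block means, counts and within-block sums of squares (gene-wise
  ## NA dropping)
  bm <- bn <- matrix(0, ng, length(ublk), dimnames = list(NULL, ublk))
  ss <- rep(0, ng)
  for (b in seq_along(ublk)) {
    Vb <- V[, blocks == ublk[b], drop = FALSE]
    bn[, b] <- rowSums(!is.na(Vb))
    mb <- rowMeans(Vb, na.rm = TRUE)
    bm[, b] <- ifelse(bn[, b] > 0, mb, NA)
    ss <- ss + rowSums((Vb - mb)^2, na.rm = TRUE)
  }
  blk_group <- group[match(ublk, blocks)]
  est_group <- function(g) {
    sel <- blk_group == g
    used <- bn[, sel, drop = FALSE] > 0
    k <- rowSums(used)
    mean_g <- rowMeans(bm[, sel, drop = FALSE], na.rm = TRUE)
    mean_g[k == 0] <- NA
    ## Var(group mean of block means) = sigma^2/k^2 * sum_b 1/m_b
    v <- rowSums(ifelse(used, 1 / pmax(bn[, sel, drop = FALSE], 1), 0)) /
      pmax(k, 1)^2
    list(mean = mean_g, var_scale = v, k = k)
  }
  A <- est_group("A")
  if (any(blk_group == "B")) {
    B <- est_group("B")
    m <- A$mean - B$mean
    se2 <- A$var_scale + B$var_scale
    n_blocks <- A$k + B$k
  } else {
    m <- A$mean
    se2 <- A$var_scale
    n_blocks <- A$k
  }
  n_used <- rowSums(!is.na(V))
  df <- pmax(n_used - n_blocks, 0)
  ## without blocking the residual is the between-observation variance
  if (is.null(design$block)) {
    ngroups <- length(unique(group))
    if (is.null(design$group)) {
      mu <- rowMeans(V, na.rm = TRUE)
      ss <- rowSums((V - mu)^2, na.rm = TRUE)
      df <- pmax(n_used - 1, 0)
    } else {
      a <- group == "A"
      mA <- rowMeans(V[, a, drop = FALSE], na.rm = TRUE)
      mB <- rowMeans(V[, !a, drop = FALSE], na.rm = TRUE)
      ss <- rowSums((V[, a, drop = FALSE] - mA)^2, na.rm = TRUE) +
        rowSums((V[, !a, drop = FALSE] - mB)^2, na.rm = TRUE)
      df <- pmax(n_used - ngroups, 0)
    }
  }
  df[is.na(m)] <- 0
  s2 <- ifelse(df > 0, ss / pmax(df, 1), NA)
  structure(data.frame(probe_id = rownames(V) %||% as.character(seq_len(ng)),
                       m = m, s2 = s2, df = df, n_used = n_used,
                       se_scale = sqrt(se2),
                       row.names = NULL, stringsAsFactors = FALSE),
            label = attr(design, "label"), class = c("gene_fit", "data.frame"))
}

## Newton inversion of the trigamma function (solve trigamma(x) = y).
trigamma_inverse <- function(y, tol = 1e-8, maxit = 100) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  x
}

#' Estimate variance-moderation hyperparameters
#'
#' Method-of-moments fit of the scaled-F model for the gene-wise residual
#' variances: across genes, log s2 has variance trigamma(df/2) +
#' trigamma(d0/2) around a mean determined by s0^2. `d0 = Inf` is returned
#' when the empirical spread does not exceed the sampling floor (all genes
#' then share s0^2).
#'
#' @param fits a `gene_fit` table; needs at least `min_genes` genes with
#'   df >= 1 and positive s2.
#' @param min_genes guard threshold, default 50.
#' @return list with `d0` (prior degrees of freedom) and `s0_2` (prior
#'   variance).
#' @export
estimate_hyperparameters <- function(fits, min_genes = 50) {
  ok <- !is.na(fits$s2) & fits$df >= 1
  if (sum(ok) < min_genes)
    stop_arg("need at least ", min_genes, " genes with df >= 1 (got ",
             sum(ok), ")")
  s2 <- fits$s2[ok]; df <- fits$df[ok]
  if (all(s2 == 0))
    stop_arg("all residual variances are zero; cannot moderate ",
             "(degenerate, noise-free data)")
  pos <- s2 > 0
  s2 <- s2[pos]; df <- df[pos]
  e <- log(s2)
  x <- e - (digamma(df / 2) - log(df / 2))
  floor_var <- mean(trigamma(df / 2))
  excess <- var(x) * (length(x) - 1) / length(x) - floor_var
  if (excess <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(x))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(mean(x) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

## limma-style estimate of the prior variance ratio v0 from the top
## prior_p fraction of |t|: match the observed extreme t quantiles to the
## two-component mixture's tail.
estimate_v0 <- function(tstat, df, se_scale, prior_p, v0_lim = NULL) {
  ngenes <- length(tstat)
  ntarget <- ceiling(prior_p / 2 * ngenes)
  if (ntarget < 1) return(0)
  p <- max(ntarget / ngenes, prior_p)
  ts <- abs(tstat)
  maxdf <- max(df)
  i <- df < maxdf
  if (any(i)) {
    tailp <- pt(ts[i], df = df[i], lower.tail = FALSE, log.p = TRUE)
    ts[i] <- qt(tailp, df = maxdf, lower.tail = FALSE, log.p = TRUE)
  }
  o <- order(ts, decreasing = TRUE)[seq_len(ntarget)]
  ts <- ts[o]
  v1 <- se_scale[o]^2
  r <- seq_len(ntarget)
  p0 <- 2 * pt(-ts, df = maxdf)
  ptarget <- ((r - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- qt(ptarget[pos] / 2, df = maxdf, lower.tail = FALSE)
    v0[pos] <- v1[pos] * pmax((ts[pos] / qtarget)^2 - 1, 0)
  }
  if (!is.null(v0_lim)) v0 <- pmin(pmax(v0, v0_lim[1]), v0_lim[2])
  mean(v0)
}

#' Moderated statistics (t and B)
#'
#' Shrinks gene-wise variances towards the prior, forms the moderated t on
#' `d0 + df` degrees of freedom, and computes B, the log posterior odds of
#' differential expression under a two-component normal model with prior
#' probability `prior_p` and prior coefficient variance `v0` (in units of
#' the residual variance).
#'
#' @param fits a `gene_fit` table.
#' @param hyper list with `d0` and `s0_2`, as from
#'   [estimate_hyperparameters()].
#' @param prior_p prior probability a gene is differentially expressed,
#'   default 0.01.
#' @param v0 `"auto"` (estimated from the top `prior_p` fraction of |t|) or
#'   a non-negative number.
#' @return data.frame of class `moderated_stats`: `probe_id`, `m`,
#'   `s2_post`, `t` (moderated), `df_total`, `b`; hyperparameters in
#'   attributes.
#' @export
moderated_stats <- function(fits, hyper, prior_p = 0.01, v0 = "auto") {
  if (!is.numeric(prior_p) || prior_p <= 0 || prior_p >= 1)
    stop_arg("prior_p must be in (0, 1)")
  d0 <- hyper$d0; s0_2 <- hyper$s0_2
  if (is.null(d0) || is.null(s0_2) || d0 < 0 || s0_2 <= 0)
    stop_arg("invalid hyperparameters")
  ok <- !is.na(fits$m)
  df <- fits$df
  s2 <- ifelse(is.na(fits$s2), 0, fits$s2)
  s2_post <- if (is.infinite(d0)) rep(s0_2, nrow(fits)) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  df_total <- d0 + df
  tstat <- fits$m / (sqrt(s2_post) * fits$se_scale)
  if (identical(v0, "auto")) {
    use <- ok & df_total > 0
    ## clamp the implied prior coefficient standard deviation (log2 fold
    ## units) to [0.1, 4], preventing blow-ups when a few genes have
    ## near-zero shrunken variance
    v0 <- estimate_v0(tstat[use], pmin(df_total[use], 1e6),
                      fits$se_scale[use], prior_p,
                      v0_lim = c(0.1, 4)^2 / s0_2)
  }
  if (!is.numeric(v0) || v0 < 0) stop_arg("v0 must be 'auto' or >= 0")
  r <- (v0 + fits$se_scale^2) / fits$se_scale^2
  b <- b_statistic(tstat, df_total, r, prior_p)
  structure(data.frame(probe_id = fits$probe_id, m = fits$m,
                       s2_post = s2_post, t = tstat, df_total = df_total,
                       b = b, row.names = NULL, stringsAsFactors = FALSE),
            d0 = d0, s0_2 = s0_2, v0 = v0, prior_p = prior_p,
            label = attr(fits, "label"),
            class = c("moderated_stats", "data.frame"))
}

## Log posterior odds of differential expression for moderated t on
## df degrees of freedom, with variance inflation r = (v0 + c^2)/c^2 under
## the alternative.
b_statistic <- function(tstat, df, r, prior_p) {
  kernel <- ifelse(is.infinite(df),
                   tstat^2 * (1 - 1 / r) / 2,
                   (1 + df) / 2 * log((tstat^2 + df) / (tstat^2 / r + df)))
  log(prior_p / (1 - prior_p)) - log(r) / 2 + kernel
}

#' Call differential expression from moderated statistics
#'
#' The rule is strict: up-regulated iff M > `m_thresh` and B > `b_thresh`;
#' down-regulated iff M < `-m_thresh` and B > `b_thresh`. The default
#' thresholds (|M| > 0.59, i.e. at least 1.5-fold, and B > 0) are the
#' pipeline's standard significance rule.
#'
#' @param stats a `moderated_stats` table.
#' @param m_thresh log2 fold-change threshold, default 0.59.
#' @param b_thresh B threshold, default 0.
#' @return data.frame of class `de_call`: `probe_id`, `m`, `b`, `call` in
#'   `up`/`down`/`none`.
#' @export
call_de <- function(stats, m_thresh = 0.59, b_thresh = 0) {
  call <- rep("none", nrow(stats))
  sig <- !is.na(stats$b) & stats$b > b_thresh & !is.na(stats$m)
  call[sig & stats$m > m_thresh] <- "up"
  call[sig & stats$m < -m_thresh] <- "down"
  structure(data.frame(probe_id = stats$probe_id, m = stats$m, b = stats$b,
                       call = call, row.names = NULL,
                       stringsAsFactors = FALSE),
            m_thresh = m_thresh, b_thresh = b_thresh,
            label = attr(stats, "label"),
            class = c("de_call", "data.frame"))
}
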