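## Two-color preprocessing: background correction with a positive offset,
## MA computation with dye-swap sign correction, print-tip local-regression
## within-array normalization, and quantile between-array normalization.

#' Background-correct a scan set
#'
#' The corrected channel is `max(fg - bg, 0.5) + offset`, guaranteeing
#' strictly positive intensities (hence finite logs) downstream. `method =
#' "none"` floors at 0.5 without subtracting.
#'
#' @param scans an `array_scan_set`, or a single scan data.frame.
#' @param method `"subtract_offset"` (default) or `"none"`.
#' @param offset positive offset added after subtraction (default 50).
#' @return Object of the same shape with corrected `fg_*` channels and
#'   `bg_*` set to 0.
#' @export
background_correct <- function(scans, method = c("subtract_offset", "none"),
                               offset = 50) {
  method <- match.arg(method)
  if (offset < 0) stop_arg("offset must be >= 0")
  fix <- function(s) {
    if (method == "subtract_offset") {
      s$fg_red <- pmax(s$fg_red - s$bg_red, 0.5) + offset
      s$fg_green <- pmax(s$fg_green - s$bg_green, 0.5) + offset
    } else {
      s$fg_red <- pmax(s$fg_red, 0.5)
      s$fg_green <- pmax(s$fg_green, 0.5)
    }
    s$bg_red <- s$bg_green <- 0
    s
  }
  if (inherits(scans, "array_scan_set")) {
    scans$scans <- lapply(scans$scans, fix)
    attr(scans, "background_corrected") <- TRUE
    scans
  } else fix(scans)
}

#' Compute M and A values from a background-corrected scan set
#'
#' M = log2(red/green), A = mean log2 intensity. Arrays marked as the
#' dye-swap member of a pair (`dye_swap_of` set) have M negated, so both
#' members of a pair share the sample-vs-reference orientation in which the
#' unswapped member carries the sample on the red (Cy5) channel.
#'
#' @param scan_set a background-corrected `array_scan_set` with one row per
#'   probe per array.
#' @return An object of class `ma_set`: list with matrices `M` and `A`
#'   (probes x arrays), integer vector `print_tip`, and the `design`.
#' @export
compute_ma <- function(scan_set) {
  stopifnot(inherits(scan_set, "array_scan_set"))
  if (!isTRUE(attr(scan_set, "background_corrected")))
    stop_arg("scan set must be background-corrected first (see background_correct)")
  probes <- scan_set$scans[[1]]$probe_id
  if (anyDuplicated(probes))
    stop_arg("scans carry replicate spots; collapse them first (collapse_spots)")
  ids <- names(scan_set$scans)
  M <- A <- matrix(NA_real_, length(probes), length(ids),
                   dimnames = list(probes, ids))
  for (id in ids) {
    s <- scan_set$scans[[id]]
    if (!identical(s$probe_id, probes))
      stop_arg("array '", id, "': probe set differs from the first array")
    if (any(s$fg_red <= 0 | s$fg_green <= 0))
      stop("internal error: nonpositive intensity after background correction")
    M[, id] <- log2(s$fg_red / s$fg_green)
    A[, id] <- 0.5 * log2(s$fg_red * s$fg_green)
  }
  swap <- scan_set$design$dye_swap_of[match(ids, scan_set$design$array_id)]
  M[, !is.na(swap)] <- -M[, !is.na(swap), drop = FALSE]
  structure(list(M = M, A = A,
                 print_tip = scan_set$scans[[1]]$print_tip_group,
                 design = scan_set$design),
            class = "ma_set")
}

#' @export
print.ma_set <- function(x, ...) {
  cat("ma_set:", nrow(x$M), "probes x", ncol(x$M), "arrays;",
      length(unique(x$print_tip)), "print-tip groups\n")
  invisible(x)
}

## The sample each array measures against its reference: the Cy5 sample for
## an unswapped array, the Cy3 sample for the dye-swap member.
array_samples <- function(design) {
  ifelse(is.na(design$dye_swap_of), design$cy5_sample, design$cy3_sample)
}

#' Tricube-weighted local polynomial regression
#'
#' Minimal loess-style smoother used for MA-trend removal: at every point a
#' polynomial of the given degree is fitted by weighted least squares over
#' the `span` fraction of nearest neighbours with tricube weights, with
#' optional bisquare robustness iterations. A local fit of degree d
#' reproduces a global polynomial trend of degree <= d exactly.
#'
#' @param x,y numeric training vectors (NA pairs are dropped).
#' @param span fraction of training points in each local window, in (0, 1].
#' @param degree local polynomial degree (default 1).
#' @param iterations bisquare robustness iterations (default 4; 0 = plain
#'   fit). Robustness matters here: differentially expressed probes and
#'   bright symbiont probes are M outliers that a non-robust fit would
#'   absorb into the trend.
#' @param xout points at which the trend is evaluated (default `x`).
#' @return Fitted values at each `xout` (NA where `xout` is NA).
#' @export
local_regression <- function(x, y, span = 0.3, degree = 1, iterations = 4,
                             xout = x) {
  if (span <= 0 || span > 1) stop_arg("span must be in (0, 1]")
  ok <- !is.na(x) & !is.na(y)
  xs <- x[ok]; ys <- y[ok]
  n <- length(xs)
  out <- rep(NA_real_, length(xout))
  oko <- !is.na(xout)
  if (n == 0) return(out)
  if (n <= degree + 1) { out[oko] <- mean(ys); return(out) }
  k <- min(max(ceiling(span * n), degree + 2), n)
  fit_at <- function(x0, rw) {
    d <- abs(xs - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) {
      sel <- d == 0
      return(if (sum(rw[sel]) > 0) sum(ys[sel] * rw[sel]) / sum(rw[sel])
             else mean(ys[sel]))
    }
    w <- (1 - pmin(d / h, 1)^3)^3 * rw
    use <- w > 0
    cf <- if (sum(use) > degree) {
      X <- outer(xs[use] - x0, 0:degree, "^")
      tryCatch(stats::lm.wfit(X, ys[use], w[use])$coefficients,
               error = function(e) NULL)
    } else NULL
    if (is.null(cf) || !is.finite(cf[1])) {
      w0 <- (1 - pmin(d / h, 1)^3)^3
      sum(w0 * ys) / sum(w0)
    } else cf[1]
  }
  rw <- rep(1, n)
  for (iter in seq_len(max(iterations, 0))) {
    f <- vapply(xs, fit_at, numeric(1), rw = rw)
    r <- ys - f
    s <- 6 * median(abs(r), na.rm = TRUE)
    rw <- if (!is.finite(s) || s <= 0) rep(1, n)
          else pmax(1 - (r / s)^2, 0)^2
    rw[!is.finite(rw)] <- 0
  }
  out[oko] <- vapply(xout[oko], fit_at, numeric(1), rw = rw)
  out
}

#' Within-array normalization by print-tip local regression
#'
#' For each array and each print-tip group independently, the
#' local-regression trend of M on A is fitted and subtracted; A is
#' unchanged. Groups with fewer than `min_tip_probes` probes fall back to
#' the whole-array fit.
#'
#' The trend can be fitted on a probe subset (`fit_probes`) and applied to
#' all probes. On this platform the symbiont-origin probes violate the
#' mostly-unchanged assumption of MA normalization by construction (they
#' collapse to background wherever symbionts are absent), so fitting the
#' trend on host-origin probes only is recommended for state contrasts.
#'
#' @param ma an `ma_set`.
#' @param span local-regression span in (0, 1], default 0.3.
#' @param degree local polynomial degree, default 1.
#' @param iterations robustness iterations, default 4.
#' @param min_tip_probes minimum fitting probes per print-tip group,
#'   default 20.
#' @param fit_probes optional character vector of probe ids (or logical
#'   vector) used to fit the trend; default all probes.
#' @return The normalized `ma_set`.
#' @export
normalize_within_array <- function(ma, span = 0.3, degree = 1,
                                   iterations = 4, min_tip_probes = 20,
                                   fit_probes = NULL) {
  stopifnot(inherits(ma, "ma_set"))
  if (span <= 0 || span > 1) stop_arg("span must be in (0, 1]")
  in_fit <- if (is.null(fit_probes)) rep(TRUE, nrow(ma$M))
            else if (is.logical(fit_probes)) fit_probes
            else rownames(ma$M) %in% fit_probes
  if (sum(in_fit) < min_tip_probes)
    stop_arg("fewer than ", min_tip_probes, " probes available to fit the ",
             "normalization trend")
  tips <- unique(ma$print_tip)
  for (j in seq_len(ncol(ma$M))) {
    whole <- NULL
    for (t in tips) {
      idx <- which(ma$print_tip == t)
      tr <- idx[in_fit[idx]]
      if (length(tr) < min_tip_probes) {
        if (is.null(whole)) {
          w <- which(in_fit)
          whole <- local_regression(ma$A[w, j], ma$M[w, j], span, degree,
                                    iterations, xout = ma$A[, j])
        }
        ma$M[idx, j] <- ma$M[idx, j] - whole[idx]
      } else {
        trend <- local_regression(ma$A[tr, j], ma$M[tr, j], span, degree,
                                  iterations, xout = ma$A[idx, j])
        ma$M[idx, j] <- ma$M[idx, j] - trend
      }
    }
  }
  ma
}

#' Quantile normalization of a matrix across columns
#'
#' Each column's empirical distribution is replaced by the mean of the
#' sorted columns; ties share the mean of the tied ranks' reference values.
#'
#' @param mat numeric matrix without NAs.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  if (anyNA(mat)) stop_arg("quantile normalization requires complete data")
  n <- nrow(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    o <- order(x)
    xs <- x[o]
    grp <- cumsum(c(TRUE, xs[-1] != xs[-n]))
    vals <- as.numeric(tapply(ref, grp, mean))
    out[o, j] <- vals[grp]
  }
  out
}

#' Between-array normalization
#'
#' `aquantile` (default) quantile-normalizes the A values across arrays and
#' leaves every M untouched; `quantile` normalizes both-channel
#' log-intensities and recomputes M and A (full quantile normalization can
#' distort two-color contrasts, which is why A-only is the default).
#'
#' @param ma an `ma_set` with at least 2 arrays sharing one probe set.
#' @param method `"aquantile"` or `"quantile"`.
#' @return The normalized `ma_set`.
#' @export
normalize_between_arrays <- function(ma, method = c("aquantile", "quantile")) {
  stopifnot(inherits(ma, "ma_set"))
  method <- match.arg(method)
  if (ncol(ma$M) < 2)
    stop_arg("between-array normalization needs at least 2 arrays")
  if (method == "aquantile") {
    ma$A <- quantile_normalize(ma$A)
  } else {
    logR <- ma$A + ma$M / 2
    logG <- ma$A - ma$M / 2
    both <- quantile_normalize(cbind(logR, logG))
    k <- ncol(ma$M)
    logR <- both[, seq_len(k), drop = FALSE]
    logG <- both[, k + seq_len(k), drop = FALSE]
    ma$M <- logR - logG
    ma$A <- (logR + logG) / 2
  }
  ma
}
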