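#' Percentage signal enhancement of one voxel
#'
#' Computes the percentage signal enhancement curve
#' `PSE(t) = 100 * (S(t) - S0) / S0` for a single voxel of a DCE series,
#' where `S0` is the mean of the declared pre-contrast (baseline) frames.
#' A voxel whose `S0` is non-positive cannot be normalized and is marked
#' invalid.
#'
#' @param series a [dce_series()].
#' @param voxel integer vector `c(i, j, k)` (k defaults to 1 if length 2).
#' @return A list with `time` (minutes), `pse` (%), `s0` and `valid`.
#' @export
compute_pse <- function(series, voxel) {
  stopifnot(inherits(series, "dce_series"))
  if (length(voxel) == 2L) voxel <- c(voxel, 1L)
  s <- series$signal[voxel[1], voxel[2], voxel[3], ]
  s0 <- mean(s[seq_len(series$baseline_frames)])
  if (!is.finite(s0) || s0 <= 0) {
    return(list(time = series$frame_times, pse = rep(NA_real_, length(s)),
                s0 = s0, valid = FALSE))
  }
  list(time = series$frame_times, pse = 100 * (s - s0) / s0, s0 = s0,
       valid = TRUE)
}

#' Fit the empirical mathematical model to a PSE curve
#'
#' Least-squares estimation of the amplitude `A`, enhancement rate `alpha`
#' and elution rate `beta` of [emm_model()] from a percentage signal
#' enhancement curve. Fitting uses Levenberg-Marquardt nonlinear least
#' squares with an analytic Jacobian and box bounds
#' (`A` in \[0, 10 * max(PSE)\], `alpha` in \[0, 50\] 1/min, `beta` in
#' \[0, 10\] 1/min). Starting values: `A` from the curve maximum, `alpha`
#' from the time to 90% of maximum, `beta` from the terminal log-slope
#' (floored at 1e-3). Only frames with `t >= 0` (post-injection) enter the
#' fit. A flat curve, an optimizer failure or an `alpha` pinned at its
#' upper bound yields `converged = FALSE`.
#'
#' @param pse numeric PSE values (%) or the result of [compute_pse()].
#' @param frame_times frame times in minutes (ignored when `pse` is a
#'   [compute_pse()] result).
#' @param init optional named starting values `c(amp=, alpha=, beta=)`.
#' @param bounds optional list with `lower` and `upper` length-3 vectors.
#' @return An object of class `emm_fit`: list with `amp`, `alpha`, `beta`,
#'   `rss` and `converged`.
#' @export
fit_emm <- function(pse, frame_times = NULL, init = NULL, bounds = NULL) {
  if (is.list(pse)) { frame_times <- pse$time; pse <- pse$pse }
  keep <- frame_times >= 0 & is.finite(pse)
  t <- frame_times[keep]; y <- pse[keep]
  if (length(y) < 4L) stop("need at least 4 post-baseline frames")
  out <- function(amp, alpha, beta, rss, converged)
    structure(list(amp = amp, alpha = alpha, beta = beta, rss = rss,
                   converged = converged), class = "emm_fit")
  ymax <- max(y)
  if (ymax < 1e-6 || max(abs(y)) < 1e-6) {        # flat / zero-signal curve
    return(out(0, 0, 0, sum(y^2), FALSE))
  }
  lower <- bounds$lower %||% c(0, 0, 0)
  upper <- bounds$upper %||% c(10 * max(ymax, 1), 50, 10)
  if (is.null(init)) {
    t90 <- t[which(y >= 0.9 * ymax)[1]]
    a0 <- if (is.finite(t90) && t90 > 0) -log(0.1) / t90 else 5
    n <- length(y)
    tail_idx <- seq(max(2L, floor(2 * n / 3)), n)
    yt <- y[tail_idx]; tt <- t[tail_idx]
    b0 <- 1e-3
    if (all(yt > 0) && length(yt) >= 3) {
      sl <- stats::coef(stats::lm.fit(cbind(1, tt), log(yt)))[2]
      if (is.finite(sl) && sl < 0) b0 <- min(-sl, upper[3] * 0.9)
      b0 <- max(b0, 1e-3)
    }
    init <- c(amp = ymax, alpha = min(max(a0, 0.1), upper[2] * 0.9), beta = b0)
  }
  resid_fn <- function(p) emm_model(t, p[1], p[2], p[3]) - y
  jac_fn <- function(p) {
    ea <- exp(-p[2] * t); eb <- exp(-p[3] * t)
    cbind((1 - ea) * eb, p[1] * t * ea * eb, -t * p[1] * (1 - ea) * eb)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(init, lower), upper), fn = resid_fn,
                       jac = jac_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out(NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  p <- fit$par
  conv <- fit$info %in% 1:4 && p[2] < upper[2] * 0.999
  out(unname(p[1]), unname(p[2]), unname(p[3]), sum(fit$fvec^2), conv)
}

# weighted log-linear monoexponential fit, vectorized over voxels:
# S = s0 * exp(slope * x), weights proportional to S^2.
# sig: n_voxels x n_samples matrix (all entries must be positive),
# returns list(slope, s0) of length n_voxels.
loglin_fit <- function(sig, x) {
  w <- sig^2
  y <- log(sig)
  sw <- rowSums(w)
  sx <- w %*% x
  sy <- rowSums(w * y)
  sxx <- w %*% x^2
  sxy <- (w * y) %*% x
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  slope[den <= 0] <- NA_real_
  icpt <- (sy - slope * sx) / sw
  list(slope = as.vector(slope), s0 = exp(as.vector(icpt)))
}

#' Monoexponential T2 fit of one voxel
#'
#' Estimates `(S0, T2)` for the relaxation model `S = S0 * exp(-TE/T2)` by
#' weighted log-linear least squares (weights proportional to the squared
#' signal, the standard variance-stabilizing choice for log-transformed
#' magnitude data). With exactly two echoes this reduces to the two-point
#' closed form. Non-positive signals or a non-decaying profile (fitted
#' slope >= 0, i.e. unbounded T2) mark the voxel invalid.
#'
#' @param signals positive signal intensities, one per echo.
#' @param te_list echo times in ms.
#' @return A list with `t2` (ms), `s0`, `rss` (signal-scale residual sum
#'   of squares) and `valid`.
#' @export
fit_t2 <- function(signals, te_list) {
  if (length(signals) < 2L) stop("need at least 2 echoes")
  stopifnot(length(signals) == length(te_list))
  if (any(!is.finite(signals)) || any(signals <= 0))
    return(list(t2 = NA_real_, s0 = NA_real_, rss = NA_real_, valid = FALSE))
  f <- loglin_fit(matrix(signals, nrow = 1), te_list)
  if (!is.finite(f$slope) || f$slope >= 0)
    return(list(t2 = NA_real_, s0 = f$s0, rss = NA_real_, valid = FALSE))
  t2 <- -1 / f$slope
  rss <- sum((signals - f$s0 * exp(-te_list / t2))^2)
  list(t2 = t2, s0 = f$s0, rss = rss, valid = TRUE)
}

#' Monoexponential ADC fit of one voxel
#'
#' Estimates `(S0, ADC)` for the diffusion attenuation model
#' `S = S0 * exp(-b * ADC)` by weighted log-linear least squares over all
#' supplied b-values (weights proportional to the squared signal). A voxel
#' with any non-positive signal is invalid; a negative fitted ADC
#' (signal increasing with b) is flagged invalid as non-physical, while
#' ADC = 0 (no attenuation) is accepted.
#'
#' @param signals positive signal intensities, one per b-value.
#' @param b_list diffusion weightings in s/mm^2.
#' @return A list with `adc` (mm^2/s), `s0`, `rss` and `valid`.
#' @export
fit_adc <- function(signals, b_list) {
  if (length(signals) < 2L) stop("need at least 2 b-values")
  stopifnot(length(signals) == length(b_list))
  if (any(!is.finite(signals)) || any(signals <= 0))
    return(list(adc = NA_real_, s0 = NA_real_, rss = NA_real_, valid = FALSE))
  f <- loglin_fit(matrix(signals, nrow = 1), b_list)
  adc <- -f$slope
  if (!is.finite(adc))
    return(list(adc = NA_real_, s0 = f$s0, rss = NA_real_, valid = FALSE))
  rss <- sum((signals - f$s0 * exp(-b_list * adc))^2)
  list(adc = adc, s0 = f$s0, rss = rss, valid = is.finite(adc) && adc >= 0)
}

#' Voxel-wise parametric mapping
#'
#' Applies a per-voxel fitter over every voxel of a mask and assembles
#' [parametric_map()] objects. `fitter = "emm"` computes the PSE curve of
#' each voxel ([compute_pse()]) and fits the empirical mathematical model
#' ([fit_emm()]), yielding `alpha`, `beta` and `amp` maps; `"t2"` and
#' `"adc"` run the monoexponential fits. Voxels outside the mask are
#' excluded; voxels whose fit fails or does not converge are flagged in
#' `valid_mask` (never silently zero).
#'
#' @param series a [dce_series()], [echo_series()] or [diffusion_series()]
#'   matching the fitter.
#' @param mask logical array over the series' spatial grid, non-empty.
#' @param fitter `"emm"`, `"t2"` or `"adc"`.
#' @param ... passed to the underlying fitter.
#' @return A named list of [parametric_map()] objects (`alpha`, `beta`,
#'   `amp` for `"emm"`; `t2` or `adc` otherwise).
#' @export
map_voxelwise <- function(series, mask, fitter = c("emm", "t2", "adc"), ...) {
  fitter <- match.arg(fitter)
  d <- dim(series$signal)[1:3]
  mask <- array(as.logical(mask), dim = d)
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  if (fitter == "emm") {
    stopifnot(inherits(series, "dce_series"))
    alpha <- beta <- amp <- array(NA_real_, d)
    valid <- array(FALSE, d)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      curve <- compute_pse(series, v)
      if (!curve$valid) next
      f <- fit_emm(curve, ...)
      alpha[v[1], v[2], v[3]] <- f$alpha
      beta[v[1], v[2], v[3]] <- f$beta
      amp[v[1], v[2], v[3]] <- f$amp
      valid[v[1], v[2], v[3]] <- isTRUE(f$converged)
    }
    return(list(alpha = parametric_map(alpha, "alpha", valid),
                beta = parametric_map(beta, "beta", valid),
                amp = parametric_map(amp, "amp", valid)))
  }
  x <- if (fitter == "t2") series$te_list else series$b_list
  flat <- matrix(series$signal, ncol = dim(series$signal)[4])
  sel <- which(mask)
  sig <- flat[sel, , drop = FALSE]
  vals <- array(NA_real_, d); valid <- array(FALSE, d)
  ok <- rowSums(!is.finite(sig) | sig <= 0) == 0
  if (any(ok)) {
    f <- loglin_fit(sig[ok, , drop = FALSE], x)
    est <- if (fitter == "t2") -1 / f$slope else -f$slope
    good <- if (fitter == "t2") is.finite(f$slope) & f$slope < 0 else
      is.finite(f$slope) & -f$slope >= 0
    v <- rep(NA_real_, sum(ok)); v[good] <- est[good]
    vals[sel[ok]] <- v
    valid[sel[ok]] <- good
  }
  nm <- fitter
  setNames(list(parametric_map(vals, nm, valid)), nm)
}

#' Mean parameter value over a region of interest
#'
#' Arithmetic mean of a parametric map over the valid voxels of a mask.
#' Invalid (non-converged) voxels are excluded; if no valid voxel lies in
#' the mask an error is raised rather than returning a silent zero.
#'
#' @param map a [parametric_map()].
#' @param mask logical array; defaults to the whole map.
#' @return A scalar.
#' @export
roi_mean <- function(map, mask = NULL) {
  stopifnot(inherits(map, "parametric_map"))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(map$values))
  sel <- mask & map$valid_mask
  if (!any(sel)) stop("no valid voxels in mask")
  mean(map$values[sel])
}
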