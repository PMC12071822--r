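#' Voxel signal series containers
#'
#' Lightweight containers for 4-D multiparametric MRI signal stacks with
#' their acquisition axes: a dynamic contrast-enhanced (DCE) time series,
#' a multi-echo series for T2 relaxometry, and a multi-b diffusion series.
#' The first three array dimensions are spatial (x, y, z); the fourth runs
#' over frames, echoes, or b-values respectively.
#'
#' @param signal 4-D numeric array `(x, y, z, t)`.
#' @param frame_times numeric, frame times in minutes from contrast
#'   injection (baseline frames have negative times); strictly increasing.
#' @param baseline_frames integer, number of leading pre-contrast frames
#'   (at least 1).
#' @return An object of class `dce_series`, `echo_series`, or
#'   `diffusion_series`.
#' @examples
#' s <- array(1000, dim = c(2, 2, 1, 5))
#' dce <- dce_series(s, frame_times = c(-0.1, 0, 0.1, 0.2, 0.3),
#'                   baseline_frames = 1)
#' @export
dce_series <- function(signal, frame_times, baseline_frames) {
  signal <- as_array4(signal)
  stopifnot(length(frame_times) == dim(signal)[4])
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L) stop("baseline_frames must be >= 1")
  if (baseline_frames >= length(frame_times))
    stop("baseline_frames must leave post-contrast frames")
  structure(list(signal = signal, frame_times = as.numeric(frame_times),
                 baseline_frames = baseline_frames),
            class = "dce_series")
}

#' @rdname dce_series
#' @param te_list numeric, echo times in ms; strictly increasing, positive.
#' @export
echo_series <- function(signal, te_list) {
  signal <- as_array4(signal)
  if (length(te_list) == 0) stop("te_list must be non-empty")
  stopifnot(length(te_list) == dim(signal)[4])
  if (any(te_list <= 0) || any(diff(te_list) <= 0))
    stop("te_list must be strictly increasing and positive")
  structure(list(signal = signal, te_list = as.numeric(te_list)),
            class = "echo_series")
}

#' @rdname dce_series
#' @param b_list numeric, diffusion weightings in s/mm^2; strictly
#'   increasing, non-negative.
#' @export
diffusion_series <- function(signal, b_list) {
  signal <- as_array4(signal)
  if (length(b_list) == 0) stop("b_list must be non-empty")
  stopifnot(length(b_list) == dim(signal)[4])
  if (any(b_list < 0) || any(diff(b_list) <= 0))
    stop("b_list must be strictly increasing and non-negative")
  structure(list(signal = signal, b_list = as.numeric(b_list)),
            class = "diffusion_series")
}

as_array4 <- function(x) {
  if (is.null(dim(x))) stop("signal must be an array")
  d <- dim(x)
  if (length(d) == 3L) {            # single-slice convenience: (x, y, t)
    x <- array(x, dim = c(d[1], d[2], 1L, d[3]))
  } else if (length(d) != 4L) {
    stop("signal must be a 3-d or 4-d array")
  }
  x
}

#' Per-voxel parametric map
#'
#' A scalar map over a voxel grid with physical units and a validity mask
#' marking voxels whose fit was accepted. Invalid voxels carry `NA` in
#' `values` and `FALSE` in `valid_mask`; they are never silently zero.
#'
#' @param values numeric array (2-d or 3-d) of per-voxel parameter values.
#' @param name one of `"alpha"`, `"beta"`, `"amp"`, `"t2"`, `"adc"`,
#'   `"lrhgle"`.
#' @param valid_mask logical array, same shape as `values`; defaults to
#'   `!is.na(values)`.
#' @return An object of class `parametric_map` with fields `values`,
#'   `name`, `units`, `valid_mask`.
#' @export
parametric_map <- function(values, name, valid_mask = NULL) {
  units <- c(alpha = "1/min", beta = "1/min", amp = "%", t2 = "ms",
             adc = "mm^2/s", lrhgle = "")
  name <- match.arg(name, names(units))
  values <- as.array(values)
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  valid_mask <- array(as.logical(valid_mask), dim = dim(values))
  values[!valid_mask] <- NA_real_
  structure(list(values = values, name = name, units = unname(units[name]),
                 valid_mask = valid_mask),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map '%s'%s> %s, %d/%d valid voxels\n",
              x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              paste(dim(x$values), collapse = "x"),
              sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}
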