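#' Texture mapping configuration
#'
#' Settings for sliding-window run-length texture mapping: the window is a
#' square of odd side (default 5, i.e. each pixel is the center of a
#' 5 x 5 matrix), gray levels are quantized into `n_levels` equal-width
#' bins (default 16, the common radiomics choice for small windows —
#' finer binning starves a 25-pixel window), runs are counted along the
#' configured `directions` (degrees; default 0 and 90, averaged to reduce
#' anisotropy), and `border_policy` selects reflect padding (full-size
#' map) or shrink (interior pixels only).
#'
#' @param window odd integer >= 3.
#' @param n_levels number of quantization bins.
#' @param directions subset of `c(0, 45, 90, 135)`.
#' @param border_policy `"reflect"` or `"shrink"`.
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(window = 5, n_levels = 16, directions = c(0, 90),
                           border_policy = c("reflect", "shrink")) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (!all(directions %in% c(0, 45, 90, 135)))
    stop("directions must be a subset of {0, 45, 90, 135}")
  structure(list(window = window, n_levels = as.integer(n_levels),
                 directions = as.integer(directions),
                 border_policy = match.arg(border_policy)),
            class = "texture_config")
}

#' Quantize an image into gray levels
#'
#' Equal-width binning of image values into integer levels `1..n_levels`.
#' By default the bin range is the observed finite value range
#' (`range_policy = "observed"`); an explicit `range = c(lo, hi)` can be
#' supplied instead (values are clamped to it). A constant image maps to
#' level 1 by convention (zero range).
#'
#' @param image numeric matrix.
#' @param n_levels number of levels.
#' @param range optional explicit value range.
#' @return Integer matrix of the same shape, values in `1..n_levels`.
#' @export
quantize <- function(image, n_levels = 16, range = NULL) {
  v <- as.numeric(image)
  if (all(!is.finite(v))) stop("image has no finite values")
  if (is.null(range)) range <- base::range(v[is.finite(v)])
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    q <- array(1L, dim = dim(image))
    return(q)
  }
  q <- floor((pmin(pmax(v, lo), hi) - lo) / (hi - lo) * n_levels) + 1L
  q[q > n_levels] <- n_levels
  q <- array(as.integer(q), dim = dim(image))
  q
}

#' Gray-level run-length matrix
#'
#' Counts `P(i, j)` of maximal runs of quantized gray level `i` and run
#' length `j`, accumulated over the configured directions. A run is a
#' maximal collinear sequence of pixels sharing one quantized level.
#'
#' @param image_window integer matrix of quantized levels (1-based), e.g.
#'   from [quantize()].
#' @param config a [texture_config()] (its `n_levels` and `directions`
#'   are used).
#' @return An object of class `run_length_matrix`: list with `counts`
#'   (n_levels x max_run integer matrix), `n_levels`, `directions` and
#'   `n_runs` (total run count Nr).
#' @export
compute_glrlm <- function(image_window, config = texture_config()) {
  if (length(image_window) == 0) stop("empty window")
  img <- matrix(as.integer(image_window), nrow = nrow(image_window))
  if (anyNA(img) || any(img < 1L) || any(img > config$n_levels))
    stop("window must be quantized to 1..n_levels")
  counts <- glrlm_cpp(img, config$n_levels, config$directions)
  structure(list(counts = counts, n_levels = config$n_levels,
                 directions = config$directions, n_runs = sum(counts)),
            class = "run_length_matrix")
}

#' Long-run high gray-level emphasis
#'
#' The run-length statistic
#' `LRHGLE = (1/Nr) * sum_i sum_j P(i, j) * i^2 * j^2`, which increases
#' when long runs occur at high gray levels.
#'
#' @param rlm a [compute_glrlm()] result.
#' @return Non-negative scalar.
#' @export
lrhgle <- function(rlm) {
  stopifnot(inherits(rlm, "run_length_matrix"))
  if (rlm$n_runs == 0) stop("run-length matrix has no runs")
  i2 <- (seq_len(nrow(rlm$counts)))^2
  j2 <- (seq_len(ncol(rlm$counts)))^2
  sum(rlm$counts * outer(i2, j2)) / rlm$n_runs
}

#' Sliding-window LRHGLE feature map
#'
#' Quantizes the image over its global observed range, then designates
#' each pixel as the center of a `window x window` matrix, computes the
#' gray-level run-length matrix of that window accumulated over the
#' configured directions, and assigns the window's LRHGLE value to the
#' center pixel. Under `border_policy = "reflect"` the image is reflect-
#' padded and the map has the input shape; under `"shrink"` only interior
#' pixels are mapped.
#'
#' @param image numeric matrix, at least `window x window`.
#' @param config a [texture_config()].
#' @return A [parametric_map()] named `"lrhgle"`.
#' @export
lrhgle_map <- function(image, config = texture_config()) {
  if (nrow(image) < config$window || ncol(image) < config$window)
    stop("image smaller than window")
  if (any(!is.finite(image)))
    stop("image contains non-finite values; fill invalid voxels first")
  q <- quantize(image, config$n_levels)
  m <- lrhgle_map_cpp(q, config$window, config$n_levels, config$directions,
                      config$border_policy == "reflect")
  parametric_map(m, "lrhgle")
}
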