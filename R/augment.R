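# Augmentation bank: 6 photometric and 8 spatial label-preserving
# transformations, randomly composed in the style of sampling-based
# automatic augmentation (a small number of operations drawn per image
# from each transformation space).

aug_photometric <- list(
  brightness = function(x) x + runif(1, -0.15, 0.15),
  contrast = function(x) {
    m <- mean(x); (x - m) * runif(1, 0.7, 1.3) + m
  },
  gamma = function(x) pmax(x, 0)^runif(1, 0.7, 1.4),
  noise = function(x) x + rnorm(length(x), 0, runif(1, 0.005, 0.03)),
  blur = function(x) channel_apply(x, function(m) gauss_blur(m, runif(1, 0.4, 1))),
  sharpen = function(x) {
    a <- runif(1, 0.3, 0.8)
    channel_apply(x, function(m) m + a * (m - gauss_blur(m, 0.8)))
  }
)

aug_spatial <- list(
  hflip = function(x) x[rev(seq_len(dim(x)[1])), , , drop = FALSE],
  vflip = function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE],
  rotate = function(x) warp_affine(x, rot_mat(runif(1, -15, 15) * pi / 180)),
  translate_x = function(x)
    warp_affine(x, diag(2), off = c(runif(1, -0.08, 0.08) * dim(x)[1], 0)),
  translate_y = function(x)
    warp_affine(x, diag(2), off = c(0, runif(1, -0.08, 0.08) * dim(x)[2])),
  scale = function(x) warp_affine(x, diag(2) * runif(1, 0.85, 1.15)),
  shear = function(x) {
    s <- runif(1, -0.15, 0.15)
    warp_affine(x, matrix(c(1, s, 0, 1), 2))
  },
  elastic = function(x) warp_elastic(x, amp = runif(1, 0.5, 1.5))
)

channel_apply <- function(x, f) {
  for (c in seq_len(dim(x)[3])) x[, , c] <- f(x[, , c])
  x
}

gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  K <- outer(k, k)
  as.matrix(EBImage::filter2(EBImage::Image(m), K, boundary = "replicate"))
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

# inverse-mapped affine warp about the image center with bilinear
# sampling and edge clamping; A maps output coords to input coords
warp_affine <- function(x, A, off = c(0, 0)) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  g <- expand.grid(i = seq_len(h), j = seq_len(w))
  src <- t(A %*% rbind(g$i - ctr[1], g$j - ctr[2])) +
    matrix(ctr + off, nrow(g), 2, byrow = TRUE)
  bilinear_gather(x, src[, 1], src[, 2])
}

warp_elastic <- function(x, amp = 1, grid = 4L) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  dx <- resize_bilinear(matrix(rnorm(grid^2, 0, amp), grid), h, w)
  dy <- resize_bilinear(matrix(rnorm(grid^2, 0, amp), grid), h, w)
  g <- expand.grid(i = seq_len(h), j = seq_len(w))
  bilinear_gather(x, g$i + as.vector(dx), g$j + as.vector(dy))
}

# vectorized bilinear sampling of all channels at (si, sj), edge clamped
bilinear_gather <- function(x, si, sj) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  si <- pmin(pmax(si, 1), h); sj <- pmin(pmax(sj, 1), w)
  i0 <- pmin(floor(si), h - 1L); j0 <- pmin(floor(sj), w - 1L)
  fi <- si - i0; fj <- sj - j0
  out <- x
  for (c in seq_len(d[3])) {
    m <- x[, , c]
    v <- m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
      m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
      m[cbind(i0, j0 + 1)] * (1 - fi) * fj +
      m[cbind(i0 + 1, j0 + 1)] * fi * fj
    out[, , c] <- matrix(v, h, w)
  }
  out
}

#' Randomly augment a sample
#'
#' Applies a random composition drawn from a fixed bank of 6 photometric
#' transformations (brightness, contrast, gamma, Gaussian noise, blur,
#' sharpen) and 8 spatial transformations (horizontal/vertical flip,
#' rotation, translation along each axis, scaling, shear, light elastic
#' deformation). All operations are label-preserving; the output is
#' clipped back to \[0, 1\]. `mode = "off"` returns the input unchanged;
#' a fixed `seed` makes the draw reproducible (the surrounding RNG state
#' is restored).
#'
#' @param image a [assemble_sample()] sample or `(H, W, C)` array in
#'   \[0, 1\].
#' @param mode `"train"` (random composition) or `"off"` (identity).
#' @param seed optional integer seed.
#' @param n_photometric,n_spatial maximum number of operations drawn from
#'   each space (the realized count is uniform on 0..max).
#' @return Same type as the input.
#' @export
augment_bank <- function(image, mode = c("train", "off"), seed = NULL,
                         n_photometric = 2, n_spatial = 2) {
  mode <- match.arg(mode)
  if (mode == "off") return(image)
  is_sample <- inherits(image, "multichannel_sample")
  x <- if (is_sample) image$pixels else image
  stopifnot(length(dim(x)) == 3L)
  x <- with_seed(seed, {
    np <- sample(0:n_photometric, 1)
    ns <- sample(0:n_spatial, 1)
    ops <- c(sample(aug_photometric, np), sample(aug_spatial, ns))
    for (f in ops) x <- f(x)
    pmin(pmax(x, 0), 1)
  })
  if (is_sample) { image$pixels <- x; image } else x
}
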