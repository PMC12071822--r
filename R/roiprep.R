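#' ROI mask on a reference grid
#'
#' A binary voxel mask together with its grid descriptor (shape, spacing,
#' origin), used to check reader agreement and to transfer contours across
#' co-registered sequences.
#'
#' @param mask logical array (2-d or 3-d), non-empty.
#' @param spacing voxel spacing per axis (defaults to 1).
#' @param origin world coordinate of voxel (1, 1, ...) center (defaults
#'   to 0).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, spacing = NULL, origin = NULL) {
  mask <- as.array(mask)
  d <- dim(mask)
  nd <- length(d)
  spacing <- spacing %||% rep(1, nd)
  origin <- origin %||% rep(0, nd)
  stopifnot(length(spacing) == nd, length(origin) == nd)
  structure(list(mask = array(as.logical(mask), d), shape = d,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "roi_mask")
}

as_roi <- function(x) if (inherits(x, "roi_mask")) x else roi_mask(x)

#' Dice similarity coefficient of two masks
#'
#' Overlap measure `2 |A intersect B| / (|A| + |B|)`; symmetric, 1 for
#' identical and 0 for disjoint masks. Both masks must live on the same
#' grid; two empty masks have no defined overlap and raise an error.
#'
#' @param a,b [roi_mask()] objects or logical arrays of equal shape.
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_roi(a); b <- as_roi(b)
  if (!identical(a$shape, b$shape)) stop("masks are on different grids")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Flag discordant reader contours
#'
#' Two contours are flagged as significantly different — prompting a
#' consensus read — when their Dice similarity coefficient is strictly
#' below the threshold (default 0.80).
#'
#' @inheritParams dice
#' @param threshold agreement threshold.
#' @return `TRUE` iff `dice(a, b) < threshold`.
#' @export
flag_discordant <- function(a, b, threshold = 0.80) {
  dice(a, b) < threshold
}

#' Transfer an ROI mask to another grid
#'
#' Nearest-neighbor resampling of a binary mask onto a co-registered
#' target grid (same patient frame; no deformable registration). Each
#' target voxel center is mapped to world coordinates and assigned the
#' value of the nearest source voxel. An empty resampled mask is an error.
#'
#' @param mask a [roi_mask()].
#' @param target_grid list with `shape` and optional `spacing`, `origin`.
#' @return A [roi_mask()] on the target grid.
#' @export
transfer_roi <- function(mask, target_grid) {
  mask <- as_roi(mask)
  shape <- target_grid$shape
  nd <- length(shape)
  stopifnot(nd == length(mask$shape))
  spacing <- target_grid$spacing %||% rep(1, nd)
  origin <- target_grid$origin %||% rep(0, nd)
  ax <- lapply(seq_len(nd), function(k) {
    world <- origin[k] + (seq_len(shape[k]) - 1) * spacing[k]
    src <- round((world - mask$origin[k]) / mask$spacing[k]) + 1
    pmin(pmax(src, 1), mask$shape[k])
  })
  grid <- as.matrix(expand.grid(ax))
  out <- array(mask$mask[grid], dim = shape)
  if (!any(out)) stop("resampled mask is empty")
  roi_mask(out, spacing, origin)
}

#' Assemble a normalized multichannel ROI sample
#'
#' Builds the model input for one axial slice: per channel, the map is
#' cropped to the mask bounding box, min-max normalized to \[0, 1\] within
#' the crop, resized to `out_size x out_size` with bilinear interpolation,
#' and the channels are stacked. A constant (degenerate) channel is
#' normalized to all zeros with a warning. Invalid map voxels inside the
#' crop are filled with the median of the valid crop values before
#' normalization.
#'
#' @param maps named list of channel images: [parametric_map()] objects or
#'   numeric matrices, all on the slice grid.
#' @param mask logical matrix on the same grid (or [roi_mask()]).
#' @param channels channel names to stack, in order (must be in `maps`).
#' @param out_size output side in pixels (default 224).
#' @param patient_id,slice_index,label sample metadata.
#' @param pad margin of context pixels added around the bounding box.
#' @return An object of class `multichannel_sample`: list with `pixels`
#'   (`out_size x out_size x C` array in \[0, 1\]), `channel_names`,
#'   `patient_id`, `slice_index`, `label`.
#' @export
assemble_sample <- function(maps, mask, channels = names(maps),
                            out_size = 224, patient_id = NA_character_,
                            slice_index = NA_integer_, label = NA_integer_,
                            pad = 2L) {
  missing_ch <- setdiff(channels, names(maps))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  mask <- as.array(mask)
  if (length(dim(mask)) != 2L) stop("mask must be a 2-d slice mask")
  if (!any(mask)) stop("mask is empty")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  rr <- c(max(1, rr[1] - pad), min(nrow(mask), rr[2] + pad))
  cc <- c(max(1, cc[1] - pad), min(ncol(mask), cc[2] + pad))
  px <- array(0, dim = c(out_size, out_size, length(channels)))
  for (ci in seq_along(channels)) {
    ch <- maps[[channels[ci]]]
    img <- if (inherits(ch, "parametric_map")) ch$values else as.array(ch)
    if (length(dim(img)) != 2L) stop("channel images must be 2-d")
    crop <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    if (anyNA(crop)) {
      fill <- median(crop, na.rm = TRUE)
      if (!is.finite(fill)) stop("channel '", channels[ci], "' has no valid voxels in crop")
      crop[is.na(crop)] <- fill
    }
    lo <- min(crop); hi <- max(crop)
    if (hi > lo) {
      crop <- (crop - lo) / (hi - lo)
    } else {
      warning("channel '", channels[ci], "' is constant over the crop; normalized to 0")
      crop[] <- 0
    }
    px[, , ci] <- resize_bilinear(crop, out_size, out_size)
  }
  structure(list(pixels = px, channel_names = channels,
                 patient_id = patient_id,
                 slice_index = as.integer(slice_index),
                 label = as.integer(label)),
            class = "multichannel_sample")
}

# bilinear resize of a 2-d matrix (EBImage backend)
resize_bilinear <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  as.matrix(EBImage::resize(EBImage::Image(img), w = h, h = w,
                            filter = "bilinear"))
}

#' @export
print.multichannel_sample <- function(x, ...) {
  cat(sprintf("<multichannel_sample> %s slice %s: %s, channels [%s], label %s\n",
              x$patient_id, x$slice_index,
              paste(dim(x$pixels), collapse = "x"),
              paste(x$channel_names, collapse = ", "), x$label))
  invisible(x)
}
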