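#' Compute parametric maps and assemble samples for a phantom cohort
#'
#' Runs the quantitative mapping stage over every patient of a cohort and
#' assembles per-slice multichannel samples: the empirical-model `alpha`
#' map is fitted voxel-wise from the DCE series, `t2` and `adc` maps from
#' the relaxometry series, the sliding-window LRHGLE texture map is
#' computed from the `alpha` map (the enhancement-rate channel carries
#' the discriminative texture), and the requested channels are cropped to
#' the lesion bounding box, normalized and resized ([assemble_sample()]).
#' Fits are evaluated over the padded bounding-box rectangle of the mask
#' so the crop has context on all channels.
#'
#' @param cohort a [gen_cohort()] result.
#' @param channels channel names from `t2`, `alpha`, `adc`, `lrhgle`
#'   (default the `t2`-`alpha`-`lrhgle` combination).
#' @param out_size sample side in pixels.
#' @param texture a [texture_config()].
#' @param pad context margin around the lesion bounding box.
#' @param progress print one line per patient.
#' @return List of [assemble_sample()] samples (one per slice
#'   intersecting the lesion, patient labels replicated per slice).
#' @export
prepare_samples <- function(cohort, channels = c("t2", "alpha", "lrhgle"),
                            out_size = 224, texture = texture_config(),
                            pad = 2L, progress = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  samples <- list()
  for (p in cohort$patients) {
    mask <- p$truth$mask
    d <- dim(mask)
    # padded bounding-box rectangle (per slice union) to fit over
    any_sl <- which(apply(mask, 3, any))
    rr <- range(which(apply(mask, 1, any)))
    cc <- range(which(apply(mask, 2, any)))
    rr <- c(max(1, rr[1] - pad), min(d[1], rr[2] + pad))
    cc <- c(max(1, cc[1] - pad), min(d[2], cc[2] + pad))
    fitmask <- array(FALSE, d)
    fitmask[rr[1]:rr[2], cc[1]:cc[2], any_sl] <- TRUE
    need_alpha <- any(c("alpha", "lrhgle") %in% channels)
    maps3d <- list()
    if (need_alpha)
      maps3d$alpha <- map_voxelwise(p$dce, fitmask, "emm")$alpha
    if ("t2" %in% channels)
      maps3d$t2 <- map_voxelwise(p$echo, fitmask, "t2")$t2
    if ("adc" %in% channels)
      maps3d$adc <- map_voxelwise(p$dwi, fitmask, "adc")$adc
    for (z in any_sl) {
      sl_maps <- lapply(maps3d, function(m) m$values[, , z])
      if ("lrhgle" %in% channels) {
        a <- sl_maps$alpha[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
        if (anyNA(a)) a[is.na(a)] <- median(a, na.rm = TRUE)
        lm_ <- lrhgle_map(a, texture)$values
        full <- matrix(NA_real_, d[1], d[2])
        full[rr[1]:rr[2], cc[1]:cc[2]] <- lm_
        sl_maps$lrhgle <- full
      }
      samples[[length(samples) + 1L]] <- assemble_sample(
        sl_maps, mask[, , z], channels = channels, out_size = out_size,
        patient_id = p$id, slice_index = z, label = p$truth$class_label,
        pad = pad)
    }
    if (progress) message("prepared ", p$id)
  }
  samples
}
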