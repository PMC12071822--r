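#' Default diffusion weightings
#'
#' The ten diffusion weighting factors (b-values) of the acquisition
#' protocol, in s/mm^2.
#'
#' @return Numeric vector of length 10.
#' @export
b_values_default <- function() c(10, 50, 100, 150, 200, 400, 600, 800, 1000, 1500)

#' Empirical mathematical model of contrast enhancement
#'
#' Percentage signal enhancement as a function of time after injection:
#' `PSE(t) = A * (1 - exp(-alpha * t)) * exp(-beta * t)`, where `A` is the
#' enhancement amplitude (%), `alpha` the signal enhancement (wash-in)
#' rate and `beta` the elution (wash-out) rate, both in 1/min.
#'
#' @param t time in minutes from injection.
#' @param amp,alpha,beta model parameters (recycled over `t`).
#' @return PSE values (%).
#' @export
emm_model <- function(t, amp, alpha, beta) {
  amp * (1 - exp(-alpha * t)) * exp(-beta * t)
}

#' Ground-truth phantom parameter maps
#'
#' Container for the per-voxel ground truth behind a synthetic patient:
#' enhancement kinetics (`amp`, `alpha`, `beta`), relaxometry (`t2`),
#' diffusivity (`adc`), the tumor mask, the binary progression label and
#' the survival outcome. All rate/relaxation/diffusivity values must be
#' strictly positive inside the mask.
#'
#' @param alpha_map,beta_map 3-d arrays, enhancement/elution rates (1/min).
#' @param amp_map 3-d array, PSE amplitude (%).
#' @param t2_map 3-d array, transverse relaxation time (ms).
#' @param adc_map 3-d array, diffusivity (mm^2/s).
#' @param mask logical 3-d array, tumor voxels.
#' @param class_label 0 (no progression) or 1 (progression to CRPC).
#' @param event_time months to progression or censoring.
#' @param censored logical flag.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(alpha_map, beta_map, amp_map, t2_map, adc_map,
                          mask, class_label, event_time = NA_real_,
                          censored = NA) {
  maps <- list(alpha_map = alpha_map, beta_map = beta_map, amp_map = amp_map,
               t2_map = t2_map, adc_map = adc_map)
  d <- dim(alpha_map)
  for (nm in names(maps)) {
    if (!identical(dim(maps[[nm]]), d)) stop(nm, " has mismatched dimensions")
    if (any(maps[[nm]][mask] <= 0)) stop(nm, " must be strictly positive inside the mask")
  }
  if (!any(mask)) stop("mask must be non-empty")
  structure(c(maps, list(mask = array(as.logical(mask), dim = d),
                         class_label = as.integer(class_label),
                         event_time = event_time, censored = censored)),
            class = "phantom_truth")
}

#' Simulate a DCE-MRI series from phantom ground truth
#'
#' Builds a dynamic contrast-enhanced series whose per-voxel signal follows
#' `S(t) = S0 * (1 + PSE(t)/100)` with PSE from the empirical mathematical
#' model ([emm_model()]) and the truth parameter maps. Post-injection
#' frames are sampled at `t = 0, dt, 2*dt, ...` spanning the acquisition
#' window (so a 7-s frame interval over 4.3 min yields 37 post-baseline
#' frames); `baseline_frames` pre-contrast frames at negative times carry
#' PSE = 0. Noise is additive Gaussian on the magnitude signal with
#' standard deviation `noise_sd` percent of `s0` (a Rician model is
#' available via `rician = TRUE`).
#'
#' @param truth a [phantom_truth()].
#' @param frame_interval temporal resolution in seconds (default 7).
#' @param duration acquisition time in minutes (default 4.3).
#' @param baseline_frames number of pre-contrast frames (default 5).
#' @param noise_sd noise standard deviation as percent of `s0`.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param s0 baseline signal, arbitrary units, strictly positive.
#' @param rician if `TRUE`, Rician (magnitude of complex Gaussian) noise.
#' @return A [dce_series()].
#' @export
gen_dce_series <- function(truth, frame_interval = 7, duration = 4.3,
                           baseline_frames = 5, noise_sd = 0, seed = NULL,
                           s0 = 1000, rician = FALSE) {
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (s0 <= 0) stop("s0 must be strictly positive")
  dt_min <- frame_interval / 60
  n_post <- floor(duration / dt_min) + 1L
  if (n_post < 3L) stop("duration must cover at least 3 frames")
  t_post <- (seq_len(n_post) - 1L) * dt_min
  t_base <- -rev(seq_len(baseline_frames)) * dt_min
  d <- dim(truth$alpha_map)
  nt <- baseline_frames + n_post
  pse <- array(0, dim = c(d, nt))
  for (k in seq_len(n_post)) {
    pse[, , , baseline_frames + k] <-
      emm_model(t_post[k], truth$amp_map, truth$alpha_map, truth$beta_map)
  }
  sig <- s0 * (1 + pse / 100)
  with_seed(seed, {
    if (noise_sd > 0) {
      sdv <- noise_sd / 100 * s0
      if (rician) {
        sig <- sqrt((sig + rnorm(length(sig), 0, sdv))^2 +
                      rnorm(length(sig), 0, sdv)^2)
      } else {
        sig <- sig + rnorm(length(sig), 0, sdv)
      }
      dim(sig) <- c(d, nt)
    }
    sig
  })
  dce_series(sig, frame_times = c(t_base, t_post),
             baseline_frames = baseline_frames)
}

#' Simulate multi-echo and multi-b series from phantom ground truth
#'
#' Echo signals follow the monoexponential relaxation model
#' `S = s0 * exp(-TE / T2)`; diffusion signals follow the monoexponential
#' attenuation model `S = s0 * exp(-b * ADC)`, per voxel, with additive
#' Gaussian noise of standard deviation `noise_sd` percent of `s0`.
#'
#' @inheritParams gen_dce_series
#' @param te_list echo times in ms (default 8 echoes, 20..160 ms).
#' @param b_list diffusion weightings in s/mm^2 (default
#'   [b_values_default()]).
#' @return A list with elements `echo` ([echo_series()]) and `dwi`
#'   ([diffusion_series()]).
#' @export
gen_relaxometry_series <- function(truth, te_list = seq(20, 160, by = 20),
                                   b_list = b_values_default(), s0 = 1000,
                                   noise_sd = 0, seed = NULL) {
  if (length(te_list) == 0) stop("te_list must be non-empty")
  if (length(b_list) == 0) stop("b_list must be non-empty")
  if (s0 <= 0) stop("s0 must be strictly positive")
  d <- dim(truth$t2_map)
  echo <- array(0, dim = c(d, length(te_list)))
  for (k in seq_along(te_list))
    echo[, , , k] <- s0 * exp(-te_list[k] / truth$t2_map)
  dwi <- array(0, dim = c(d, length(b_list)))
  for (k in seq_along(b_list))
    dwi[, , , k] <- s0 * exp(-b_list[k] * truth$adc_map)
  with_seed(seed, {
    if (noise_sd > 0) {
      sdv <- noise_sd / 100 * s0
      echo <- echo + rnorm(length(echo), 0, sdv)
      dwi <- dwi + rnorm(length(dwi), 0, sdv)
      dim(echo) <- c(d, length(te_list)); dim(dwi) <- c(d, length(b_list))
    }
    NULL
  })
  list(echo = echo_series(echo, te_list), dwi = diffusion_series(dwi, b_list))
}

# default inter-patient distribution parameters for the phantom generator;
# values are field-plausible for prostate at 3T, not taken from any cohort
phantom_params_default <- function() {
  list(
    alpha_tumor_mean = 2.0, alpha_tumor_sd = 0.4, alpha_bg_mean = 1.2,
    alpha_class_shift = 0.4,        # per unit of class_effect, in 1/min
    beta_range = c(0.03, 0.15),
    amp_tumor = c(120, 15), amp_bg = c(60, 10),
    t2_tumor = c(80, 8), t2_bg = c(110, 10),
    adc_tumor = c(0.8e-3, 0.08e-3), adc_bg = c(1.4e-3, 0.1e-3),
    texture_base = 0.2, texture_class_gain = 0.2,  # coarse-pattern mixing
    psa_meanlog = log(15), psa_sdlog = 0.5, psa_class_shift = 0.25,
    event_median = c(crpc = 8, noncrpc = 40), censor_horizon = 36
  )
}

# smooth-ish heterogeneity pattern in [-1, 1]: mix of a coarse blocky
# component (long runs of high/low values) and fine-grained noise
texture_pattern <- function(nr, nc, coarse_weight, block = 4L) {
  coarse <- matrix(sample(c(-1, 1), ceiling(nr / block) * ceiling(nc / block),
                          replace = TRUE),
                   ceiling(nr / block))
  coarse <- coarse[rep(seq_len(nrow(coarse)), each = block)[seq_len(nr)],
                   rep(seq_len(ncol(coarse)), each = block)[seq_len(nc)],
                   drop = FALSE]
  fine <- matrix(runif(nr * nc, -1, 1), nr)
  coarse_weight * coarse + (1 - coarse_weight) * fine
}

# one synthetic patient's ground-truth maps (uses the current RNG stream)
gen_patient_truth <- function(shape = c(28, 28), n_slices = 3,
                              class_label = 0, class_effect = 2,
                              params = phantom_params_default()) {
  p <- params
  nr <- shape[1]; nc <- shape[2]
  d <- c(nr, nc, n_slices)
  cx <- nr / 2 + runif(1, -2, 2); cy <- nc / 2 + runif(1, -2, 2)
  rx <- runif(1, 5, 8); ry <- runif(1, 4, 7)
  mask <- array(FALSE, d)
  for (z in seq_len(n_slices)) {
    shrink <- 1 - 0.15 * abs(z - (n_slices + 1) / 2)   # lesion tapers off-slice
    gx <- (row(matrix(0, nr, nc)) - cx) / (rx * shrink)
    gy <- (col(matrix(0, nr, nc)) - cy) / (ry * shrink)
    mask[, , z] <- gx^2 + gy^2 <= 1
  }
  pos <- class_label == 1L
  a_mu <- rnorm(1, p$alpha_tumor_mean +
                  (if (pos) class_effect * p$alpha_class_shift else 0),
                p$alpha_tumor_sd)
  coarse_w <- min(1, p$texture_base + (if (pos) class_effect * p$texture_class_gain else 0))
  alpha <- beta <- amp <- t2 <- adc <- array(0, d)
  b_pat <- runif(1, p$beta_range[1], p$beta_range[2])
  for (z in seq_len(n_slices)) {
    tex <- texture_pattern(nr, nc, coarse_w)
    a_sl <- matrix(rnorm(nr * nc, p$alpha_bg_mean, 0.1), nr)
    a_sl[mask[, , z]] <- a_mu * (1 + 0.15 * tex[mask[, , z]])
    alpha[, , z] <- pmax(a_sl, 0.05)
    beta[, , z] <- pmax(matrix(rnorm(nr * nc, b_pat, 0.01), nr), 1e-3)
    am <- matrix(rnorm(nr * nc, p$amp_bg[1], p$amp_bg[2]), nr)
    am[mask[, , z]] <- rnorm(sum(mask[, , z]), p$amp_tumor[1], p$amp_tumor[2])
    amp[, , z] <- pmax(am, 5)
    t2s <- matrix(rnorm(nr * nc, p$t2_bg[1], p$t2_bg[2]), nr)
    t2s[mask[, , z]] <- rnorm(sum(mask[, , z]), p$t2_tumor[1], p$t2_tumor[2])
    t2[, , z] <- pmax(t2s, 20)
    ad <- matrix(rnorm(nr * nc, p$adc_bg[1], p$adc_bg[2]), nr)
    ad[mask[, , z]] <- rnorm(sum(mask[, , z]), p$adc_tumor[1], p$adc_tumor[2])
    adc[, , z] <- pmax(ad, 1e-4)
  }
  ev_med <- if (pos) p$event_median[["crpc"]] else p$event_median[["noncrpc"]]
  t_ev <- rexp(1, rate = log(2) / ev_med)
  censored <- t_ev > p$censor_horizon
  phantom_truth(alpha, beta, amp, t2, adc, mask, class_label,
                event_time = min(t_ev, p$censor_horizon), censored = censored)
}

# class-conditional clinical covariates (uses the current RNG stream)
gen_clinical_record <- function(class_label, class_effect,
                                params = phantom_params_default()) {
  p <- params
  pos <- class_label == 1L
  age <- round(min(max(rnorm(1, 65, 8), 45), 88))
  psa <- exp(rnorm(1, p$psa_meanlog + (if (pos) class_effect * p$psa_class_shift else 0),
                   p$psa_sdlog))
  g_scores <- 6:10
  w <- c(0.25, 0.30, 0.25, 0.15, 0.05)
  if (pos) w <- w * exp(0.3 * class_effect * (g_scores - 8))
  gleason <- sample(g_scores, 1, prob = w / sum(w))
  t_digit <- sample(2:4, 1, prob = if (pos) {
    wt <- c(1, 2, 2) * exp(0.3 * class_effect * (0:2)); wt / sum(wt)
  } else c(0.5, 0.35, 0.15))
  n_flag <- rbinom(1, 1, min(0.9, 0.15 + (if (pos) 0.08 * class_effect else 0)))
  m_flag <- rbinom(1, 1, min(0.9, 0.08 + (if (pos) 0.08 * class_effect else 0)))
  data.frame(age = age, psa = psa, gleason = gleason,
             tnm = sprintf("T%dN%dM%d", t_digit, n_flag, m_flag))
}

#' Generate a synthetic two-class phantom cohort
#'
#' Builds a full cohort of synthetic patients: per-patient multi-slice DCE,
#' multi-echo and multi-b series with a tumor mask and known ground-truth
#' parameter maps, plus class-conditional clinical covariates (age, PSA,
#' Gleason score, clinical TNM stage) and survival outcomes. `class_effect`
#' scales the separation between the progressing and non-progressing
#' classes: the tumor enhancement-rate means are shifted by
#' `class_effect` standard deviations, the coarse (long-run) texture
#' mixing weight and the PSA/Gleason/TNM distributions shift accordingly.
#' `class_effect = 0` produces an uninformative cohort.
#'
#' @param n_patients total number of patients (at least 4).
#' @param class_effect class separation in units described above.
#' @param slices_per_patient axial slices intersecting the lesion.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param n_positive number of progressing patients; defaults to the
#'   38/96 cohort proportion, and both classes must be non-empty.
#' @param shape in-plane grid size `c(nx, ny)`.
#' @param noise_sd acquisition noise, percent of baseline signal.
#' @param params generator distribution parameters
#'   ([phantom_params_default()]).
#' @param frame_interval,duration DCE sampling settings, see
#'   [gen_dce_series()].
#' @return An object of class `phantom_cohort`: list with `patients` (each
#'   holding `id`, `truth`, `dce`, `echo`, `dwi`), `clinical` (data frame
#'   with columns patient_id, age, psa, gleason, tnm, label, event_months,
#'   censored) and `truth` (list of [phantom_truth()]).
#' @export
gen_cohort <- function(n_patients, class_effect = 2, slices_per_patient = 3,
                       seed = 1, n_positive = round(n_patients * 38 / 96),
                       shape = c(28, 28), noise_sd = 2,
                       params = phantom_params_default(),
                       frame_interval = 7, duration = 4.3) {
  if (n_patients < 4) stop("n_patients must be at least 4")
  if (n_positive < 1 || n_positive > n_patients - 1)
    stop("both classes must be represented")
  with_seed(seed, {
    labels <- sample(rep(c(1L, 0L), c(n_positive, n_patients - n_positive)))
    patients <- vector("list", n_patients)
    clin <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      tr <- gen_patient_truth(shape, slices_per_patient, labels[i],
                              class_effect, params)
      dce <- gen_dce_series(tr, frame_interval = frame_interval,
                            duration = duration, noise_sd = noise_sd)
      rel <- gen_relaxometry_series(tr, noise_sd = noise_sd)
      id <- sprintf("P%03d", i)
      patients[[i]] <- list(id = id, truth = tr, dce = dce,
                            echo = rel$echo, dwi = rel$dwi)
      rec <- gen_clinical_record(labels[i], class_effect, params)
      clin[[i]] <- cbind(data.frame(patient_id = id), rec,
                         data.frame(label = labels[i],
                                    event_months = tr$event_time,
                                    censored = tr$censored))
    }
    structure(list(patients = patients,
                   clinical = do.call(rbind, clin),
                   truth = lapply(patients, `[[`, "truth"),
                   seed = seed, class_effect = class_effect),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients (%d progressing), class_effect = %g, seed = %d\n",
              length(x$patients), sum(x$clinical$label), x$class_effect, x$seed))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes per-patient NIfTI volumes (DCE, echo and diffusion stacks and the
#' tumor mask), `clinical.csv` and a `truth.json` with the ground-truth
#' scalar summaries, so that synthetic and real data enter the pipeline
#' through the same files.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    RNifti::writeNifti(p$dce$signal, file.path(dir, paste0(p$id, "_dce.nii.gz")))
    RNifti::writeNifti(p$echo$signal, file.path(dir, paste0(p$id, "_echo.nii.gz")))
    RNifti::writeNifti(p$dwi$signal, file.path(dir, paste0(p$id, "_dwi.nii.gz")))
    RNifti::writeNifti(p$truth$mask + 0, file.path(dir, paste0(p$id, "_mask.nii.gz")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  truth <- lapply(cohort$patients, function(p) {
    m <- p$truth$mask
    list(patient_id = p$id, class_label = p$truth$class_label,
         event_months = p$truth$event_time, censored = p$truth$censored,
         alpha_tumor_mean = mean(p$truth$alpha_map[m]),
         t2_tumor_mean = mean(p$truth$t2_map[m]),
         adc_tumor_mean = mean(p$truth$adc_map[m]))
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
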