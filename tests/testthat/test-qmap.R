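make_dce <- function(curve_fun, baseline = 3, s0 = 100, dt = 7 / 60,
                     n_post = 37) {
  t_post <- (seq_len(n_post) - 1) * dt
  times <- c(-rev(seq_len(baseline)) * dt, t_post)
  sig <- array(0, c(1, 1, 1, length(times)))
  sig[1, 1, 1, ] <- c(rep(s0, baseline), curve_fun(t_post) * s0)
  dce_series(sig, times, baseline)
}

test_that("PSE follows its defining ratio identities", {
  dce <- make_dce(function(t) rep(1, length(t)))
  expect_equal(compute_pse(dce, c(1, 1, 1))$pse,
               rep(0, 40), tolerance = 1e-12)
  dce <- make_dce(function(t) rep(1.5, length(t)))
  p <- compute_pse(dce, c(1, 1, 1))
  expect_equal(p$pse[p$time >= 0], rep(50, 37), tolerance = 1e-12)
  # S0 is the mean of the declared baseline frames
  sig <- array(c(98, 100, 102, 150, 150, 150, 150), c(1, 1, 1, 7))
  dce <- dce_series(sig, seq(-3, 3) * 7 / 60, baseline_frames = 3)
  expect_equal(compute_pse(dce, c(1, 1, 1))$s0, 100)
  # non-positive S0 marks the voxel invalid
  sig0 <- array(c(-1, 1, 5, 5, 5, 5, 5), c(1, 1, 1, 7))
  dce0 <- dce_series(sig0, seq(-3, 3) * 7 / 60, baseline_frames = 2)
  expect_false(compute_pse(dce0, c(1, 1, 1))$valid)
})

test_that("EMM fitting recovers noiseless kinetics and flags degenerate input", {
  t <- seq(0, 4.3, by = 7 / 60)
  f <- fit_emm(emm_model(t, 120, 3, 0.05), t)
  expect_true(f$converged)
  expect_lt(abs(f$amp - 120) / 120, 1e-3)
  expect_lt(abs(f$alpha - 3) / 3, 1e-3)
  expect_lt(abs(f$beta - 0.05) / 0.05, 1e-3)
  z <- fit_emm(rep(0, length(t)), t)
  expect_equal(z$amp, 0)
  expect_false(z$converged)
  expect_error(fit_emm(c(0, 1, 2), c(0, 0.1, 0.2)), "at least 4")
})

test_that("PSE + EMM fit is invariant to rescaling the raw signal", {
  tr <- uniform_truth(alpha = 2, beta = 0.1, amp = 90)
  d1 <- gen_dce_series(tr, noise_sd = 0, s0 = 100)
  d2 <- d1; d2$signal <- d1$signal * 37.5
  f1 <- fit_emm(compute_pse(d1, c(1, 1, 1)))
  f2 <- fit_emm(compute_pse(d2, c(1, 1, 1)))
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_equal(f1$amp, f2$amp, tolerance = 1e-10)
})

test_that("T2 and ADC fits match the two-point closed form and flag degeneracies", {
  f <- fit_t2(c(1000 * exp(-50 / 80), 1000 * exp(-100 / 80)), c(50, 100))
  expect_equal(f$t2, 80, tolerance = 1e-10)
  expect_equal(f$s0, 1000, tolerance = 1e-8)
  expect_false(fit_t2(c(500, 500), c(50, 100))$valid)  # T2 unbounded
  expect_false(fit_t2(c(100, -5), c(50, 100))$valid)
  te <- seq(20, 160, by = 20)
  f8 <- fit_t2(900 * exp(-te / 65), te)
  expect_lt(abs(f8$t2 - 65) / 65, 1e-6)
  b <- b_values_default()
  fa <- fit_adc(2000 * exp(-b * 1e-3), b)
  expect_equal(fa$adc, 1e-3, tolerance = 1e-10)
  expect_equal(fit_adc(c(1000, 1000), c(0, 1000))$adc, 0, tolerance = 1e-12)
  expect_false(fit_adc(c(1000, 0), c(0, 1000))$valid)
  # two-point agreement on random positive decaying pairs
  set.seed(5)
  for (k in 1:20) {
    s <- sort(runif(2, 10, 1000), decreasing = TRUE)
    x <- sort(runif(2, 10, 100))
    slope <- (log(s[2]) - log(s[1])) / (x[2] - x[1])
    expect_equal(fit_t2(s, x)$t2, -1 / slope, tolerance = 1e-8)
    expect_equal(fit_adc(s, x)$adc, -slope, tolerance = 1e-8)
  }
})

test_that("noise degrades fits monotonically in the median", {
  set.seed(77)
  tr <- uniform_truth(alpha = 2.5, beta = 0.08, amp = 110,
                      shape = c(10, 10, 1))
  med_err <- sapply(c(10, 5, 1), function(ns) {
    dce <- gen_dce_series(tr, noise_sd = ns, seed = 100 + ns)
    m <- map_voxelwise(dce, tr$mask, "emm")$alpha
    median(abs(m$values[m$valid_mask] - 2.5) / 2.5)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("voxel-wise mapping equals the manual per-voxel loop", {
  set.seed(12)
  tr <- mpfusion:::gen_patient_truth(shape = c(8, 8), n_slices = 1,
                                     class_label = 0, class_effect = 1)
  rel <- gen_relaxometry_series(tr, noise_sd = 1, seed = 3)
  mask <- tr$mask
  mt2 <- map_voxelwise(rel$echo, mask, "t2")$t2
  madc <- map_voxelwise(rel$dwi, mask, "adc")$adc
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    expect_equal(mt2$values[v[1], v[2], v[3]],
                 fit_t2(rel$echo$signal[v[1], v[2], v[3], ], rel$echo$te_list)$t2,
                 tolerance = 1e-10)
    expect_equal(madc$values[v[1], v[2], v[3]],
                 fit_adc(rel$dwi$signal[v[1], v[2], v[3], ], rel$dwi$b_list)$adc,
                 tolerance = 1e-10)
  }
  dce <- gen_dce_series(tr, noise_sd = 0)
  one <- array(FALSE, dim(mask)); one[idx[1, 1], idx[1, 2], 1] <- TRUE
  m1 <- map_voxelwise(dce, one, "emm")$alpha
  expect_equal(sum(m1$valid_mask), 1)
  expect_equal(m1$values[idx[1, 1], idx[1, 2], 1],
               fit_emm(compute_pse(dce, idx[1, ]))$alpha, tolerance = 1e-12)
  expect_error(map_voxelwise(dce, array(FALSE, dim(mask)), "emm"), "empty")
  # uniform phantom -> constant map over the mask interior
  tru <- uniform_truth(shape = c(6, 6, 1))
  mm <- map_voxelwise(gen_relaxometry_series(tru, noise_sd = 0)$echo,
                      tru$mask, "t2")$t2
  expect_lt(diff(range(mm$values[mm$valid_mask])), 1e-9)
})

test_that("ROI averaging uses valid voxels only", {
  m <- parametric_map(array(c(1, 2, 3), c(3, 1)), "alpha")
  expect_equal(roi_mean(m), 2)
  m2 <- parametric_map(array(c(1, 2, NA), c(3, 1)), "alpha")
  expect_equal(roi_mean(m2), 1.5)
  m3 <- parametric_map(array(NA_real_, c(2, 2)), "alpha")
  expect_error(roi_mean(m3), "no valid voxels")
  set.seed(8)
  v <- array(runif(24), c(4, 6))
  ok <- array(runif(24) > 0.3, c(4, 6))
  mask <- array(runif(24) > 0.2, c(4, 6))
  m4 <- parametric_map(v, "t2", ok)
  sel <- ok & mask
  if (any(sel)) expect_equal(roi_mean(m4, mask), sum(v[sel]) / sum(sel))
})
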