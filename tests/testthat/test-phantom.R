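test_that("DCE frame schedule matches the acquisition protocol", {
  tr <- uniform_truth()
  dce <- gen_dce_series(tr, frame_interval = 7, duration = 4.3,
                        baseline_frames = 5, noise_sd = 0)
  post <- dce$frame_times[dce$frame_times >= 0]
  expect_equal(length(post), 37)
  expect_equal(dce$baseline_frames, 5L)
  expect_equal(dim(dce$signal)[4], 42)
  expect_equal(diff(post)[1], 7 / 60, tolerance = 1e-12)
  expect_error(gen_dce_series(tr, s0 = 0), "positive")
  expect_error(gen_dce_series(tr, frame_interval = 7, duration = 0.1),
               "at least 3")
})

test_that("noiseless DCE generation reproduces the enhancement model exactly", {
  tr <- uniform_truth(alpha = 2.5, beta = 0.08, amp = 100)
  dce <- gen_dce_series(tr, noise_sd = 0, s0 = 500)
  curve <- compute_pse(dce, c(2, 3, 1))
  t_post <- curve$time[curve$time >= 0]
  expect_equal(curve$pse[curve$time >= 0],
               emm_model(t_post, 100, 2.5, 0.08), tolerance = 1e-12)
  expect_equal(curve$pse[curve$time < 0], rep(0, 5), tolerance = 1e-12)
  expect_true(all(dce$signal >= 0))
})

test_that("generation is seeded: identical under one seed, different across seeds", {
  tr <- uniform_truth()
  a <- gen_dce_series(tr, noise_sd = 5, seed = 11)
  b <- gen_dce_series(tr, noise_sd = 5, seed = 11)
  c <- gen_dce_series(tr, noise_sd = 5, seed = 12)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  r1 <- gen_relaxometry_series(tr, noise_sd = 3, seed = 4)
  r2 <- gen_relaxometry_series(tr, noise_sd = 3, seed = 4)
  expect_identical(r1$echo$signal, r2$echo$signal)
})

test_that("relaxometry generation follows the monoexponential closed forms", {
  tr <- uniform_truth(t2 = 80, adc = 1e-3)
  r <- gen_relaxometry_series(tr, te_list = c(40, 80), b_list = c(500, 1000),
                              s0 = 1000, noise_sd = 0)
  expect_equal(r$echo$signal[1, 1, 1, 2], 1000 * exp(-1), tolerance = 1e-12)
  expect_equal(r$dwi$signal[1, 1, 1, 2], 1000 * exp(-1), tolerance = 1e-12)
  expect_length(b_values_default(), 10)
  expect_equal(b_values_default(),
               c(10, 50, 100, 150, 200, 400, 600, 800, 1000, 1500))
  expect_error(gen_relaxometry_series(tr, te_list = numeric(0)), "non-empty")
})

test_that("cohort generation honours the requested class split and seed", {
  coh <- gen_cohort(12, class_effect = 2, slices_per_patient = 2, seed = 9,
                    n_positive = 5)
  expect_equal(sum(coh$clinical$label), 5)
  expect_equal(nrow(coh$clinical), 12)
  coh2 <- gen_cohort(12, class_effect = 2, slices_per_patient = 2, seed = 9,
                     n_positive = 5)
  expect_identical(coh$clinical, coh2$clinical)
  expect_identical(coh$patients[[3]]$dce$signal, coh2$patients[[3]]$dce$signal)
  expect_error(gen_cohort(12, n_positive = 0), "both classes")
  expect_error(gen_cohort(12, n_positive = 12), "both classes")
  expect_error(gen_cohort(3), "at least 4")
  # truth invariants: strictly positive parameters inside the mask
  for (tr in coh$truth[1:3]) {
    m <- tr$mask
    expect_true(all(tr$alpha_map[m] > 0))
    expect_true(all(tr$t2_map[m] > 0))
    expect_true(all(tr$adc_map[m] > 0))
  }
})

test_that("noiseless phantom generation round-trips through every fitter", {
  set.seed(31)
  tr <- mpfusion:::gen_patient_truth(shape = c(16, 16), n_slices = 1,
                                     class_label = 1, class_effect = 2)
  dce <- gen_dce_series(tr, noise_sd = 0)
  rel <- gen_relaxometry_series(tr, noise_sd = 0)
  vox <- which(tr$mask, arr.ind = TRUE)[1:5, , drop = FALSE]
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    f <- fit_emm(compute_pse(dce, v))
    expect_lt(abs(f$alpha - tr$alpha_map[v[1], v[2], v[3]]) /
                tr$alpha_map[v[1], v[2], v[3]], 1e-3)
    expect_lt(abs(f$amp - tr$amp_map[v[1], v[2], v[3]]) /
                tr$amp_map[v[1], v[2], v[3]], 1e-3)
    t2f <- fit_t2(rel$echo$signal[v[1], v[2], v[3], ], rel$echo$te_list)
    expect_lt(abs(t2f$t2 - tr$t2_map[v[1], v[2], v[3]]) /
                tr$t2_map[v[1], v[2], v[3]], 1e-6)
    af <- fit_adc(rel$dwi$signal[v[1], v[2], v[3], ], rel$dwi$b_list)
    expect_lt(abs(af$adc - tr$adc_map[v[1], v[2], v[3]]) /
                tr$adc_map[v[1], v[2], v[3]], 1e-6)
  }
})

test_that("cohort files round-trip through the NIfTI/CSV writer", {
  coh <- gen_cohort(4, seed = 2, n_positive = 2, slices_per_patient = 1,
                    shape = c(12, 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "P001_dce.nii.gz")))
  back <- RNifti::readNifti(file.path(dir, "P001_dce.nii.gz"))
  expect_equal(dim(back), dim(coh$patients[[1]]$dce$signal))
  expect_equal(as.array(back), unclass(coh$patients[[1]]$dce$signal),
               ignore_attr = TRUE, tolerance = 1e-6)
})
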