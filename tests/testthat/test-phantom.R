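test_that("phantom satisfies its geometric and fraction invariants", {
  ph <- make_phantom(c(32, 32, 32), seed = 1)
  m <- ph$masks
  fsum <- ph$fractions$f_mw + ph$fractions$f_ie + ph$fractions$f_csf
  expect_equal(max(abs(fsum[m$brain] - 1)), 0)
  expect_true(all(ph$fractions$f_mw[m$brain] >= 0))
  expect_true(all(ph$fractions$f_csf[m$brain] >= 0))
  # mask algebra
  expect_true(all(m$wmh[m$wmh] & m$wm[m$wmh]))
  expect_true(all(m$wm[m$pvs_truth]))
  expect_true(all(m$gm[m$admask]))
  expect_true(all(m$brain[m$cerebellum_ref]))
  expect_false(any(m$gm & m$wm))
  expect_true(all(ph$fw_truth >= 0 & ph$fw_truth <= 1))
})

test_that("phantom generation is deterministic and rejects degenerate shapes", {
  expect_identical(make_phantom(seed = 7), make_phantom(seed = 7))
  expect_error(make_phantom(c(8, 32, 32)), "shape")
  expect_error(make_phantom(c(32, 32, 32), phantom_spec(pvs_radius_vox = 6)),
               "tubule")
})

test_that("tubule voxel count matches a brute-force scan of the analytic cylinder", {
  ph <- make_phantom(c(32, 32, 32), phantom_spec(pvs_radius_vox = 1,
                                                 pvs_length_vox = 10))
  # brute force: recompute the cylinder membership voxel by voxel
  ctr <- (c(32, 32, 32) + 1) / 2
  R <- 32 / 2 - 1
  x0 <- round(ctr[1] - 10 / 2); y0 <- round(ctr[2]); z0 <- round(ctr[3] + 0.475 * R)
  scan <- array(FALSE, c(32, 32, 32))
  for (x in 1:32) for (y in 1:32) for (z in 1:32)
    scan[x, y, z] <- x >= x0 && x <= x0 + 9 && (y - y0)^2 + (z - z0)^2 <= 1
  expect_identical(ph$masks$pvs_truth, scan)
  # radius-1 disc has 5 voxels; 10 slices
  expect_identical(sum(scan), 50L)
  expect_identical(sum(ph$masks$pvs_truth), 50L)
})

test_that("multi-echo simulation matches the three-pool forward model at infinite SNR", {
  ph <- small_phantom()
  series <- simulate_multiecho(ph, snr = Inf)
  # t = 0 echo equals M0 everywhere
  expect_equal(series$data[, , , 1], ph$m0)
  # spot-check voxels against the closed-form signal
  idx <- which(ph$masks$wm)[c(1, 50, 200)]
  for (ii in idx) {
    f <- c(ph$fractions$f_mw[ii], ph$fractions$f_ie[ii], ph$fractions$f_csf[ii])
    pred <- predict_t2_signal(f, default_t2s, ph$m0[ii], series$t2prep_times_ms)
    got <- series$data[ii + (seq_along(pred) - 1) * prod(ph$shape)]
    expect_equal(got, pred, tolerance = 1e-12)
  }
  expect_identical(simulate_multiecho(ph, snr = 50, seed = 3)$data,
                   simulate_multiecho(ph, snr = 50, seed = 3)$data)
})

test_that("Rician noise has the closed-form floor at zero signal", {
  set.seed(99)
  sigma <- 1 / 5
  draws <- add_rician_noise(rep(0, 10000), sigma)
  floor_mean <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(10000)
  expect_lt(abs(mean(draws) - floor_mean), 3 * se)
})

test_that("DWI simulation matches the bi-tensor forward model", {
  ph <- small_phantom()
  acq <- default_dwi_acquisition(n_per_shell = 8)
  dwi <- simulate_dwi(ph, acq, snr = Inf)
  # b = 0 volumes equal S0
  expect_equal(dwi$data[, , , 1], ph$m0)
  # ventricular voxel: pure free water, S/S0 = exp(-b * d_iso)
  csf_idx <- which(ph$labels == 3L)[1]
  nvox <- prod(ph$shape)
  b1500_vol <- which(dwi$bvals == 1500)[1]
  expect_equal(dwi$data[csf_idx + (b1500_vol - 1) * nvox], exp(-1500 * 3e-3),
               tolerance = 1e-12)
  # WM voxel against bitensor_signal
  wm_idx <- which(ph$masks$wm)[10]
  d6 <- ph$tissue_tensor[arrayInd(wm_idx, ph$shape)[1],
                         arrayInd(wm_idx, ph$shape)[2],
                         arrayInd(wm_idx, ph$shape)[3], ]
  pred <- bitensor_signal(d6, ph$fw_truth[wm_idx], ph$m0[wm_idx],
                          dwi$bvals, dwi$bvecs)
  got <- dwi$data[wm_idx + (seq_along(dwi$bvals) - 1) * nvox]
  expect_equal(got, pred, tolerance = 1e-12)
  # single-shell refusal
  acq1 <- acquisition_spec(bvals = c(0, rep(1500, 8)),
                           bvecs = rbind(0, glymap:::fibonacci_directions(8)))
  expect_error(simulate_dwi(ph, acq1), "identifiability")
})

test_that("structural simulation yields lower EPC inside PVS than in plain WM", {
  ph <- small_phantom()
  st <- simulate_structural(ph, seed = 2)
  epc <- compute_epc(st$t1w, st$t2w, ph$masks$brain)
  pvs <- ph$masks$pvs_truth
  plain <- ph$masks$wm & !pvs
  expect_lt(mean(epc$data[pvs]), mean(epc$data[plain]))
  # zero noise gives per-structure constants
  st0 <- simulate_structural(ph, structural_contrast(noise_sd = 0))
  expect_equal(length(unique(st0$t1w[ph$masks$wm & !pvs & !ph$masks$wmh])), 1L)
  expect_identical(simulate_structural(ph, seed = 5),
                   simulate_structural(ph, seed = 5))
  expect_error(simulate_structural(ph, list(t1w = c(gm = -1, wm = 1, csf = 1,
                                                    pvs = 1, wmh = 1),
                                            t2w = structural_contrast()$t2w,
                                            noise_sd = 0)),
               "positive")
})

test_that("PET simulation plants the SUVR exactly at zero noise", {
  ph <- small_phantom()
  pet <- simulate_pet(ph, suvr_truth = 2.07, noise_sd = 0)
  expect_equal(compute_suvr(pet, ph$masks$admask, ph$masks$cerebellum_ref), 2.07)
  pet1 <- simulate_pet(ph, suvr_truth = 1.0, noise_sd = 0)
  expect_equal(unique(pet1[ph$masks$admask | ph$masks$cerebellum_ref]), 1)
  # noisy SUVR is unbiased
  est <- vapply(1:100, function(s)
    compute_suvr(simulate_pet(ph, 1.5, noise_sd = 0.01, seed = s),
                 ph$masks$admask, ph$masks$cerebellum_ref), 1)
  expect_lt(abs(mean(est) - 1.5), 3 * sd(est) / sqrt(100))
})

test_that("cohort generator reproduces the study design", {
  co <- make_cohort(cohort_spec(seed = 4), make_phantoms = FALSE)
  tab <- cohort_truth_table(co)
  expect_identical(nrow(tab), 29L)
  expect_identical(sum(tab$dx == "NL"), 16L)
  expect_identical(sum(tab$dx == "MCIAD"), 13L)
  expect_true(all(tab$wm_pcsf >= 0 & tab$wm_pcsf <= 100))
  # near-zero sds collapse each subject onto its group mean
  sp <- cohort_spec(seed = 2)
  sp$group_sds <- lapply(sp$group_sds, function(s) s * 0 + 1e-9)
  tt <- cohort_truth_table(make_cohort(sp, make_phantoms = FALSE))
  expect_equal(unique(round(tt$wm_pcsf[tt$dx == "NL"], 6)), 4.45)
  expect_equal(unique(round(tt$wm_pcsf[tt$dx == "MCIAD"], 6)), 4.86)
  # law of large numbers: sample means near targets at n = 200/group
  spL <- cohort_spec(n_nl = 200, n_mciad = 200, seed = 8)
  tl <- cohort_truth_table(make_cohort(spL, make_phantoms = FALSE))
  for (g in c("NL", "MCIAD")) {
    key <- if (g == "NL") "nl" else "mciad"
    mu <- spL$group_means[[key]][["wm_pcsf"]]
    se <- spL$group_sds[[key]][["wm_pcsf"]] / sqrt(200)
    expect_lt(abs(mean(tl$wm_pcsf[tl$dx == g]) - mu), 3 * se)
  }
  expect_error(make_cohort(cohort_spec(n_nl = 1)), "group sizes")
})

test_that("per-subject phantoms carry the subject's ROI truth after rescaling", {
  sp <- cohort_spec(n_nl = 2, n_mciad = 2, seed = 6)
  co <- make_cohort(sp, make_phantoms = TRUE, shape = c(16, 16, 16),
                    phantom_pars = phantom_spec(pvs_length_vox = 3,
                                                wmh_radius_vox = 1))
  for (s in co) {
    ph <- s$phantom
    roi <- ph$masks$wm & !ph$masks$wmh
    wm_pcsf <- 100 * mean(ph$fractions$f_csf[roi]) * twc_constants()$wm
    expect_equal(wm_pcsf, s$record$wm_pcsf, tolerance = 1e-9)
    fsum <- ph$fractions$f_mw + ph$fractions$f_ie + ph$fractions$f_csf
    expect_equal(max(abs(fsum[ph$masks$brain] - 1)), 0, tolerance = 1e-12)
  }
})
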