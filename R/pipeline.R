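#' Measure one subject's biomarkers from simulated images
#'
#' Runs the full image path for one cohort subject: simulate the multi-echo
#' T2prep series, the two-shell DWI, the structural pair and the PET volume
#' from the subject's phantom, fit the relaxometry and free-water models,
#' segment perivascular spaces on the enhanced PVS contrast, calibrate the
#' fraction maps by tissue total water content and extract ROI values (WMH
#' excluded from WM ROIs). This is the end-to-end route; it is exact at
#' `snr = Inf` up to fit tolerances.
#'
#' @param phantom subject phantom (`glymap_phantom`)
#' @param record one-row subject record (needs `suvr_truth` and covariates)
#' @param snr acquisition SNR for the MR simulations (`Inf` for noise-free)
#' @param pet_noise_sd PET additive noise
#' @param seed noise seed
#' @param t2_model [t2_pool_model()]
#' @param dwi_acq diffusion acquisition (`NULL` for the default two-shell
#'   protocol)
#' @param fit_dwi also fit the free-water map (the slowest stage); when
#'   `FALSE` the WM FW value is derived from the phantom free-water truth
#' @return named list suitable for [build_subject_table()]
#' @export
measure_subject <- function(phantom, record, snr = Inf, pet_noise_sd = 0,
                            seed = 1, t2_model = t2_pool_model(),
                            dwi_acq = NULL, fit_dwi = TRUE) {
  m <- phantom$masks
  twc <- twc_constants()

  series <- simulate_multiecho(phantom, snr = snr, seed = seed)
  relax <- fit_t2_volume(series, t2_model)
  pcsf <- calibrate_fraction_map(relax$f_csf, m$gm, m$wm, twc)

  if (fit_dwi) {
    acq <- dwi_acq %||% default_dwi_acquisition()
    dwi <- simulate_dwi(phantom, acq, snr = snr, seed = child_seed(seed, 2))
    fw_fit <- fit_fw_volume(dwi)
    fw_map <- fw_fit$f_fw
  } else {
    fw_map <- phantom$fw_truth
  }
  fw <- calibrate_fraction_map(fw_map, m$gm, m$wm, twc)

  st <- simulate_structural(phantom, seed = child_seed(seed, 3))
  epc <- compute_epc(st$t1w, st$t2w, m$brain)
  ves <- frangi_vesselness(epc$data, voxel_size_mm = phantom$voxel_size_mm,
                           roi_mask = m$wm)
  pvs <- segment_pvs(ves, m$wm, m$wmh)

  pet <- simulate_pet(phantom, record$suvr_truth, noise_sd = pet_noise_sd,
                      seed = child_seed(seed, 4))

  list(id = record$id, age = record$age, sex = record$sex, dx = record$dx,
       apoe4 = record$apoe4,
       wm_pcsf = roi_mean(pcsf, m$wm, m$wmh),
       gm_pcsf = roi_mean(pcsf, m$gm),
       admask_pcsf = roi_mean(pcsf, m$admask),
       wm_fw = roi_mean(fw, m$wm, m$wmh),
       pvs_wmv = pvs_burden(pvs, m$wm, phantom$voxel_size_mm^3),
       suvr = compute_suvr(pet, m$admask, m$cerebellum_ref))
}

#' Detection power of the pipeline's statistical battery on synthetic cohorts
#'
#' Generates `n_replicates` independent cohorts at the study's group effect
#' sizes and, per replicate, tests (i) whether the planted WM pCSF group
#' difference is detected (normality-gated two-group test, p < `alpha`) and
#' (ii) whether the planted positive pCSF-to-SUVR association has its sign
#' recovered by the adjusted model `suvr ~ wm_pcsf + age + sex`. Subject
#' biomarkers enter at the cohort-model level (the image path is validated
#' separately to reproduce them exactly at high SNR).
#'
#' @param n_per_group subjects per diagnostic group
#' @param n_replicates number of cohort replicates
#' @param spec base [cohort_spec()] (sizes are overridden)
#' @param seed master seed
#' @param alpha detection level
#' @return list: `detect_rate_wm_pcsf`, `sign_rate_pcsf_suvr`, per-replicate
#'   logical vectors, `n_replicates`
#' @export
power_check <- function(n_per_group = 100, n_replicates = 100,
                        spec = cohort_spec(), seed = 1, alpha = 0.05) {
  detected <- logical(n_replicates)
  sign_ok <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    sp <- spec
    sp$n_nl <- n_per_group; sp$n_mciad <- n_per_group
    sp$seed <- child_seed(seed, r)
    cohort <- make_cohort(sp, make_phantoms = FALSE)
    tab <- cohort_truth_table(cohort)
    tab$suvr <- tab$suvr_truth
    gc <- group_compare(tab, "wm_pcsf", kind = "auto")
    detected[r] <- gc$p_value < alpha
    fit <- fit_linear_model(tab, "suvr", c("wm_pcsf", "age", "sex"))
    est <- fit$terms$estimate[fit$terms$term == "wm_pcsf"]
    sign_ok[r] <- est > 0
  }
  list(detect_rate_wm_pcsf = mean(detected),
       sign_rate_pcsf_suvr = mean(sign_ok),
       detected = detected, sign_ok = sign_ok,
       n_replicates = n_replicates)
}
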