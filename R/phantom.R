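#' Multi-echo T2 preparation times used by the FAST-T2 protocol
#'
#' Six T2prep times in milliseconds; the first echo has the preparation
#' turned off (t = 0), so its signal equals the proton-density scale M0.
#'
#' @return numeric vector of echo-preparation times (ms)
#' @export
default_t2prep_times <- function() c(0, 7.5, 17.5, 67.5, 147.5, 307.5)

# deterministic quasi-uniform unit directions (spherical Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Construct an MRI acquisition specification
#'
#' Bundles the T2prep echo times, the diffusion shells (b-values and unit
#' gradient directions) and the voxel size used by the simulators.
#'
#' @param t2prep_times_ms strictly increasing echo-preparation times, first 0
#' @param bvals b-values in s/mm^2, one per DWI volume (0 marks b=0 volumes)
#' @param bvecs n x 3 matrix of gradient directions; unit norm for b > 0
#' @param voxel_size_mm isotropic voxel spacing in mm
#' @return object of class `glymap_acquisition`
#' @export
acquisition_spec <- function(t2prep_times_ms = default_t2prep_times(),
                             bvals = NULL, bvecs = NULL, voxel_size_mm = 1) {
  t <- as.numeric(t2prep_times_ms)
  if (length(t) < 2 || t[1] != 0 || any(diff(t) <= 0))
    stop_invalid("t2prep_times_ms must be strictly increasing with first element 0")
  if (is.null(bvals) != is.null(bvecs))
    stop_invalid("bvals and bvecs must be supplied together")
  if (!is.null(bvals)) {
    bvecs <- as.matrix(bvecs)
    if (length(bvals) != nrow(bvecs))
      stop_invalid("length(bvals) must equal nrow(bvecs)")
    nz <- bvals > 0
    if (any(nz)) {
      nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        stop_invalid("nonzero-b gradient directions must have unit norm")
    }
  }
  structure(list(t2prep_times_ms = t, bvals = bvals, bvecs = bvecs,
                 voxel_size_mm = voxel_size_mm),
            class = "glymap_acquisition")
}

#' Two-shell diffusion acquisition matching the study protocol
#'
#' 49 quasi-uniform directions per shell at b = 1500 and 3000 s/mm^2
#' (98 diffusion-weighted volumes) plus `n_b0` b = 0 volumes.
#'
#' @param n_per_shell directions per shell
#' @param n_b0 number of b=0 volumes
#' @param shells nonzero b-values, s/mm^2
#' @param voxel_size_mm voxel spacing
#' @return `glymap_acquisition`
#' @export
default_dwi_acquisition <- function(n_per_shell = 49, n_b0 = 2,
                                    shells = c(1500, 3000), voxel_size_mm = 1) {
  dirs <- fibonacci_directions(n_per_shell)
  bvals <- c(rep(0, n_b0), rep(shells, each = n_per_shell))
  bvecs <- rbind(matrix(0, n_b0, 3),
                 do.call(rbind, rep(list(dirs), length(shells))))
  acquisition_spec(bvals = bvals, bvecs = bvecs, voxel_size_mm = voxel_size_mm)
}

#' Parameters of the synthetic brain phantom
#'
#' Defaults follow a concentric-shell geometry (ventricular CSF core, WM
#' shell, GM rind) with one straight-cylinder perivascular-space tubule and
#' one small WMH lesion embedded in WM. Compartment water fractions default
#' to (myelin, intra/extra-cellular, parenchymal CSF) = (0.12, 0.83, 0.05) in
#' WM and (0.03, 0.92, 0.05) in GM.
#'
#' @param fractions_wm,fractions_gm length-3 fraction vectors (sum to 1)
#' @param f_csf_pvs,f_csf_wmh elevated parenchymal-CSF fraction inside the
#'   PVS tubule and the WMH lesion
#' @param pvs_radius_vox,pvs_length_vox tubule radius and length in voxels
#' @param wmh_radius_vox WMH lesion radius in voxels
#' @param wm_eigenvalues diffusion-tensor eigenvalues in WM, mm^2/s
#'   (principal axis along x)
#' @param gm_md,csf_d isotropic diffusivities for GM tissue and CSF, mm^2/s
#' @param fw_wm,fw_gm free-water fraction ground truth in WM and GM
#' @param m0 proton-density scale inside the brain
#' @return list of phantom parameters
#' @export
phantom_spec <- function(fractions_wm = c(0.12, 0.83, 0.05),
                         fractions_gm = c(0.03, 0.92, 0.05),
                         f_csf_pvs = 0.30, f_csf_wmh = 0.15,
                         pvs_radius_vox = 1, pvs_length_vox = 10,
                         wmh_radius_vox = 2,
                         wm_eigenvalues = c(1.5, 0.4, 0.4) * 1e-3,
                         gm_md = 0.8e-3, csf_d = 3.0e-3,
                         fw_wm = 0.36, fw_gm = 0.15, m0 = 1) {
  for (f in list(fractions_wm, fractions_gm)) {
    if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop_invalid("compartment fractions must be nonnegative and sum to 1")
  }
  as.list(environment())
}

# analytic cylinder: voxels within `radius` of an x-aligned axis at (y0, z0),
# over `length` consecutive x planes starting at x0
cylinder_mask <- function(shape, x0, y0, z0, radius, length) {
  m <- array(FALSE, shape)
  xs <- x0:(x0 + length - 1)
  yy <- matrix(seq_len(shape[2]), shape[2], shape[3])
  zz <- matrix(seq_len(shape[3]), shape[2], shape[3], byrow = TRUE)
  disc <- (yy - y0)^2 + (zz - z0)^2 <= radius^2
  for (x in xs) m[x, , ] <- disc
  m
}

sphere_mask <- function(shape, center, radius) {
  g <- expand_grid_dist2(shape, center)
  array(g <= radius^2, shape)
}

# squared distance of every voxel center to `center`, as a 3D array
expand_grid_dist2 <- function(shape, center) {
  dx2 <- (seq_len(shape[1]) - center[1])^2
  dy2 <- (seq_len(shape[2]) - center[2])^2
  dz2 <- (seq_len(shape[3]) - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate a synthetic multi-compartment brain phantom
#'
#' Builds a concentric-shell brain — ventricular CSF core, white-matter
#' shell, grey-matter rind — on a shared 1 mm isotropic RAS grid, with
#' per-voxel ground truth for the three-pool water fractions, the tissue
#' diffusion tensor, the free-water fraction, and the masks the downstream
#' analysis consumes (GM, WM, WMH, PVS truth, cortical AD meta-ROI and
#' cerebellar reference). A straight-cylinder PVS tubule and a spherical WMH
#' lesion are embedded in WM so segmentation and exclusion rules can be
#' exercised against analytic truth.
#'
#' @param shape integer 3-vector of grid dimensions, each >= 16
#' @param spec phantom parameters from [phantom_spec()]
#' @param seed integer seed (stored; phantom geometry is deterministic)
#' @param voxel_size_mm isotropic voxel spacing
#' @return object of class `glymap_phantom` with elements `shape`, `labels`
#'   (0 background, 1 GM, 2 WM, 3 ventricular CSF), `masks` (list: `brain`,
#'   `gm`, `wm`, `wmh`, `pvs_truth`, `admask`, `cerebellum_ref`), `fractions`
#'   (list of arrays `f_mw`, `f_ie`, `f_csf` summing to 1 in-brain),
#'   `tissue_tensor` (x,y,z,6 array: Dxx,Dyy,Dzz,Dxy,Dxz,Dyz in mm^2/s),
#'   `fw_truth`, `m0`, `voxel_size_mm`, `seed`
#' @export
make_phantom <- function(shape = c(32, 32, 32), spec = phantom_spec(), seed = 1,
                         voxel_size_mm = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop_invalid("shape must be three dimensions, each >= 16")
  ctr <- (shape + 1) / 2
  R <- min(shape) / 2 - 1
  r <- sqrt(expand_grid_dist2(shape, ctr))

  brain <- r <= R
  csf   <- r <= 0.25 * R
  wm    <- r > 0.25 * R & r <= 0.70 * R
  gm    <- r > 0.70 * R & brain

  labels <- array(0L, shape)
  labels[gm] <- 1L; labels[wm] <- 2L; labels[csf] <- 3L

  # PVS tubule: x-aligned cylinder at mid-WM depth above the center
  d_wm <- 0.475 * R
  pvs <- cylinder_mask(shape,
                       x0 = round(ctr[1] - spec$pvs_length_vox / 2),
                       y0 = round(ctr[2]), z0 = round(ctr[3] + d_wm),
                       radius = spec$pvs_radius_vox,
                       length = spec$pvs_length_vox)
  if (any(pvs & !wm))
    stop_invalid("PVS tubule does not fit inside the WM shell; ",
                 "reduce its radius/length or enlarge the grid")

  # WMH lesion: small ball at mid-WM depth below the center
  wmh <- sphere_mask(shape, c(ctr[1], ctr[2], ctr[3] - d_wm), spec$wmh_radius_vox)
  if (any(wmh & !wm))
    stop_invalid("WMH lesion does not fit inside the WM shell")

  admask <- gm & outer(outer(seq_len(shape[1]) >= ctr[1] + 0.35 * R,
                             rep(TRUE, shape[2]), `&`),
                       rep(TRUE, shape[3]), `&`)
  cereb <- gm & outer(outer(rep(TRUE, shape[1]), rep(TRUE, shape[2]), `&`),
                      seq_len(shape[3]) <= ctr[3] - 0.35 * R, `&`)
  cereb <- cereb & !admask
  if (!any(admask) || !any(cereb))
    stop_invalid("grid too small to carve AD and cerebellar reference ROIs")

  f_mw <- array(0, shape); f_ie <- array(0, shape); f_csf <- array(0, shape)
  f_mw[wm] <- spec$fractions_wm[1]; f_ie[wm] <- spec$fractions_wm[2]
  f_csf[wm] <- spec$fractions_wm[3]
  f_mw[gm] <- spec$fractions_gm[1]; f_ie[gm] <- spec$fractions_gm[2]
  f_csf[gm] <- spec$fractions_gm[3]
  f_csf[csf] <- 1
  # fluid-rich structures: raise the long-T2 pool, take it out of the IE pool
  f_csf[pvs] <- spec$f_csf_pvs
  f_ie[pvs] <- 1 - f_mw[pvs] - spec$f_csf_pvs
  f_csf[wmh] <- spec$f_csf_wmh
  f_ie[wmh] <- 1 - f_mw[wmh] - spec$f_csf_wmh

  tensor <- array(0, c(shape, 6))
  idx <- function(k) slice.index(tensor, 4) == k
  put <- function(mask3, comps) {
    for (k in 1:6) {
      tk <- tensor[, , , k]; tk[mask3] <- comps[k]; tensor[, , , k] <<- tk
    }
  }
  put(wm, c(spec$wm_eigenvalues, 0, 0, 0))
  put(gm, c(rep(spec$gm_md, 3), 0, 0, 0))
  put(csf, c(rep(spec$csf_d, 3), 0, 0, 0))

  fw <- array(0, shape)
  fw[wm] <- spec$fw_wm; fw[gm] <- spec$fw_gm; fw[csf] <- 1
  m0 <- array(0, shape); m0[brain] <- spec$m0

  structure(list(shape = shape, labels = labels,
                 masks = list(brain = brain, gm = gm, wm = wm, wmh = wmh,
                              pvs_truth = pvs, admask = admask,
                              cerebellum_ref = cereb),
                 fractions = list(f_mw = f_mw, f_ie = f_ie, f_csf = f_csf),
                 tissue_tensor = tensor, fw_truth = fw, m0 = m0,
                 voxel_size_mm = voxel_size_mm, spec = spec,
                 seed = as.integer(seed)),
            class = "glymap_phantom")
}

#' Simulate a multi-echo T2prep series from a phantom
#'
#' Evaluates the three-pool exponential decay at each echo time and adds
#' Rician noise with per-voxel sigma = S(t=0)/snr. At `snr = Inf` the output
#' equals the forward model exactly.
#'
#' @param phantom `glymap_phantom`
#' @param acq `glymap_acquisition` carrying the T2prep times
#' @param snr signal-to-noise ratio at t = 0 (positive, may be `Inf`)
#' @param seed integer seed for the noise
#' @param t2_ms named vector of pool T2 values (ms), defaults mw 20 / ie 80 /
#'   csf 2000
#' @return object of class `glymap_multiecho`: 4D `data` (x,y,z,echo),
#'   `t2prep_times_ms`, `brain_mask`
#' @export
simulate_multiecho <- function(phantom, acq = acquisition_spec(), snr = Inf,
                               seed = 1, t2_ms = c(mw = 20, ie = 80, csf = 2000)) {
  if (!inherits(phantom, "glymap_phantom")) stop_invalid("phantom required")
  if (is.null(phantom$fractions$f_csf)) stop_invalid("phantom lacks fraction fields")
  times <- acq$t2prep_times_ms
  if (length(times) < 4) stop_invalid("need >= 4 echo times")
  if (!(snr > 0)) stop_invalid("snr must be positive")
  fr <- phantom$fractions
  data <- array(0, c(phantom$shape, length(times)))
  for (e in seq_along(times)) {
    t <- times[e]
    data[, , , e] <- phantom$m0 *
      (fr$f_mw * exp(-t / t2_ms[["mw"]]) +
       fr$f_ie * exp(-t / t2_ms[["ie"]]) +
       fr$f_csf * exp(-t / t2_ms[["csf"]]))
  }
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- phantom$m0 / snr
    for (e in seq_along(times))
      data[, , , e] <- add_rician_noise(data[, , , e], sigma)
  }
  structure(list(data = data, t2prep_times_ms = times,
                 brain_mask = phantom$masks$brain),
            class = "glymap_multiecho")
}

#' Simulate a two-shell diffusion-weighted series from a phantom
#'
#' Evaluates the bi-tensor free-water signal model per voxel and adds Rician
#' noise with sigma = S0/snr. Single-shell acquisitions are refused because
#' the bi-tensor model is not identifiable from one shell.
#'
#' @param phantom `glymap_phantom`
#' @param acq `glymap_acquisition` with bvals/bvecs (>= 2 nonzero shells,
#'   >= 6 unique nonzero directions)
#' @param snr SNR at b = 0 (positive, may be `Inf`)
#' @param seed noise seed
#' @param d_iso isotropic free-water diffusivity, mm^2/s
#' @return object of class `glymap_dwi`: 4D `data`, `bvals`, `bvecs`,
#'   `brain_mask`
#' @export
simulate_dwi <- function(phantom, acq = default_dwi_acquisition(), snr = Inf,
                         seed = 1, d_iso = 3.0e-3) {
  bvals <- acq$bvals; bvecs <- acq$bvecs
  if (is.null(bvals)) stop_invalid("acquisition has no diffusion shells")
  shells <- unique(bvals[bvals > 0])
  if (length(shells) < 2)
    stop_invalid("identifiability: bi-tensor simulation requires >= 2 nonzero shells")
  if (nrow(unique(round(bvecs[bvals > 0, , drop = FALSE], 6))) < 6)
    stop_invalid("need >= 6 unique nonzero gradient directions")
  if (!(snr > 0)) stop_invalid("snr must be positive")

  Dt <- phantom$tissue_tensor
  fw <- phantom$fw_truth
  data <- array(0, c(phantom$shape, length(bvals)))
  for (v in seq_along(bvals)) {
    b <- bvals[v]
    if (b == 0) { data[, , , v] <- phantom$m0; next }
    g <- bvecs[v, ]
    q <- Dt[, , , 1] * g[1]^2 + Dt[, , , 2] * g[2]^2 + Dt[, , , 3] * g[3]^2 +
      2 * (Dt[, , , 4] * g[1] * g[2] + Dt[, , , 5] * g[1] * g[3] +
           Dt[, , , 6] * g[2] * g[3])
    data[, , , v] <- phantom$m0 * ((1 - fw) * exp(-b * q) + fw * exp(-b * d_iso))
  }
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- phantom$m0 / snr
    for (v in seq_along(bvals))
      data[, , , v] <- add_rician_noise(data[, , , v], sigma)
  }
  structure(list(data = data, bvals = bvals, bvecs = bvecs,
                 brain_mask = phantom$masks$brain),
            class = "glymap_dwi")
}

#' Default structural contrast: per-label mean intensities
#'
#' PVS voxels are T2w-hyperintense and T1w-hypointense so the enhanced PVS
#' contrast (T1w/T2w ratio) is dark inside perivascular spaces; WMH lesions
#' are T2w-hyperintense.
#'
#' @param noise_sd additive Gaussian noise standard deviation
#' @return list of per-structure T1w/T2w mean intensities
#' @export
structural_contrast <- function(noise_sd = 1) {
  list(t1w = c(gm = 80, wm = 100, csf = 30, pvs = 60, wmh = 85),
       t2w = c(gm = 90, wm = 70, csf = 180, pvs = 140, wmh = 130),
       noise_sd = noise_sd)
}

#' Simulate co-registered T1w and T2w structural volumes
#'
#' Piecewise-constant intensities per structure plus additive Gaussian noise.
#' All modalities share the phantom grid (registration is identity).
#'
#' @param phantom `glymap_phantom`
#' @param contrast list from [structural_contrast()]
#' @param seed noise seed
#' @return list with 3D arrays `t1w` and `t2w`
#' @export
simulate_structural <- function(phantom, contrast = structural_contrast(), seed = 1) {
  if (any(contrast$t1w <= 0) || any(contrast$t2w <= 0))
    stop_invalid("structural intensity means must be positive")
  m <- phantom$masks
  paint <- function(means) {
    v <- array(0, phantom$shape)
    v[m$gm] <- means[["gm"]]; v[m$wm] <- means[["wm"]]
    v[phantom$labels == 3L] <- means[["csf"]]
    v[m$wmh] <- means[["wmh"]]; v[m$pvs_truth] <- means[["pvs"]]
    v
  }
  t1w <- paint(contrast$t1w); t2w <- paint(contrast$t2w)
  if (contrast$noise_sd > 0) {
    set.seed(seed)
    t1w <- t1w + array(stats::rnorm(length(t1w), 0, contrast$noise_sd), phantom$shape)
    t2w <- t2w + array(stats::rnorm(length(t2w), 0, contrast$noise_sd), phantom$shape)
  }
  list(t1w = t1w, t2w = t2w)
}

#' Simulate an amyloid PET uptake volume with a planted SUVR
#'
#' Constructs uptake with unit mean in the cerebellar reference region and
#' mean `suvr_truth` in the cortical AD meta-ROI, so the noise-free
#' target/reference ratio equals `suvr_truth` exactly. Gaussian noise is
#' added on top.
#'
#' @param phantom `glymap_phantom`
#' @param suvr_truth planted standardized uptake value ratio (> 0)
#' @param noise_sd additive Gaussian noise sd
#' @param seed noise seed
#' @return 3D uptake array
#' @export
simulate_pet <- function(phantom, suvr_truth, noise_sd = 0, seed = 1) {
  m <- phantom$masks
  if (!any(m$admask) || !any(m$cerebellum_ref))
    stop_invalid("AD and cerebellar reference masks must be nonempty")
  if (!(suvr_truth > 0)) stop_invalid("suvr_truth must be positive")
  pet <- array(0, phantom$shape)
  pet[m$brain] <- 1
  pet[m$admask] <- suvr_truth
  if (noise_sd > 0) {
    set.seed(seed)
    pet <- pet + array(stats::rnorm(length(pet), 0, noise_sd), phantom$shape)
  }
  pet
}

#' Cohort generation parameters
#'
#' Defaults encode the study's two diagnostic groups: 16 cognitively normal
#' (NL) and 13 MCI/Alzheimer's disease (MCIAD) subjects, with group biomarker
#' means and SDs (WM/GM pCSF, WM FW, PVS/WMV in percent; amyloid SUVR as a
#' ratio), age distributions, male fraction and APOE4 carrier probability per
#' group. A positive association between WM pCSF and SUVR is planted with
#' strength `slope_pcsf_suvr` (SUVR units per percentage point of pCSF).
#'
#' @param n_nl,n_mciad group sizes (>= 2)
#' @param group_means,group_sds per-group named biomarker vectors
#'   (wm_pcsf, gm_pcsf, wm_fw, pvs_wmv, suvr)
#' @param age_mean,age_sd per-group age distribution (years)
#' @param sex_prob_male,apoe4_prob per-group probabilities
#' @param slope_pcsf_suvr planted pCSF-to-SUVR slope
#' @param seed master seed
#' @return list of class `glymap_cohort_spec`
#' @export
cohort_spec <- function(n_nl = 16, n_mciad = 13,
                        group_means = list(
                          nl = c(wm_pcsf = 4.45, gm_pcsf = 4.41, wm_fw = 25.15,
                                 pvs_wmv = 1.52, suvr = 1.17),
                          mciad = c(wm_pcsf = 4.86, gm_pcsf = 4.83, wm_fw = 25.77,
                                    pvs_wmv = 1.68, suvr = 2.07)),
                        group_sds = list(
                          nl = c(wm_pcsf = 0.29, gm_pcsf = 0.31, wm_fw = 1.26,
                                 pvs_wmv = 0.43, suvr = 0.13),
                          mciad = c(wm_pcsf = 0.34, gm_pcsf = 0.36, wm_fw = 0.99,
                                    pvs_wmv = 0.49, suvr = 0.53)),
                        age_mean = c(nl = 67.69, mciad = 73.00),
                        age_sd = c(nl = 8.40, mciad = 8.54),
                        sex_prob_male = c(nl = 0.375, mciad = 0.385),
                        apoe4_prob = c(nl = 3 / 16, mciad = 9 / 13),
                        slope_pcsf_suvr = 0.25, seed = 1) {
  if (n_nl < 2 || n_mciad < 2) stop_invalid("group sizes must be >= 2")
  for (g in c("nl", "mciad")) {
    if (any(group_sds[[g]] <= 0)) stop_invalid("group sds must be positive")
  }
  if (any(c(sex_prob_male, apoe4_prob) < 0) || any(c(sex_prob_male, apoe4_prob) > 1))
    stop_invalid("probabilities must lie in [0,1]")
  structure(as.list(environment()), class = "glymap_cohort_spec")
}

#' Generate a synthetic cohort of subject records (and optional phantoms)
#'
#' Per-subject biomarker ground truths are drawn from the group normal
#' distributions in `spec`; the planted amyloid association sets
#' `suvr_truth = group SUVR mean + slope * (WM pCSF truth - group pCSF mean)
#' + residual`, with the residual variance chosen so the total SUVR SD
#' matches the group target. When `make_phantoms` is `TRUE`, each subject
#' receives a phantom whose fraction and free-water fields are rescaled so
#' its tissue ROI truths equal the subject's drawn values (the pCSF fraction
#' is the percent truth divided by the tissue total water content).
#'
#' @param spec `glymap_cohort_spec`
#' @param make_phantoms generate a per-subject phantom (heavier)
#' @param shape phantom grid when phantoms are generated
#' @param phantom_pars [phantom_spec()] used for per-subject phantoms
#' @return list of class `glymap_cohort`; each element has `record` (a
#'   one-row data.frame: id, age, sex, dx, apoe4, the biomarker truths and
#'   `suvr_truth`) and `phantom` (or `NULL`)
#' @export
make_cohort <- function(spec = cohort_spec(), make_phantoms = TRUE,
                        shape = c(32, 32, 32), phantom_pars = phantom_spec()) {
  groups <- c(rep("NL", spec$n_nl), rep("MCIAD", spec$n_mciad))
  n <- length(groups)
  out <- vector("list", n)
  twc <- twc_constants()
  for (i in seq_len(n)) {
    g <- if (groups[i] == "NL") "nl" else "mciad"
    mu <- spec$group_means[[g]]; sd <- spec$group_sds[[g]]
    set.seed(child_seed(spec$seed, i))
    wm_pcsf <- stats::rnorm(1, mu[["wm_pcsf"]], sd[["wm_pcsf"]])
    gm_pcsf <- stats::rnorm(1, mu[["gm_pcsf"]], sd[["gm_pcsf"]])
    wm_fw   <- stats::rnorm(1, mu[["wm_fw"]], sd[["wm_fw"]])
    pvs_wmv <- max(stats::rnorm(1, mu[["pvs_wmv"]], sd[["pvs_wmv"]]), 0.01)
    resid_sd <- sqrt(max(sd[["suvr"]]^2 -
                           spec$slope_pcsf_suvr^2 * sd[["wm_pcsf"]]^2,
                         0.04 * sd[["suvr"]]^2))
    suvr <- mu[["suvr"]] + spec$slope_pcsf_suvr * (wm_pcsf - mu[["wm_pcsf"]]) +
      stats::rnorm(1, 0, resid_sd)
    suvr <- max(suvr, 0.2)
    rec <- data.frame(
      id = sprintf("sub-%03d", i),
      age = max(stats::rnorm(1, spec$age_mean[[g]], spec$age_sd[[g]]), 40),
      sex = if (stats::runif(1) < spec$sex_prob_male[[g]]) "M" else "F",
      dx = groups[i],
      apoe4 = as.integer(stats::runif(1) < spec$apoe4_prob[[g]]),
      wm_pcsf = min(max(wm_pcsf, 0), 100),
      gm_pcsf = min(max(gm_pcsf, 0), 100),
      wm_fw = min(max(wm_fw, 0), 100),
      pvs_wmv = min(pvs_wmv, 100),
      suvr_truth = suvr,
      stringsAsFactors = FALSE)
    ph <- NULL
    if (make_phantoms) {
      ph <- make_phantom(shape, phantom_pars, seed = child_seed(spec$seed, i))
      ph <- rescale_phantom_truth(ph, rec, twc)
    }
    out[[i]] <- list(record = rec, phantom = ph)
  }
  structure(out, class = "glymap_cohort", seed = spec$seed)
}

# set a phantom's in-tissue fraction/FW fields so ROI truths match the record.
# The subject's WM pCSF is defined as the ROI mean over WM minus WMH (the
# quantity the pipeline measures); the fluid-rich PVS tubule keeps its own
# elevated fraction, so the plain-WM level is solved to hit the ROI mean.
rescale_phantom_truth <- function(phantom, record, twc = twc_constants()) {
  fr <- phantom$fractions
  m <- phantom$masks
  roi <- m$wm & !m$wmh
  plain_wm <- roi & !m$pvs_truth
  target_wm <- record$wm_pcsf / 100 / twc$wm
  n_roi <- sum(roi); n_pvs <- sum(roi & m$pvs_truth)
  f_plain <- (target_wm * n_roi - phantom$spec$f_csf_pvs * n_pvs) /
    (n_roi - n_pvs)
  if (f_plain < 0)
    stop_invalid("subject WM pCSF truth too low for the embedded PVS tubule")
  fr$f_csf[plain_wm] <- f_plain
  fr$f_csf[m$gm] <- record$gm_pcsf / 100 / twc$gm
  fr$f_ie <- ifelse(m$brain, 1 - fr$f_mw - fr$f_csf, 0)
  dim(fr$f_ie) <- phantom$shape
  if (any(fr$f_ie[m$brain] < 0))
    stop_invalid("subject truth implies negative intra/extra-cellular fraction")
  phantom$fractions <- fr
  phantom$fw_truth[roi] <- record$wm_fw / 100 / twc$wm
  phantom
}

#' Cohort ground-truth covariate table
#'
#' @param cohort `glymap_cohort`
#' @return data.frame, one row per subject
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "record"))
}
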