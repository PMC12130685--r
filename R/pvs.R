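# separable Gaussian smoothing and Hessian filtering -------------------------

gaussian_kernel <- function(sigma_vox, order = 0) {
  r <- max(2L, ceiling(4 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  switch(order + 1L,
         g,
         -x / sigma_vox^2 * g,
         (x^2 - sigma_vox^2) / sigma_vox^4 * g)
}

# shift a 3D array by `s` voxels along `axis`, replicating edges
shift_array <- function(a, axis, s) {
  d <- dim(a)
  i <- pmin(pmax(seq_len(d[axis]) + s, 1L), d[axis])
  switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
         a[, , i, drop = FALSE])
}

convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * shift_array(a, axis, j - 1L - r)
  out
}

#' Separable 3D Gaussian smoothing
#'
#' @param volume 3D array
#' @param sigma_vox Gaussian standard deviation in voxels
#' @return smoothed array
#' @export
gaussian_smooth3 <- function(volume, sigma_vox) {
  k <- gaussian_kernel(sigma_vox)
  for (ax in 1:3) volume <- convolve_axis(volume, k, ax)
  volume
}

# Gaussian-scale-space Hessian via separable convolution with analytic
# Gaussian-derivative kernels (the canonical vesselness construction);
# derivative orders per axis are (2,0,0) for xx, (1,1,0) for xy, etc.
# `h` is the voxel spacing in mm; derivatives are per mm.
hessian3 <- function(volume, sigma_vox, h) {
  sep <- function(ox, oy, oz) {
    a <- convolve_axis(volume, gaussian_kernel(sigma_vox, ox), 1)
    a <- convolve_axis(a, gaussian_kernel(sigma_vox, oy), 2)
    a <- convolve_axis(a, gaussian_kernel(sigma_vox, oz), 3)
    a / h^(ox + oy + oz)
  }
  list(xx = sep(2, 0, 0), yy = sep(0, 2, 0), zz = sep(0, 0, 2),
       xy = sep(1, 1, 0), xz = sep(1, 0, 1), yz = sep(0, 1, 1))
}

# vectorized eigenvalues of symmetric 3x3 matrices given component arrays
# (analytic method via the characteristic polynomial in trigonometric form)
sym3_eigenvalues <- function(H) {
  a <- H$xx; b <- H$yy; c <- H$zz; d <- H$xy; e <- H$xz; f <- H$yz
  p1 <- d^2 + e^2 + f^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  safe_p <- ifelse(p > 0, p, 1)
  ba <- (a - q) / safe_p; bb <- (b - q) / safe_p; bc <- (c - q) / safe_p
  bd <- d / safe_p; be <- e / safe_p; bf <- f / safe_p
  detB <- ba * (bb * bc - bf^2) - bd * (bd * bc - bf * be) +
    be * (bd * bf - bb * be)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  zero <- p2 <= 0
  l1[zero] <- q[zero]; l2[zero] <- q[zero]; l3[zero] <- q[zero]
  list(l1, l2, l3)
}

#' Frangi vesselness filter parameters
#'
#' Defaults follow the classical construction: alpha = beta = 0.5, the
#' structureness constant c set per scale to half the maximum Frobenius norm
#' of the Hessian, scales 0.5/1.0/1.5 mm, and dark-tube polarity (on the
#' enhanced PVS contrast, perivascular spaces are T2w-bright, hence
#' EPC-dark).
#'
#' @param scales_mm Gaussian scales in mm (> 0)
#' @param alpha plate/line sensitivity (> 0)
#' @param beta blob sensitivity (> 0)
#' @param c structureness sensitivity, or `NULL` for the per-scale automatic
#'   value
#' @param polarity `"dark"` for dark tubes on bright background, `"bright"`
#'   for the opposite
#' @return list of class `glymap_vesselness_params`
#' @export
vesselness_params <- function(scales_mm = c(0.5, 1.0, 1.5), alpha = 0.5,
                              beta = 0.5, c = NULL,
                              polarity = c("dark", "bright")) {
  if (any(scales_mm <= 0) || alpha <= 0 || beta <= 0)
    stop_invalid("scales, alpha and beta must be positive")
  structure(list(scales_mm = scales_mm, alpha = alpha, beta = beta, c = c,
                 polarity = match.arg(polarity)),
            class = "glymap_vesselness_params")
}

#' Multi-scale Frangi vesselness
#'
#' Hessian-eigenvalue tubularity measure: with |l1| <= |l2| <= |l3|,
#' V = (1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) *
#' (1 - exp(-S^2 / 2 c^2)) where Ra = |l2|/|l3| separates tubes from plates,
#' Rb = |l1|/sqrt(|l2 l3|) suppresses blobs and S is the Frobenius norm of
#' the Hessian. Voxels violating the tube polarity (dark tubes need
#' l2, l3 > 0; bright tubes l2, l3 < 0) get 0. The Hessian is computed at
#' each Gaussian scale with sigma^2 scale normalization and the voxelwise
#' maximum over scales is returned.
#'
#' When `roi_mask` is given, voxels outside the ROI are replaced by the ROI
#' median before filtering and the automatic `c` is taken from the ROI.
#' PVS segmentation is WM-restricted, so this stops strong tissue-boundary
#' Hessians (ventricle and cortical edges) from dominating the structureness
#' normalization and suppressing the much weaker tubule responses.
#'
#' @param volume 3D image
#' @param params [vesselness_params()]
#' @param voxel_size_mm isotropic voxel spacing; scales are interpreted in mm
#' @param roi_mask optional logical array restricting the filter's context
#' @return vesselness map in [0,1], same shape as `volume`
#' @export
frangi_vesselness <- function(volume, params = vesselness_params(),
                              voxel_size_mm = 1, roi_mask = NULL) {
  if (length(dim(volume)) != 3) stop_invalid("volume must be 3D")
  if (!is.null(roi_mask)) {
    check_same_grid(volume, roi_mask, what = "volume/roi")
    fill <- stats::median(volume[roi_mask])
    volume[!roi_mask] <- fill
  }
  if (length(voxel_size_mm) > 1 && length(unique(voxel_size_mm)) > 1)
    warning("anisotropic voxels: scales are interpreted along each axis in mm ",
            "without resampling")
  h <- voxel_size_mm[1]
  best <- array(0, dim(volume))
  for (sigma_mm in params$scales_mm) {
    H <- hessian3(volume, sigma_mm / h, h)
    for (k in names(H)) H[[k]] <- H[[k]] * sigma_mm^2  # scale normalization
    ev <- sym3_eigenvalues(H)
    abs_ev <- lapply(ev, abs)
    # sort voxelwise by |eigenvalue|
    ord <- function(i) {
      m <- cbind(as.numeric(abs_ev[[1]]), as.numeric(abs_ev[[2]]),
                 as.numeric(abs_ev[[3]]))
      v <- cbind(as.numeric(ev[[1]]), as.numeric(ev[[2]]), as.numeric(ev[[3]]))
      o <- t(apply(m, 1, order))
      list(sabs = matrix(m[cbind(rep(seq_len(nrow(m)), 3),
                                 as.numeric(o))], ncol = 3),
           sval = matrix(v[cbind(rep(seq_len(nrow(m)), 3),
                                 as.numeric(o))], ncol = 3))
    }
    s <- ord()
    a1 <- s$sabs[, 1]; a2 <- s$sabs[, 2]; a3 <- s$sabs[, 3]
    v2 <- s$sval[, 2]; v3 <- s$sval[, 3]
    S2 <- a1^2 + a2^2 + a3^2
    cpar <- params$c %||%
      (sqrt(max(if (is.null(roi_mask)) S2 else S2[as.vector(roi_mask)])) / 2)
    if (cpar <= 0) next
    ra2 <- (a2 / pmax(a3, .Machine$double.eps))^2
    rb2 <- a1^2 / pmax(a2 * a3, .Machine$double.eps)
    V <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
      exp(-rb2 / (2 * params$beta^2)) *
      (1 - exp(-S2 / (2 * cpar^2)))
    bad <- if (params$polarity == "dark") (v2 <= 0 | v3 <= 0) else (v2 >= 0 | v3 >= 0)
    V[bad | a3 <= .Machine$double.eps] <- 0
    V <- array(pmin(pmax(V, 0), 1), dim(volume))
    best <- pmax(best, V)
  }
  best
}

#' Label connected components of a 3D binary mask (26-connectivity)
#'
#' 26-connectivity keeps thin oblique tubes connected, which fragment under
#' 6-connectivity.
#'
#' @param mask logical 3D array
#' @return integer array; 0 background, components numbered from 1
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  idx_all <- which(mask)
  nextlab <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (cur - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (cur - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1L
      x <- rem %% d[1] + 1L
      nx <- x + off[, 1]; ny <- y + off[, 2]; nz <- z + off[, 3]
      ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
      ni <- (nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]
      ni <- ni[mask[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- nextlab
        queue <- c(queue, ni)
      }
    }
  }
  lab
}

#' Enhanced PVS contrast (EPC) from T1w and T2w volumes
#'
#' EPC = T1w / max(T2w, eps) inside the brain mask. Voxels whose T2w value
#' was clipped by `eps` are flagged.
#'
#' @param t1w,t2w 3D volumes on the same grid
#' @param brain_mask logical array
#' @param eps denominator floor (> 0)
#' @return list of class `glymap_epc`: `data`, `brain_mask`, `clipped`
#' @export
compute_epc <- function(t1w, t2w, brain_mask, eps = 1e-6) {
  if (eps <= 0) stop_invalid("eps must be positive")
  check_same_grid(t1w, t2w, brain_mask, what = "T1w/T2w/mask")
  data <- array(0, dim(t1w))
  clipped <- array(FALSE, dim(t1w))
  data[brain_mask] <- t1w[brain_mask] / pmax(t2w[brain_mask], eps)
  clipped[brain_mask] <- t2w[brain_mask] < eps
  structure(list(data = data, brain_mask = brain_mask, clipped = clipped),
            class = "glymap_epc")
}

#' Segment perivascular spaces from a vesselness map
#'
#' Thresholds the vesselness map, restricts to WM, excludes WMH voxels and
#' removes clusters smaller than `min_cluster_voxels` (26-connectivity).
#'
#' @param vesselness map in [0,1]
#' @param wm_mask white-matter mask (nonempty)
#' @param wmh_mask WMH exclusion mask, or `NULL`
#' @param threshold vesselness cut in (0,1)
#' @param min_cluster_voxels minimum connected-cluster size retained
#' @return logical PVS mask
#' @export
segment_pvs <- function(vesselness, wm_mask, wmh_mask = NULL, threshold = 0.2,
                        min_cluster_voxels = 2) {
  if (!any(wm_mask)) stop_invalid("WM mask is empty")
  if (threshold <= 0 || threshold >= 1) stop_invalid("threshold must be in (0,1)")
  check_same_grid(vesselness, wm_mask, what = "vesselness/masks")
  mask <- (vesselness >= threshold) & wm_mask
  if (!is.null(wmh_mask)) mask <- mask & !wmh_mask
  if (min_cluster_voxels > 1 && any(mask)) {
    lab <- label_components(mask)
    keep <- which(tabulate(lab[lab > 0]) >= min_cluster_voxels)
    mask <- array(lab %in% keep, dim(mask))
  }
  mask
}

#' PVS burden: segmented PVS volume as a percentage of WM volume
#'
#' @param pvs_mask logical PVS mask
#' @param wm_mask logical WM mask (nonempty)
#' @param voxel_volume_mm3 voxel volume (cancels in the ratio)
#' @return burden in percent, 100 * |PVS| / |WM|
#' @export
pvs_burden <- function(pvs_mask, wm_mask, voxel_volume_mm3 = 1) {
  n_wm <- sum(wm_mask)
  if (n_wm == 0) stop_invalid("WM mask is empty")
  100 * (sum(pvs_mask) * voxel_volume_mm3) / (n_wm * voxel_volume_mm3)
}
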