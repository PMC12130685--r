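# tensor helpers ------------------------------------------------------------

as_tensor_matrix <- function(d) {
  if (is.matrix(d)) {
    if (!all(dim(d) == c(3, 3)) || max(abs(d - t(d))) > 1e-12)
      stop_invalid("tensor must be a symmetric 3x3 matrix")
    return(d)
  }
  if (length(d) != 6) stop_invalid("tensor must be 3x3 or a 6-vector")
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

#' Bi-tensor free-water signal model
#'
#' S = S0 * ((1 - f) exp(-b g' D g) + f exp(-b d_iso)): an anisotropic tissue
#' tensor plus an isotropic free-water pool with diffusivity `d_iso`
#' (body-temperature free water, 3.0e-3 mm^2/s by default). At b = 0 the
#' signal equals `s0` regardless of `f_fw`.
#'
#' @param d_tissue symmetric 3x3 tissue tensor (mm^2/s), or 6-vector
#'   (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz); must be positive semi-definite
#' @param f_fw free-water fraction in [0,1]
#' @param s0 b = 0 signal
#' @param bvals,bvecs acquisition shells and unit directions
#' @param d_iso isotropic diffusivity (mm^2/s), > 0
#' @return signal vector
#' @export
bitensor_signal <- function(d_tissue, f_fw, s0, bvals, bvecs, d_iso = 3.0e-3) {
  D <- as_tensor_matrix(d_tissue)
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop_invalid("tissue tensor must be positive semi-definite")
  if (d_iso <= 0) stop_invalid("d_iso must be positive")
  if (f_fw < 0 || f_fw > 1) stop_invalid("f_fw must lie in [0,1]")
  bvecs <- as.matrix(bvecs)
  q <- rowSums((bvecs %*% D) * bvecs)
  as.numeric(s0 * ((1 - f_fw) * exp(-bvals * q) + f_fw * exp(-bvals * d_iso)))
}

#' Fractional anisotropy of a diffusion tensor
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda|| from the tensor
#' eigenvalues; 0 for an isotropic tensor, 1 in the stick limit, and 0 by
#' convention for the all-zero tensor. Rotation-invariant.
#'
#' @param d_tissue symmetric 3x3 tensor or 6-vector
#' @return FA in [0,1]
#' @export
compute_fa <- function(d_tissue) {
  D <- as_tensor_matrix(d_tissue)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ss <- sum(ev^2)
  if (ss == 0) return(0)
  fa <- sqrt(1.5 * sum((ev - mean(ev))^2) / ss)
  min(max(fa, 0), 1)
}

# log-linear single-tensor fit used for initialization
loglinear_tensor_fit <- function(signal, bvals, bvecs) {
  ok <- signal > 0
  X <- cbind(1, -bvals * bvecs[, 1]^2, -bvals * bvecs[, 2]^2,
             -bvals * bvecs[, 3]^2,
             -2 * bvals * bvecs[, 1] * bvecs[, 2],
             -2 * bvals * bvecs[, 1] * bvecs[, 3],
             -2 * bvals * bvecs[, 2] * bvecs[, 3])
  beta <- stats::lm.fit(X[ok, , drop = FALSE], log(signal[ok]))$coefficients
  list(s0 = exp(beta[1]), d6 = beta[2:7])
}

# Cholesky factorisation with PSD projection; D = L L', L lower-triangular.
# Internal scale: tensors are handled in units of 1e-3 mm^2/s so optimizer
# parameters are O(1).
TENSOR_SCALE <- 1e-3

chol_from_tensor <- function(d6) {
  D <- as_tensor_matrix(d6) / TENSOR_SCALE
  e <- eigen(D, symmetric = TRUE)
  ev <- pmax(e$values, 1e-4)
  L <- t(chol(e$vectors %*% diag(ev) %*% t(e$vectors)))
  L[lower.tri(L, diag = TRUE)]
}

tensor_from_chol <- function(l6) {
  L <- matrix(0, 3, 3)
  L[lower.tri(L, diag = TRUE)] <- l6
  D <- L %*% t(L) * TENSOR_SCALE
  c(D[1, 1], D[2, 2], D[3, 3], D[2, 1], D[3, 1], D[3, 2])
}

fw_residual <- function(theta, signal, bvals, bvecs, d_iso) {
  f <- theta[1]; s0 <- theta[2]
  d6 <- tensor_from_chol(theta[3:8])
  D <- as_tensor_matrix(d6)
  q <- rowSums((bvecs %*% D) * bvecs)
  s0 * ((1 - f) * exp(-bvals * q) + f * exp(-bvals * d_iso)) - signal
}

#' Options for the free-water fit
#'
#' @param d_iso isotropic free-water diffusivity (mm^2/s)
#' @param f_init initial free-water fraction
#' @param maxiter Levenberg-Marquardt iteration cap
#' @return list
#' @export
fw_fit_options <- function(d_iso = 3.0e-3, f_init = 0.1, maxiter = 300) {
  list(d_iso = d_iso, f_init = f_init, maxiter = maxiter)
}

#' Fit the bi-tensor free-water model to one voxel
#'
#' Bounded nonlinear least squares over the free-water fraction, the b = 0
#' signal and the tissue tensor; the tensor is parameterized by its Cholesky
#' factor so positive semi-definiteness is enforced without constraints.
#' Initialization is a log-linear single-tensor fit with f0 = `f_init`.
#' Two distinct nonzero shells are required: the bi-tensor model is not
#' identifiable from a single shell.
#'
#' @param signal measured magnitudes, one per volume (nonnegative)
#' @param bvals,bvecs acquisition (must include b = 0, two nonzero shells and
#'   >= 6 unique nonzero directions)
#' @param opts [fw_fit_options()]
#' @return list of class `glymap_fwfit`: `f_fw`, `d_tissue` (3x3, mm^2/s),
#'   `fa`, `s0`, `objective`, `converged`
#' @export
fit_fw_voxel <- function(signal, bvals, bvecs, opts = fw_fit_options()) {
  bvecs <- as.matrix(bvecs)
  shells <- unique(bvals[bvals > 0])
  if (length(shells) < 2)
    stop_invalid("identifiability: the bi-tensor fit requires >= 2 nonzero shells")
  if (nrow(unique(round(bvecs[bvals > 0, , drop = FALSE], 6))) < 6)
    stop_invalid("need >= 6 unique nonzero gradient directions")
  if (any(signal < 0)) stop_invalid("negative signal values")
  if (all(signal == 0)) {
    return(structure(list(f_fw = 0, d_tissue = matrix(0, 3, 3), fa = 0,
                          s0 = 0, objective = 0, converged = FALSE),
                     class = "glymap_fwfit"))
  }
  init <- loglinear_tensor_fit(pmax(signal, 1e-12), bvals, bvecs)
  theta0 <- c(opts$f_init, init$s0, chol_from_tensor(init$d6))
  lower <- c(0, 1e-12, rep(-Inf, 6))
  upper <- c(1, Inf, rep(Inf, 6))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                       fn = fw_residual, signal = signal, bvals = bvals,
                       bvecs = bvecs, d_iso = opts$d_iso,
                       control = minpack.lm::nls.lm.control(
                         maxiter = opts$maxiter, ftol = 1e-14, ptol = 1e-13)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(f_fw = opts$f_init,
                          d_tissue = as_tensor_matrix(init$d6), fa = NA_real_,
                          s0 = init$s0, objective = NA_real_,
                          converged = FALSE),
                     class = "glymap_fwfit"))
  }
  par <- unname(fit$par)
  d6 <- tensor_from_chol(par[3:8])
  D <- as_tensor_matrix(d6)
  structure(list(f_fw = par[1], d_tissue = D, fa = compute_fa(D),
                 s0 = par[2], objective = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4),
            class = "glymap_fwfit")
}

#' Voxelwise free-water mapping over a DWI series
#'
#' Independent per-voxel bi-tensor fits inside the brain mask; non-converged
#' voxels are recorded in the failure mask. An empty mask yields empty (zero)
#' maps without error.
#'
#' @param series `glymap_dwi` (or list with `data`, `bvals`, `bvecs`,
#'   `brain_mask`)
#' @param opts [fw_fit_options()]
#' @return list of class `glymap_fwmaps`: `f_fw` map, `fa` map,
#'   `failure_mask`, `brain_mask`
#' @export
fit_fw_volume <- function(series, opts = fw_fit_options()) {
  data <- series$data
  mask <- series$brain_mask
  shape <- dim(data)[1:3]
  if (!all(dim(mask) == shape)) stop_invalid("mask does not match the DWI grid")
  nvol <- dim(data)[4]
  if (nvol != length(series$bvals)) stop_invalid("bvals do not match volumes")
  f_map <- array(0, shape); fa_map <- array(0, shape)
  fail <- array(FALSE, shape)
  idx <- which(mask)
  nvox <- prod(shape)
  for (ii in idx) {
    sig <- data[ii + (seq_len(nvol) - 1L) * nvox]
    fit <- fit_fw_voxel(sig, series$bvals, series$bvecs, opts)
    f_map[ii] <- fit$f_fw; fa_map[ii] <- fit$fa
    fail[ii] <- !fit$converged
  }
  structure(list(f_fw = f_map, fa = fa_map, failure_mask = fail,
                 brain_mask = mask),
            class = "glymap_fwmaps")
}
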