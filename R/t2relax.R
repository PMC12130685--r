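#' Three-pool T2 relaxometry model configuration
#'
#' The voxel signal is modelled as a sum of three water pools — myelin water
#' (short T2), intra/extra-cellular water (intermediate T2) and parenchymal
#' CSF (long T2, 200-2000 ms). The parenchymal CSF fraction (pCSFF) is the
#' long-T2 fraction. Fitting is bounded nonlinear least squares with an L2
#' penalty pulling the fraction vector toward a prior, which stabilizes the
#' ill-posed long-T2 estimation from only six echoes.
#'
#' With only six echoes the pool T2s themselves are barely identifiable:
#' jointly fitting them inflates the pCSFF error severalfold through the
#' f_csf/T2_ie trade-off. Following common practice for few-echo
#' multicompartment T2 mapping, the pool T2s are therefore fixed at their
#' literature values by default (`fit_pool_t2s = FALSE`) and only the pool
#' amplitudes are estimated; bounded estimation of the MW/IE T2s remains
#' available via `fit_pool_t2s = TRUE`.
#'
#' @param t2_bounds_ms per-pool T2 bounds (ms); must be nested and
#'   non-overlapping, CSF upper bound 2000 ms
#' @param t2_init_ms per-pool T2 initial (or fixed) values (ms)
#' @param csf_t2_fixed keep the CSF T2 fixed at its initial value (2000 ms by
#'   default); a 307.5 ms maximum echo cannot resolve T2s far beyond the
#'   sampling window
#' @param fit_pool_t2s estimate the MW/IE T2s within bounds instead of
#'   fixing them at `t2_init_ms`
#' @param lambda L2 regularization weight; `NULL` means 0.01 * ||signal||^2,
#'   computed per voxel at fit time
#' @param f_prior prior fractions (mw, ie, csf), summing to 1
#' @return list of class `glymap_t2_model`
#' @export
t2_pool_model <- function(t2_bounds_ms = list(mw = c(5, 40), ie = c(40, 200),
                                              csf = c(200, 2000)),
                          t2_init_ms = c(mw = 20, ie = 80, csf = 2000),
                          csf_t2_fixed = TRUE, fit_pool_t2s = FALSE,
                          lambda = NULL,
                          f_prior = c(0.10, 0.85, 0.05)) {
  b <- t2_bounds_ms
  if (b$mw[2] > b$ie[1] || b$ie[2] > b$csf[1])
    stop_invalid("pool T2 bounds must be non-overlapping and ordered mw < ie < csf")
  if (abs(sum(f_prior) - 1) > 1e-9) stop_invalid("f_prior must sum to 1")
  if (!is.null(lambda) && lambda < 0) stop_invalid("lambda must be >= 0")
  structure(list(t2_bounds_ms = b, t2_init_ms = t2_init_ms,
                 csf_t2_fixed = csf_t2_fixed, fit_pool_t2s = fit_pool_t2s,
                 lambda = lambda, f_prior = f_prior),
            class = "glymap_t2_model")
}

#' Three-pool T2 decay forward model
#'
#' S(t) = M0 * (f_mw exp(-t/T2_mw) + f_ie exp(-t/T2_ie) + f_csf exp(-t/T2_csf)).
#' At t = 0 the signal equals M0.
#'
#' @param f length-3 fractions (mw, ie, csf), nonnegative, summing to 1
#' @param t2_ms length-3 positive pool T2 values (ms)
#' @param m0 proton-density scale
#' @param times echo-preparation times (ms), nonnegative
#' @return signal vector, one value per echo time
#' @export
predict_t2_signal <- function(f, t2_ms, m0, times) {
  if (any(t2_ms <= 0)) stop_invalid("all T2 values must be positive")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-6)
    stop_invalid("fractions must be nonnegative and sum to 1")
  if (any(times < 0)) stop_invalid("echo times must be nonnegative")
  as.numeric(m0 * (exp(outer(-times, 1 / t2_ms)) %*% f))
}

# residual vector for the penalized fit; theta = (a_mw, a_ie, a_csf,
# <free pool T2s, if any>); `free_t2` flags which of (mw, ie, csf) are fitted
t2_residual <- function(theta, signal, times, f_prior, lambda, free_t2,
                        t2_fixed_ms) {
  a <- theta[1:3]
  t2 <- t2_fixed_ms
  if (any(free_t2)) t2[free_t2] <- theta[-(1:3)]
  s <- sum(a)
  f <- if (s > 0) a / s else f_prior
  model <- as.numeric(exp(outer(-times, 1 / t2)) %*% a)
  c(model - signal, sqrt(lambda) * (f - f_prior))
}

#' Fit the three-pool T2 model to one voxel
#'
#' Penalized bounded least squares: minimizes
#' ||S_model - S_data||^2 + lambda * ||f - f_prior||^2 over pool amplitudes
#' and the free pool T2s (Levenberg-Marquardt with box bounds), with three
#' deterministic multi-starts (prior-weighted, CSF-heavy, MW-heavy) because
#' multi-exponential objectives are multi-modal. Ties are broken by lowest
#' objective, then lexicographic parameter order. All-zero signals are
#' flagged as fit failures and carry the prior fractions.
#'
#' @param signal magnitude signal vector (same length as `times`, >= 4)
#' @param times echo times (ms)
#' @param model `glymap_t2_model`
#' @return list of class `glymap_voxelfit`: `f_mw`, `f_ie`, `f_csf` (the last
#'   is the pCSFF), `t2_mw`, `t2_ie`, `t2_csf` (ms), `m0`, `objective`,
#'   `converged`
#' @export
fit_t2_voxel <- function(signal, times, model = t2_pool_model()) {
  if (length(signal) != length(times) || length(signal) < 4)
    stop_invalid("signal and times must match, with >= 4 echoes")
  if (any(!is.finite(signal))) stop_invalid("non-finite signal values")
  if (all(signal == 0)) {
    return(structure(list(f_mw = model$f_prior[1], f_ie = model$f_prior[2],
                          f_csf = model$f_prior[3],
                          t2_mw = model$t2_init_ms[["mw"]],
                          t2_ie = model$t2_init_ms[["ie"]],
                          t2_csf = model$t2_init_ms[["csf"]],
                          m0 = 0, objective = 0, converged = FALSE),
                     class = "glymap_voxelfit"))
  }
  lambda <- model$lambda %||% (0.01 * sum(signal^2))
  b <- model$t2_bounds_ms
  s0 <- max(signal[1], max(signal))
  starts <- list(model$f_prior, c(0.10, 0.50, 0.40), c(0.40, 0.50, 0.10))
  t2_init <- model$t2_init_ms
  free_t2 <- c(model$fit_pool_t2s, model$fit_pool_t2s, !model$csf_t2_fixed)

  lower <- c(0, 0, 0, c(b$mw[1], b$ie[1], b$csf[1])[free_t2])
  upper <- c(Inf, Inf, Inf, c(b$mw[2], b$ie[2], b$csf[2])[free_t2])

  best <- NULL
  for (f0 in starts) {
    theta0 <- c(f0 * s0, unname(t2_init)[free_t2])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = t2_residual, signal = signal, times = times,
                         f_prior = model$f_prior, lambda = lambda,
                         free_t2 = free_t2, t2_fixed_ms = unname(t2_init),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj - 1e-15 ||
        (abs(obj - best$obj) <= 1e-15 &&
         isTRUE(all(fit$par < best$par)[1]))) {
      best <- list(obj = obj, par = fit$par, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(structure(list(f_mw = model$f_prior[1], f_ie = model$f_prior[2],
                          f_csf = model$f_prior[3],
                          t2_mw = t2_init[["mw"]], t2_ie = t2_init[["ie"]],
                          t2_csf = t2_init[["csf"]], m0 = s0,
                          objective = NA_real_, converged = FALSE),
                     class = "glymap_voxelfit"))
  }
  a <- best$par[1:3]
  m0 <- sum(a)
  f <- if (m0 > 0) a / m0 else model$f_prior
  t2 <- unname(t2_init)
  if (any(free_t2)) t2[free_t2] <- best$par[-(1:3)]
  structure(list(f_mw = f[1], f_ie = f[2], f_csf = f[3],
                 t2_mw = t2[1], t2_ie = t2[2], t2_csf = t2[3],
                 m0 = m0, objective = best$obj,
                 converged = best$info %in% 1:4),
            class = "glymap_voxelfit")
}

#' Fit the three-pool model voxelwise over a multi-echo series
#'
#' Independent per-voxel fits inside the brain mask; voxel order does not
#' affect the result. Non-converged voxels carry the prior fractions and are
#' recorded in the failure mask instead of aborting the volume.
#'
#' @param series `glymap_multiecho` (or list with `data`, `t2prep_times_ms`,
#'   `brain_mask`)
#' @param model `glymap_t2_model`
#' @return list of class `glymap_relaxometry`: volumes `f_mw`, `f_ie`,
#'   `f_csf` (pCSFF map), `m0`, `t2_mw`, `t2_ie`, plus `failure_mask` and the
#'   input `brain_mask`
#' @export
fit_t2_volume <- function(series, model = t2_pool_model()) {
  data <- series$data; times <- series$t2prep_times_ms
  if (dim(data)[4] != length(times))
    stop_invalid("echo dimension does not match the echo-time list")
  mask <- series$brain_mask
  if (!any(mask)) stop_invalid("brain mask is empty")
  shape <- dim(data)[1:3]
  vol <- function() array(0, shape)
  maps <- list(f_mw = vol(), f_ie = vol(), f_csf = vol(), m0 = vol(),
               t2_mw = vol(), t2_ie = vol())
  fail <- array(FALSE, shape)
  idx <- which(mask)
  nvox <- prod(shape)
  for (ii in idx) {
    sig <- data[ii + (seq_along(times) - 1L) * nvox]
    fit <- fit_t2_voxel(sig, times, model)
    maps$f_mw[ii] <- fit$f_mw; maps$f_ie[ii] <- fit$f_ie
    maps$f_csf[ii] <- fit$f_csf; maps$m0[ii] <- fit$m0
    maps$t2_mw[ii] <- fit$t2_mw; maps$t2_ie[ii] <- fit$t2_ie
    fail[ii] <- !fit$converged
  }
  structure(c(maps, list(failure_mask = fail, brain_mask = mask)),
            class = "glymap_relaxometry")
}
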