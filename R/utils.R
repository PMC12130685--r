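#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible child seed from a master seed
#'
#' One master seed spawns independent per-subject (or per-replicate) seeds by
#' fixed integer arithmetic, so cohorts are reproducible while subjects stay
#' independent. The result is always a positive integer below 2^31.
#'
#' @param master integer master seed
#' @param i index (1-based) of the child stream
#' @return integer seed
#' @export
child_seed <- function(master, i) {
  stopifnot(is.numeric(master), is.numeric(i))
  as.integer((as.numeric(master) * 1009 + as.numeric(i) * 99991) %% 2147483647L) + 1L
}

#' Add Rician noise to a magnitude signal
#'
#' Magnitude-MRI noise: the observed value is the modulus of the complex
#' signal plus independent Gaussian noise of standard deviation `sigma` in
#' each channel. At zero underlying signal the mean is sigma*sqrt(pi/2)
#' (the Rician floor); at high SNR the distribution is close to Gaussian.
#'
#' @param signal numeric vector/array of noise-free magnitudes (>= 0)
#' @param sigma per-channel Gaussian noise standard deviation (>= 0); may be a
#'   scalar or an object recyclable against `signal`
#' @return noisy magnitudes, same shape as `signal`
#' @export
add_rician_noise <- function(signal, sigma) {
  if (any(sigma < 0)) stop_invalid("sigma must be >= 0")
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

# shared validation for 3D grids
check_same_grid <- function(..., what = "volumes") {
  vols <- list(...)
  d <- lapply(vols, dim)
  if (length(unique(vapply(d, paste, "", collapse = "x"))) != 1L)
    stop_invalid("grid mismatch: ", what, " must share one voxel grid")
  invisible(TRUE)
}
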