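# small phantom used throughout the suite (short tubule fits the 16-cube WM shell)
small_phantom <- function(seed = 1) {
  make_phantom(c(16, 16, 16),
               phantom_spec(pvs_length_vox = 3, wmh_radius_vox = 1),
               seed = seed)
}

default_t2s <- c(20, 80, 2000)

# exhaustive simplex grid-search oracle for the three-pool fit at fixed T2s:
# fractions stepped on the simplex, M0 profiled out in closed form
t2_grid_oracle <- function(signal, times, t2_ms = default_t2s, step = 0.005) {
  f_mw <- seq(0, 1, by = step)
  best <- Inf
  E <- exp(outer(-times, 1 / t2_ms))
  for (a in f_mw) {
    b <- seq(0, 1 - a, by = step)
    fmat <- rbind(a, b, 1 - a - b)
    S <- E %*% fmat                        # echoes x grid
    m0 <- colSums(S * signal) / colSums(S^2)
    obj <- colSums((sweep(S, 2, m0, `*`) - signal)^2)
    best <- min(best, obj)
  }
  best
}
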