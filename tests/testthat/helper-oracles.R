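# Independent brute-force oracles used across the suite.

# Dense-grid root tracking for the cantilever equilibrium, phrased as a
# single scan: roots of k*delta = F(s + delta) are level-crossings of
# h(d) = k*d - F(d) at level k*s, so marching the sample in (s decreasing)
# walks h down from large d. The approach branch ends at a local minimum
# of h (fold -> jump) or at d -> 0 (smooth contact). Sub-threshold folds
# hop to the inner branch and keep going.
oracle_contact_onset <- function(p, min_jump = 0.05, n_grid = 200000) {
  k <- p$spring_constant
  d <- exp(seq(log(1e-6), log(1000), length.out = n_grid))
  h <- k * d - tip_sample_force(d, p)
  i_hi <- length(d)
  repeat {
    hh <- h[1:i_hi]
    mins <- which(diff(sign(diff(hh))) > 0) + 1L
    if (length(mins) == 0L)
      return(list(jumped = FALSE, s_c = hh[1] / k))
    m <- mins[length(mins)]                    # first minimum seen from above
    below <- which(hh[1:(m - 1L)] <= hh[m])
    d_land <- if (length(below)) d[max(below)] else 0
    if (d[m] - d_land >= min_jump)
      return(list(jumped = TRUE, s_c = hh[m] / k))
    i_hi <- if (length(below)) max(below) else 1L
    if (i_hi <= 2L) return(list(jumped = FALSE, s_c = h[1] / k))
  }
}

# Fixed-point iteration for the equilibrium deflection, valid when the
# force gradient is small against the spring (contraction).
oracle_fixed_point <- function(s, p, tol = 1e-12, itmax = 10000) {
  k <- p$spring_constant
  delta <- 0
  for (i in seq_len(itmax)) {
    new <- tip_sample_force(s + delta, p) / k
    if (abs(new - delta) < tol) return(new)
    delta <- new
  }
  delta
}

# Noiseless-generation config: the acquisition noise and tilt switched off.
noiseless_ranges <- function(extra = list()) {
  c(list(noise_sigma_contact = c(0, 0), noise_ratio = c(1, 1),
         baseline_tilt = c(0, 0)), extra)
}

# Small curve fixtures built in code.
make_linear_kink_curve <- function(n = 200, zc_frac = 0.6, ramp = 100,
                                   slope = 0.05, label = TRUE) {
  z <- seq(0, ramp, length.out = n)
  zc <- zc_frac * ramp
  psd <- ifelse(z < zc, 0, (z - zc) * slope)
  fc <- force_curve(z, psd, sensitivity = slope)
  if (!label) return(fc)
  labeled_curve(fc, contact_label(zc, fc), "simulated")
}

tiny_convnet <- function(input_length = 256L, seed = 1L, l2 = 0) {
  build_convnet1d(convnet_spec(n_blocks = 2L, filters = c(4L, 8L),
                               kernel_sizes = c(7L, 5L),
                               pool_sizes = c(4L, 4L),
                               dense_units = 16L, l2_strength = l2),
                  input_length = input_length, seed = seed)
}
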