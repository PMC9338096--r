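test_that("debye_length matches the closed form evaluated independently", {
  # frozen from an independent evaluation with CODATA 2018 constants,
  # eps_r = 78.54, T = 298.15 K
  expect_equal(debye_length(0.001), 9.6223, tolerance = 1e-4)
  expect_equal(debye_length(0.1), 0.96223, tolerance = 1e-4)
  # inverse-square-root scaling in ionic strength
  expect_equal(debye_length(0.004), debye_length(0.001) / 2, tolerance = 1e-12)
  expect_error(debye_length(0), class = "fp_domain_error")
  expect_error(debye_length(-1), class = "fp_domain_error")
})

test_that("tip_sample_force has the stated limits and sign structure", {
  p <- hard_surface_params(surface_force_amp = 0.5, hamaker_term = 0.05)
  expect_lt(abs(tip_sample_force(500, p)), 1e-6)
  expect_lt(abs(tip_sample_force(5e4, p)), 1e-10)
  # no attraction: positive, strictly decreasing
  p0 <- hard_surface_params(surface_force_amp = 0.5, hamaker_term = 0)
  d <- seq(0.05, 30, length.out = 200)
  f0 <- tip_sample_force(d, p0)
  expect_true(all(f0 > 0))
  expect_true(all(diff(f0) < 0))
  expect_error(tip_sample_force(0, p), class = "fp_domain_error")
  expect_error(tip_sample_force(-1, p), class = "fp_domain_error")
})

test_that("force sign change located by bisection matches a dense grid scan", {
  set.seed(12)
  for (i in 1:10) {
    p <- hard_surface_params(ionic_strength = sample(c(0.001, 0.01, 0.1), 1),
                             surface_force_amp = runif(1, 0.1, 1),
                             hamaker_term = runif(1, 0.01, 0.1))
    dg <- seq(0.01, 50, length.out = 200001)
    fg <- tip_sample_force(dg, p)
    sc <- which(fg[-1] * fg[-length(fg)] <= 0)
    if (length(sc) == 1L) {
      root <- uniroot(function(d) tip_sample_force(d, p),
                      c(dg[sc], dg[sc + 1]), tol = 1e-12)$root
      expect_lt(abs(root - dg[sc]), diff(dg[1:2]) + 1e-12)
    }
  }
})

test_that("equilibrium deflection matches a fixed-point oracle for stiff repulsion", {
  p <- hard_surface_params(surface_force_amp = 0.4, hamaker_term = 0,
                           spring_constant = 0.5)
  for (s in c(0.5, 1, 3, 10)) {
    out <- solve_equilibrium_deflection(s, p)
    expect_false(out$jumped)
    expect_equal(out$deflection, oracle_fixed_point(s, p), tolerance = 1e-10)
  }
  # free cantilever: F == 0 everywhere
  pf <- hard_surface_params(surface_force_amp = 0, hamaker_term = 0)
  out <- solve_equilibrium_deflection(5, pf)
  expect_equal(out$deflection, 0, tolerance = 1e-12)
  expect_false(out$jumped)
})

test_that("jump detection agrees with dense-grid branch tracking", {
  set.seed(77)
  n_jump <- 0
  for (i in 1:20) {
    p <- hard_surface_params(
      ionic_strength = sample(c(0.001, 0.01, 0.1), 1),
      surface_force_amp = runif(1, 0.05, 1),
      hamaker_term = exp(runif(1, log(5e-4), log(0.1))))
    on <- forcepoint:::hard_contact_onset(p)
    or <- oracle_contact_onset(p)
    expect_identical(on$jumped, or$jumped)
    expect_lt(abs(on$s_c - or$s_c), 1e-3)
    n_jump <- n_jump + on$jumped
  }
  expect_gt(n_jump, 0)           # both outcomes exercised
  expect_lt(n_jump, 20)
})

test_that("hard curves degenerate to flat-then-linear with exact kink", {
  p <- hard_surface_params(surface_force_amp = 0, hamaker_term = 0,
                           hard_wall_slope = 1)
  a <- acquisition_params(ramp_length = 100, n_points = 512,
                          max_deflection = 0.4, sensitivity = 0.05,
                          noise_sigma_noncontact = 0, noise_sigma_contact = 0,
                          baseline_tilt = 0)
  lc <- generate_hard_curve(p, a)
  zc_expect <- 100 - (0.4 / 0.05) / 1
  expect_equal(lc$label$zc, zc_expect, tolerance = 1e-12)
  pre <- lc$curve$z < lc$label$zc
  expect_true(all(abs(lc$curve$psd[pre]) < 1e-12))
  post <- lc$curve$psd[!pre]
  expect_equal(diff(diff(post)), rep(0, length(post) - 2), tolerance = 1e-10)
  expect_equal(lc$curve$psd[length(post) + sum(pre)], 0.4, tolerance = 1e-9)
  # frac_index reproduces zc through the z axis
  z_back <- approx(seq_along(lc$curve$z) - 1, lc$curve$z,
                   xout = lc$label$frac_index)$y
  expect_lt(abs(z_back - lc$label$zc), 1e-9)
})

test_that("with attraction the jump-in dip precedes (or meets) contact", {
  p <- hard_surface_params(ionic_strength = 0.01, surface_force_amp = 0.1,
                           hamaker_term = 0.08)
  a <- acquisition_params(noise_sigma_noncontact = 0, noise_sigma_contact = 0,
                          baseline_tilt = 0)
  lc <- generate_hard_curve(p, a)
  first_contact <- ceiling(lc$label$frac_index) + 1   # 1-based
  expect_lte(which.min(lc$curve$psd), first_contact)
})

test_that("soft curves with zero steric amplitude put zc at the contact onset", {
  p <- soft_film_params(steric_amp = 0, film_thickness = 30,
                        contact_stiffness_amp = 0.2)
  a <- acquisition_params(ramp_length = 150, n_points = 1024,
                          noise_sigma_noncontact = 0, noise_sigma_contact = 0,
                          baseline_tilt = 0)
  lc <- generate_soft_curve(p, a)
  pre <- lc$curve$z < lc$label$zc
  expect_true(all(abs(lc$curve$psd[pre]) < 1e-12))
  expect_true(all(diff(lc$curve$psd[!pre]) > -1e-12))   # monotone contact
})

test_that("indentation events are negative steps strictly inside contact", {
  p <- soft_film_params(n_indent_events = 2, indent_depth_range = c(2, 4))
  a <- acquisition_params(ramp_length = 150, n_points = 1024,
                          max_deflection = 0.6,
                          noise_sigma_noncontact = 0, noise_sigma_contact = 0,
                          baseline_tilt = 0)
  lc <- generate_soft_curve(p, a, seed = 21)
  d1 <- diff(lc$curve$psd)
  thr <- -1.5 * a$sensitivity      # events are >= 2 nm deep
  drops <- which(d1 < thr)
  expect_length(drops, 2L)
  expect_true(all(drops > lc$label$frac_index + 1))
  # monotone between events on the contact branch
  contact <- which(lc$curve$z >= lc$label$zc)
  ok <- d1[setdiff(contact[-length(contact)], drops)]
  expect_true(all(ok > -1e-10))
})

test_that("noise sd drops on entering the contact region", {
  ranges <- list(noise_ratio = c(3, 3), n_points = c(2048, 4096),
                 ramp_length = c(50, 200))
  ds <- generate_dataset(sim_config("soft", n_curves = 12, seed = 31,
                                    param_ranges = ranges))
  rel <- vapply(ds$curves, function(lc) {
    i <- floor(lc$label$frac_index) + 1
    m <- min(100, i - 1, lc$curve$n_points - i - 1)
    pre <- lc$curve$psd[(i - m):(i - 1)]
    post <- lc$curve$psd[(i + 1):(i + m)]
    sd(diff(pre)) / sd(diff(post))    # differencing removes the trends
  }, numeric(1))
  expect_gt(mean(rel), 1.5)
})

test_that("datasets are deterministic under seed and respect configured ranges", {
  cfg <- sim_config("hard", n_curves = 8, seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$curves, d2$curves)
  d3 <- generate_dataset(sim_config("hard", n_curves = 8, seed = 6))
  expect_false(identical(d1$curves, d3$curves))
  np <- vapply(d1$curves, function(lc) lc$curve$n_points, integer(1))
  expect_true(all(np >= 256 & np <= 4096))
  empty <- generate_dataset(sim_config("hard", n_curves = 0, seed = 1))
  expect_length(empty$curves, 0)
  expect_length(empty$manifest$curves, 0)
})

test_that("dataset files and manifest round-trip through a directory", {
  dir <- withr::local_tempdir()
  cfg <- sim_config("soft", n_curves = 4, seed = 77)
  ds <- generate_dataset(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_length(back$curves, 4)
  expect_equal(vapply(back$curves, function(lc) lc$label$zc, numeric(1)),
               ds$manifest$zc, tolerance = 1e-9)
})

test_that("infeasible acquisitions raise generation errors", {
  p <- hard_surface_params(surface_force_amp = 0, hamaker_term = 0)
  a <- acquisition_params(ramp_length = 50, n_points = 256,
                          max_deflection = 1, sensitivity = 0.01)
  expect_error(generate_hard_curve(p, a), class = "fp_generation_error")
  ps <- soft_film_params(steric_amp = 1, spring_constant = 0.1)
  as <- acquisition_params(max_deflection = 0.2, sensitivity = 0.05)
  # trigger deflection 4 nm < steric transition deflection 10 nm
  expect_error(generate_soft_curve(ps, as), class = "fp_generation_error")
})

test_that("ground-truth kink sits at the strongest curvature for jump curves", {
  ranges <- noiseless_ranges(list(hamaker_term = c(0.05, 0.1)))
  ds <- generate_dataset(sim_config("hard", n_curves = 10, seed = 55,
                                    param_ranges = ranges))
  for (lc in ds$curves) {
    d2 <- abs(diff(lc$curve$psd, differences = 2))
    kink <- which.max(d2)       # d2[j] is curvature at sample j + 1 (1-based)
    expect_lt(abs(kink - lc$label$frac_index), 2)
  }
})
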