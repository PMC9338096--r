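#' Debye screening length
#'
#' Characteristic decay length of the electrostatic double-layer force in a
#' symmetric 1:1 electrolyte,
#' \eqn{\kappa^{-1} = \sqrt{\epsilon_r \epsilon_0 k_B T / (2 N_A e^2 I)}},
#' with the ionic strength \eqn{I} converted from mol/L to mol/m^3.
#' CODATA 2018 values are used for the physical constants.
#'
#' @param ionic_strength Ionic strength (mol/L), positive.
#' @param temperature Temperature (K).
#' @param eps_r Relative permittivity of the medium (water at 25 C by
#'   default).
#' @return Debye length in nm. About 9.62 nm in 1 mM NaCl and 0.96 nm in
#'   100 mM NaCl at 298.15 K.
#' @export
debye_length <- function(ionic_strength, temperature = 298.15, eps_r = 78.54) {
  if (any(!is.finite(ionic_strength)) || any(ionic_strength <= 0))
    stop_fp("ionic_strength must be positive", class = "fp_domain_error")
  e <- 1.602176634e-19; kB <- 1.380649e-23
  NAv <- 6.02214076e23; eps0 <- 8.8541878128e-12
  lam <- sqrt(eps_r * eps0 * kB * temperature /
                (2 * NAv * e^2 * ionic_strength * 1000))
  lam * 1e9
}

#' Simulator parameter sets
#'
#' `hard_surface_params()` describes the tip--sample force model for a hard
#' charged surface (mica-like): a repulsive electrostatic double-layer term
#' decaying with the Debye length plus an attractive inverse-square van der
#' Waals term smoothly saturated at a molecular-scale softening length,
#' \eqn{F(d) = A e^{-d/\lambda_D} - H / (d^2 + d_0^2)}. Forces are in nN,
#' distances in nm, stiffness in N/m (numerically identical to nN/nm).
#'
#' @param ionic_strength Ionic strength of the medium (mol/L).
#' @param surface_force_amp Electrostatic prefactor at contact (nN).
#' @param hamaker_term Lumped van der Waals prefactor H R / 6 (nN nm^2).
#' @param spring_constant Cantilever spring constant (N/m).
#' @param hard_wall_slope Deflection gained per nm of sample travel in
#'   contact, in (0, 1]; 1 is an infinitely stiff surface.
#' @param vdw_cutoff Softening length regularizing the van der Waals
#'   divergence at contact (nm); the attraction saturates smoothly at
#'   `-hamaker_term / (d^2 + vdw_cutoff^2)`.
#' @param temperature Temperature (K), used for the Debye length.
#' @return A list of class `fp_hard_params`.
#' @export
hard_surface_params <- function(ionic_strength = 0.01,
                                surface_force_amp = 0.3,
                                hamaker_term = 0.05,
                                spring_constant = 0.1,
                                hard_wall_slope = 0.99,
                                vdw_cutoff = 0.3,
                                temperature = 298.15) {
  p <- list(ionic_strength = ionic_strength,
            surface_force_amp = surface_force_amp,
            hamaker_term = hamaker_term,
            spring_constant = spring_constant,
            hard_wall_slope = hard_wall_slope,
            vdw_cutoff = vdw_cutoff,
            temperature = temperature)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num) || any(unlist(p[num]) < 0))
    stop_fp("hard-surface parameters must be non-negative numbers",
            class = "fp_validation_error")
  if (p$ionic_strength <= 0 || p$spring_constant <= 0 ||
      p$hard_wall_slope <= 0 || p$hard_wall_slope > 1 || p$vdw_cutoff <= 0)
    stop_fp("invalid hard-surface parameters", class = "fp_validation_error")
  p$debye <- debye_length(ionic_strength, temperature)
  structure(p, class = "fp_hard_params")
}

#' @rdname hard_surface_params
#' @param steric_amp Steric repulsion amplitude at the compression point
#'   (nN).
#' @param steric_decay Steric decay length (nm), positive.
#' @param film_thickness Compressible film thickness (nm); once the
#'   indentation exceeds it the response becomes constant-compliance
#'   (substrate).
#' @param contact_stiffness_amp Compliant-contact (Hertz-like) prefactor
#'   (nN/nm^1.5).
#' @param n_indent_events Number of sudden indentation (breakthrough)
#'   events inserted in the contact regime.
#' @param indent_depth_range Length-2 range of event depths (nm of
#'   deflection).
#' @export
soft_film_params <- function(steric_amp = 0.5,
                             steric_decay = 8,
                             film_thickness = 15,
                             contact_stiffness_amp = 0.2,
                             n_indent_events = 0L,
                             indent_depth_range = c(1, 5),
                             spring_constant = 0.1) {
  p <- list(steric_amp = steric_amp, steric_decay = steric_decay,
            film_thickness = film_thickness,
            contact_stiffness_amp = contact_stiffness_amp,
            n_indent_events = as.integer(n_indent_events),
            indent_depth_range = as.numeric(indent_depth_range),
            spring_constant = spring_constant)
  if (any(unlist(p) < 0) || p$steric_decay <= 0 || p$spring_constant <= 0 ||
      length(p$indent_depth_range) != 2L)
    stop_fp("invalid soft-film parameters", class = "fp_validation_error")
  structure(p, class = "fp_soft_params")
}

#' @rdname hard_surface_params
#' @param ramp_length Ramp length (nm).
#' @param n_points Number of samples along the ramp, in \[64, 4096\].
#' @param max_deflection Trigger deflection ending the ramp (V).
#' @param sensitivity Photodetector sensitivity (V/nm).
#' @param noise_sigma_noncontact Gaussian noise sd before contact (V).
#' @param noise_sigma_contact Gaussian noise sd in contact (V); must not
#'   exceed the non-contact sd (the deflection noise drops on entering the
#'   contact region).
#' @param baseline_tilt Linear baseline tilt (V/nm).
#' @export
acquisition_params <- function(ramp_length = 275, n_points = 1024L,
                               max_deflection = 0.4, sensitivity = 0.05,
                               noise_sigma_noncontact = 0.004,
                               noise_sigma_contact = 0.002,
                               baseline_tilt = 0) {
  a <- list(ramp_length = ramp_length, n_points = as.integer(n_points),
            max_deflection = max_deflection, sensitivity = sensitivity,
            noise_sigma_noncontact = noise_sigma_noncontact,
            noise_sigma_contact = noise_sigma_contact,
            baseline_tilt = baseline_tilt)
  if (a$n_points < 64L || a$n_points > 4096L)
    stop_fp("n_points must lie in [64, 4096], got %d", a$n_points,
            class = "fp_validation_error")
  if (a$ramp_length <= 0 || a$max_deflection <= 0 || a$sensitivity <= 0)
    stop_fp("ramp_length, max_deflection and sensitivity must be positive",
            class = "fp_validation_error")
  if (a$noise_sigma_contact > a$noise_sigma_noncontact + 1e-15)
    stop_fp("noise_sigma_contact must not exceed noise_sigma_noncontact",
            class = "fp_validation_error")
  structure(a, class = "fp_acq_params")
}

#' Tip--sample force law (hard charged surface)
#'
#' DLVO-type force on the tip at separation `d`:
#' repulsive exponential double-layer term minus an inverse-square van der
#' Waals attraction smoothly saturated at the `vdw_cutoff` softening
#' length. Positive values are repulsive.
#'
#' @param d Tip--sample separation(s), nm, strictly positive.
#' @param p A [hard_surface_params()] object.
#' @return Force in nN (vectorized over `d`).
#' @export
tip_sample_force <- function(d, p) {
  stopifnot(inherits(p, "fp_hard_params"))
  if (any(!is.finite(d)) || any(d <= 0))
    stop_fp("separation d must be positive", class = "fp_domain_error")
  p$surface_force_amp * exp(-d / p$debye) -
    p$hamaker_term / (d^2 + p$vdw_cutoff^2)
}

# dF/dd of the hard-surface force law.
tip_sample_force_grad <- function(d, p) {
  -p$surface_force_amp / p$debye * exp(-d / p$debye) +
    2 * p$hamaker_term * d / (d^2 + p$vdw_cutoff^2)^2
}

# The band of separations where dF/dd >= k (no stable equilibrium). Its
# upper edge is where the non-contact branch folds (jump-to-contact).
# NULL when the branch never folds (e.g. no attraction).
critical_band <- function(p) {
  k <- p$spring_constant
  if (p$hamaker_term <= 0) return(NULL)
  dg <- exp(seq(log(p$vdw_cutoff / 100), log(1000), length.out = 4000))
  h <- tip_sample_force_grad(dg, p) - k
  up <- which(h[-length(h)] > 0 & h[-1] <= 0)   # + -> - : band's upper edge
  dn <- which(h[-length(h)] <= 0 & h[-1] > 0)   # - -> + : band's lower edge
  if (length(up) == 0L) return(NULL)
  f <- function(d) tip_sample_force_grad(d, p) - k
  i <- max(up)
  hi <- stats::uniroot(f, c(dg[i], dg[i + 1]), tol = 1e-12)$root
  lo <- if (length(dn) > 0L) {
    j <- min(dn)
    stats::uniroot(f, c(dg[j], dg[j + 1]), tol = 1e-12)$root
  } else 0
  c(lo, hi)
}

critical_distance <- function(p) {
  band <- critical_band(p)
  if (is.null(band)) 0 else band[2]
}

#' Quasi-static cantilever equilibrium
#'
#' For an undeflected tip--sample separation `s` (sample approaching: `s`
#' decreases), the actual separation is `d = s + delta` where the
#' deflection `delta` (positive away from the sample) balances the spring:
#' `k delta = F(d)`. The stable equilibrium branch connected to large
#' separations ends where `dF/dd = k`; past that point no stable root
#' exists and the tip jumps to contact.
#'
#' @param s Undeflected tip--sample separation (nm).
#' @param p A [hard_surface_params()] object.
#' @return A list with `deflection` (nm), `jumped` (logical) and `d` (the
#'   equilibrium separation, 0 after a jump). After a jump the tip is
#'   placed in contact (`d = 0`, `deflection = -s`).
#' @export
solve_equilibrium_deflection <- function(s, p) {
  stopifnot(inherits(p, "fp_hard_params"))
  k <- p$spring_constant
  on <- hard_contact_onset(p)
  if (s <= on$s_c)
    return(list(deflection = -s, jumped = on$jumped, d = 0))
  g <- function(d) k * (d - s) - tip_sample_force(d, p)
  hi <- max(s, 0) + p$surface_force_amp / k + 1
  # past a sub-resolution fold the tracked branch is the inner one
  inner <- !on$jumped && on$dcrit > 0 && !is.na(on$s_fold) && s <= on$s_fold
  lo <- if (inner) 1e-9 else max(on$dcrit, 1e-9)
  hi <- if (inner) on$d_land * (1 + 1e-9) + 1e-12 else hi
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  list(deflection = root - s, jumped = FALSE, d = root)
}

# Noiseless non-contact deflection profile, vectorized by inverting the
# branch relation s(d) = d - F(d)/k on a dense d grid down to d_lo (the
# fold separation for jumping parameter sets, else ~0).

noncontact_deflection <- function(s, p, d_lo, skip = NULL) {
  k <- p$spring_constant
  d_lo <- max(d_lo, 1e-9)
  d_hi <- max(s, 0) + p$surface_force_amp / k + 1
  # log-dense near the fold where d(s) has a sqrt singularity
  dg <- unique(sort(c(d_lo + exp(seq(log(1e-7), log(1), length.out = 2000)),
                      seq(d_lo + 1, d_hi, length.out = 4000))))
  if (!is.null(skip) && skip[2] > skip[1]) {
    # excise the d-window bypassed by a sub-resolution fold: the tracked
    # branch hops from skip[2] to skip[1], and s(d) is multi-valued in
    # between
    dg <- dg[dg <= skip[1] | dg >= skip[2]]
  }
  sg <- dg - tip_sample_force(dg, p) / k
  cm <- cummax(sg)                         # guard against fp-level folds
  keep <- sg >= cm & !duplicated(cm)
  stats::approx(sg[keep], dg[keep] - sg[keep], xout = s, rule = 2)$y
}

# Shared machinery: contact onset for the hard model.
# Returns list(s_c, delta_c, jumped): contact begins at separation s_c with
# deflection delta_c = -s_c (tip at d = 0).
hard_contact_onset <- function(p, min_jump = 0.05) {
  k <- p$spring_constant
  F0 <- p$surface_force_amp - p$hamaker_term / p$vdw_cutoff^2
  band <- critical_band(p)
  dcrit <- if (is.null(band)) 0 else band[2]
  if (dcrit > 0) {
    s_star <- dcrit - tip_sample_force(dcrit, p) / k
    # jump amplitude: distance from the fold to the landing equilibrium on
    # the inner stable branch (below the unstable band). Folds smaller
    # than min_jump (sub-noise, created by near-critical parameters) are
    # followed through: the tip hops to the inner branch and the curve
    # continues to smooth contact at d = 0.
    g0 <- -k * s_star - F0
    d_land <- if (g0 < 0 && band[1] > 1e-9) {
      stats::uniroot(function(d) k * (d - s_star) - tip_sample_force(d, p),
                     c(1e-9, band[1]), tol = 1e-12)$root
    } else 0
    if (dcrit - d_land >= min_jump)
      return(list(s_c = s_star, delta_c = -s_star, jumped = TRUE,
                  dcrit = dcrit, d_land = d_land, s_fold = s_star))
    return(list(s_c = -F0 / k, delta_c = F0 / k, jumped = FALSE,
                dcrit = dcrit, d_land = d_land, s_fold = s_star))
  }
  list(s_c = -F0 / k, delta_c = F0 / k, jumped = FALSE, dcrit = 0,
       d_land = 0, s_fold = NA_real_)
}

#' Generate a synthetic hard-surface force curve
#'
#' Simulates an approach curve on a hard charged surface: quasi-static
#' equilibrium deflection under the DLVO-type force along the ramp, a
#' jump-to-contact discontinuity when the attractive force gradient
#' exceeds the spring constant, then a linear constant-compliance branch
#' until the deflection trigger. The ramp is laid out so that the trigger
#' is reached exactly at its far end; deflection is converted to volts
#' with the photodetector sensitivity, a linear baseline tilt is added and
#' Gaussian noise with a regime-dependent sd is applied. The ground-truth
#' contact point `zc` is the sample position where mechanical contact is
#' established (the jump landing point if a jump occurred, else where the
#' separation reaches zero).
#'
#' @param p A [hard_surface_params()] object.
#' @param a An [acquisition_params()] object.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A [labeled_curve()] with `truth_source = "simulated"`.
#' @export
generate_hard_curve <- function(p, a, seed = NULL) {
  with_seed(seed, {
    stopifnot(inherits(p, "fp_hard_params"), inherits(a, "fp_acq_params"))
    k <- p$spring_constant
    on <- hard_contact_onset(p)
    delta_trig <- a$max_deflection / a$sensitivity
    travel <- (delta_trig - on$delta_c) / p$hard_wall_slope
    # the labeled transition needs support on both sides of the ramp
    min_travel <- max(0.02 * a$ramp_length, 3 * a$ramp_length / (a$n_points - 1))
    if (!is.finite(travel) || travel < min_travel ||
        travel >= 0.95 * a$ramp_length)
      stop_fp("trigger deflection unreachable within the ramp (contact travel %.3g nm vs ramp %.3g nm)",
              travel, a$ramp_length, class = "fp_generation_error")
    zc <- a$ramp_length - travel
    z0 <- zc + on$s_c                      # undeflected-touch position
    z <- seq(0, a$ramp_length, length.out = a$n_points)
    delta <- numeric(a$n_points)
    pre <- z < zc
    if (any(pre)) {
      skip <- if (!on$jumped && on$dcrit > 0) c(on$d_land, on$dcrit) else NULL
      delta[pre] <- noncontact_deflection(z0 - z[pre], p,
                                          if (on$jumped) on$dcrit else 0,
                                          skip = skip)
    }
    delta[!pre] <- on$delta_c + p$hard_wall_slope * (z[!pre] - zc)
    sigma <- ifelse(pre, a$noise_sigma_noncontact, a$noise_sigma_contact)
    psd <- a$sensitivity * delta + a$baseline_tilt * z +
      stats::rnorm(a$n_points, 0, sigma)
    fc <- force_curve(z, psd, ramp_length = a$ramp_length,
                      spring_constant = k, sensitivity = a$sensitivity,
                      medium = sprintf("NaCl_%gmM", p$ionic_strength * 1000),
                      surface = "mica")
    labeled_curve(fc, contact_label(zc, fc), "simulated")
  })
}

#' Generate a synthetic soft-film force curve
#'
#' Simulates an approach curve on a soft film (salivary-pellicle-like): an
#' exponential steric repulsion from the diffuse outer layer solved
#' quasi-statically in the non-contact regime, then a compliant Hertz-like
#' contact branch (force growing with indentation to the 3/2 power) from
#' the film-compression point, switching to constant compliance once the
#' indentation exceeds the film thickness. Optional sudden deflection
#' drops (indentation/breakthrough events) are inserted strictly inside
#' the contact branch, and the noise sd switches from its non-contact to
#' its (lower) contact value at the contact point.
#'
#' @inheritParams generate_hard_curve
#' @param p A [soft_film_params()] object.
#' @return A [labeled_curve()] with `truth_source = "simulated"`.
#' @export
generate_soft_curve <- function(p, a, seed = NULL) {
  with_seed(seed, {
    stopifnot(inherits(p, "fp_soft_params"), inherits(a, "fp_acq_params"))
    k <- p$spring_constant
    A <- p$steric_amp; lam <- p$steric_decay; C <- p$contact_stiffness_amp
    Tf <- p$film_thickness
    delta_c <- A / k                       # deflection at the transition
    delta_trig <- a$max_deflection / a$sensitivity
    if (delta_trig <= delta_c)
      stop_fp("trigger (%.3g nm) reached inside the steric regime; no contact transition",
              delta_trig, class = "fp_generation_error")
    # contact branch, parameterized by indentation di (nm past transition):
    # k*delta = A + C*di^1.5 while di < Tf, then constant compliance.
    delta_wall <- (A + C * Tf^1.5) / k
    t_wall <- Tf + (C / k) * Tf^1.5
    travel <- if (C > 0 && delta_trig <= delta_wall) {
      ((k * delta_trig - A) / C)^(2 / 3) + delta_trig - delta_c
    } else {
      t_wall + (delta_trig - delta_wall)
    }
    min_travel <- max(0.02 * a$ramp_length, 3 * a$ramp_length / (a$n_points - 1))
    if (!is.finite(travel) || travel < min_travel ||
        travel >= 0.95 * a$ramp_length)
      stop_fp("contact transition falls outside the ramp (contact travel %.3g nm vs ramp %.3g nm)",
              travel, a$ramp_length, class = "fp_generation_error")
    zc <- a$ramp_length - travel
    z0 <- zc - delta_c                     # position of zero separation
    z <- seq(0, a$ramp_length, length.out = a$n_points)
    pre <- z < zc
    delta <- numeric(a$n_points)
    if (any(pre)) {
      if (A > 0) {
        s <- z0 - z[pre]
        dg <- unique(sort(c(exp(seq(log(1e-7), log(1), length.out = 1000)),
                            seq(1, max(s, 1) + delta_c + 10 * lam,
                                length.out = 4000))))
        sg <- dg - (A / k) * exp(-dg / lam)
        delta[pre] <- stats::approx(sg, (A / k) * exp(-dg / lam),
                                    xout = s, rule = 2)$y
      } else delta[pre] <- 0
    }
    tt <- z[!pre] - zc                     # travel past the transition
    if (C > 0) {
      dig <- seq(0, Tf, length.out = 3000)
      tg <- dig + (C / k) * dig^1.5
      di <- stats::approx(tg, dig, xout = pmin(tt, t_wall), rule = 2)$y
      dcb <- delta_c + pmin(tt, t_wall) - di
    } else {
      dcb <- delta_c + 0 * tt              # force plateau: deflection flat
    }
    over <- tt > t_wall
    dcb[over] <- delta_wall + (tt[over] - t_wall)
    delta[!pre] <- dcb
    # indentation events: instantaneous deflection drops inside contact
    n_contact <- sum(!pre)
    if (p$n_indent_events > 0L && n_contact > 6L) {
      ci <- which(!pre)
      pos <- sort(sample(ci[3:(length(ci) - 2)], p$n_indent_events))
      depths <- stats::runif(p$n_indent_events, p$indent_depth_range[1],
                             p$indent_depth_range[2])
      for (j in seq_along(pos))
        delta[pos[j]:a$n_points] <- delta[pos[j]:a$n_points] - depths[j]
    }
    sigma <- ifelse(pre, a$noise_sigma_noncontact, a$noise_sigma_contact)
    psd <- a$sensitivity * delta + a$baseline_tilt * z +
      stats::rnorm(a$n_points, 0, sigma)
    fc <- force_curve(z, psd, ramp_length = a$ramp_length,
                      spring_constant = k, sensitivity = a$sensitivity,
                      medium = NA_character_, surface = "pellicle")
    labeled_curve(fc, contact_label(zc, fc), "simulated")
  })
}

# ---- dataset-level generation --------------------------------------------

#' Default simulator parameter ranges
#'
#' Per-field `(lo, hi)` ranges (and discrete choice sets) from which
#' [generate_dataset()] draws per-curve parameters uniformly. The spring
#' constant is fixed at 0.1 N/m (the cantilevers this emulates); ionic
#' strength is drawn from \{1, 10, 100\} mM; acquisition parameters span
#' ramp lengths of 50--500 nm, 256--4096 samples, triggers of 0.2--0.8 V
#' and sensitivities of 0.02--0.08 V/nm, with the non-contact/contact
#' noise-sd ratio between 1 and 4.
#'
#' @param system `"hard"` or `"soft"`.
#' @return A named list of length-2 numeric ranges (or choice vectors,
#'   for `ionic_strength`).
#' @export
default_param_ranges <- function(system = c("hard", "soft")) {
  system <- match.arg(system)
  acq <- list(
    ramp_length = c(50, 500),
    n_points = c(256, 4096),
    max_deflection = c(0.2, 0.8),
    sensitivity = c(0.02, 0.08),
    noise_sigma_contact = c(0.001, 0.004),
    noise_ratio = c(1, 4),
    baseline_tilt = c(-2e-5, 2e-5)
  )
  phys <- if (system == "hard") {
    list(ionic_strength = c(0.001, 0.01, 0.1),
         surface_force_amp = c(0.05, 1),
         hamaker_term = c(0.01, 0.1),
         spring_constant = c(0.1, 0.1),
         hard_wall_slope = c(0.97, 1),
         vdw_cutoff = c(0.3, 0.3))
  } else {
    list(steric_amp = c(0.1, 2),
         steric_decay = c(2, 20),
         film_thickness = c(5, 30),
         contact_stiffness_amp = c(0.05, 0.5),
         n_indent_events = c(0, 2),
         indent_depth_min = c(1, 1),
         indent_depth_max = c(5, 5),
         spring_constant = c(0.1, 0.1))
  }
  c(phys, acq)
}

#' Simulation configuration
#'
#' @param system `"hard"` or `"soft"`.
#' @param n_curves Number of curves to generate.
#' @param seed Integer seed; each curve uses a sub-stream derived from it,
#'   so datasets are reproducible and curves independent.
#' @param param_ranges Named list of `(lo, hi)` ranges as in
#'   [default_param_ranges()]; entries with more than two values are
#'   treated as discrete choice sets.
#' @return A list of class `fp_sim_config`.
#' @export
sim_config <- function(system = c("hard", "soft"), n_curves = 100L, seed = 1L,
                       param_ranges = default_param_ranges(system)) {
  system <- match.arg(system)
  base <- default_param_ranges(system)
  for (nm in names(param_ranges)) base[[nm]] <- param_ranges[[nm]]
  for (nm in names(base)) {
    r <- base[[nm]]
    if (length(r) == 2L && r[1] > r[2])
      stop_fp("range for '%s' has lo > hi", nm, class = "fp_validation_error")
  }
  structure(list(system = system, n_curves = as.integer(n_curves),
                 seed = as.integer(seed), param_ranges = base),
            class = "fp_sim_config")
}

draw_in <- function(r) {
  if (length(r) > 2L) sample(r, 1L)
  else if (r[1] == r[2]) r[1]
  else stats::runif(1, r[1], r[2])
}

# Draw one parameter set + acquisition from the configured ranges using the
# current RNG stream.
draw_curve_params <- function(cfg) {
  r <- cfg$param_ranges
  sc <- draw_in(r$noise_sigma_contact)
  acq <- acquisition_params(
    ramp_length = draw_in(r$ramp_length),
    n_points = round(draw_in(r$n_points)),
    max_deflection = draw_in(r$max_deflection),
    sensitivity = draw_in(r$sensitivity),
    noise_sigma_noncontact = sc * draw_in(r$noise_ratio),
    noise_sigma_contact = sc,
    baseline_tilt = draw_in(r$baseline_tilt))
  p <- if (cfg$system == "hard") {
    hard_surface_params(
      ionic_strength = draw_in(r$ionic_strength),
      surface_force_amp = draw_in(r$surface_force_amp),
      hamaker_term = draw_in(r$hamaker_term),
      spring_constant = draw_in(r$spring_constant),
      hard_wall_slope = draw_in(r$hard_wall_slope),
      vdw_cutoff = draw_in(r$vdw_cutoff))
  } else {
    soft_film_params(
      steric_amp = draw_in(r$steric_amp),
      steric_decay = draw_in(r$steric_decay),
      film_thickness = draw_in(r$film_thickness),
      contact_stiffness_amp = draw_in(r$contact_stiffness_amp),
      n_indent_events = round(draw_in(r$n_indent_events)),
      indent_depth_range = c(r$indent_depth_min[1], r$indent_depth_max[1]),
      spring_constant = draw_in(r$spring_constant))
  }
  list(params = p, acq = acq)
}

#' Generate a labeled synthetic dataset
#'
#' Draws per-curve physical and acquisition parameters uniformly from the
#' configured ranges and generates `n_curves` labeled curves. Each curve
#' uses its own RNG sub-stream derived from the configuration seed, so the
#' dataset is bit-reproducible and curves are independent. Parameter draws
#' that land in the documented generation-error region (trigger
#' unreachable within the ramp) are redrawn within the curve's sub-stream,
#' deterministically, up to 100 times.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, curve files and a
#'   `manifest.json` are written there.
#' @return Invisibly, a list with `curves` (list of [labeled_curve()]) and
#'   `manifest` (list mirroring the JSON manifest).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "fp_sim_config"))
  gen <- if (cfg$system == "hard") generate_hard_curve else generate_soft_curve
  curves <- vector("list", cfg$n_curves)
  for (i in seq_len(cfg$n_curves)) {
    curves[[i]] <- with_seed(derive_seed(cfg$seed, i), {
      lc <- NULL
      for (try in 1:100) {
        dp <- draw_curve_params(cfg)
        lc <- tryCatch(gen(dp$params, dp$acq),
                       fp_generation_error = function(e) NULL)
        if (!is.null(lc)) break
      }
      if (is.null(lc))
        stop_fp("curve %d: no feasible parameter draw in 100 attempts", i,
                class = "fp_generation_error")
      lc
    })
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(out_dir, sprintf("curve_%05d.txt", seq_len(cfg$n_curves)))
    for (i in seq_along(curves)) write_curve(curves[[i]], files[i])
  }
  manifest <- list(system = cfg$system, n_curves = cfg$n_curves,
                   seed = cfg$seed,
                   curves = if (length(files)) basename(files) else character(0),
                   zc = vapply(curves, function(lc) lc$label$zc, numeric(1)))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(curves = curves, manifest = manifest))
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir Directory containing `manifest.json` and curve files.
#' @return A list with `curves` and `manifest`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop_fp("no manifest.json in %s", dir, class = "fp_io_error")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  curves <- lapply(file.path(dir, manifest$curves), read_curve)
  list(curves = curves, manifest = manifest)
}
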