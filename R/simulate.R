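#' Coverage of a circular wound healed by an inward radial front
#'
#' Cells migrate inward from the wound edge at speed `v`, so the open area
#' is a shrinking disk of radius `r - v t` and the covered fraction is
#' `coverage(t) = 1 - ((r - v t)/r)^2` until closure at `t = r / v`, and 1
#' afterwards.
#'
#' @param t_h hours since the wound (vectorised, >= 0).
#' @param v front speed, um/h.
#' @param r wound radius, um (default 125).
#' @return coverage fraction in \[0, 1\].
#' @export
simulate_wound_recovery_coverage <- function(t_h, v, r = 125) {
  if (v <= 0 || r <= 0) stop_domain("v and r must be > 0")
  if (any(t_h < 0)) stop_domain("t_h must be >= 0")
  ifelse(t_h < r / v, 1 - ((r - v * t_h) / r)^2, 1)
}

#' Calibrate the barrier resistance to a target covered 4 kHz resistance
#'
#' Solves for Rb (on the rising branch, Rb in \[1e-6, 30\] Ohm cm^2) such
#' that the absolute series resistance of the fully covered electrode at
#' 4 kHz equals `target_R4k` Ohm, for given alpha and Cm.
#'
#' @param target_R4k target absolute resistance at 4 kHz, Ohm.
#' @param alpha adhesion parameter, Ohm^1/2 cm.
#' @param m a `gk_electrode`.
#' @param Cm per-membrane capacitance, F/cm^2.
#' @param interval search interval for Rb, Ohm cm^2.
#' @return Rb in Ohm cm^2.
#' @export
calibrate_barrier_resistance <- function(target_R4k, alpha, m, Cm = 1e-6,
                                         interval = c(1e-6, 30)) {
  fn <- function(Rb) {
    p <- cell_model_params(alpha = alpha, Rb = Rb, Cm = Cm)
    Re(covered_electrode_impedance(4000, m, p)) / m$area - target_R4k
  }
  lo <- fn(interval[1]); hi <- fn(interval[2])
  if (lo > 0) {
    stop_domain("target 4 kHz resistance (", target_R4k, " Ohm) is below the ",
                "alpha-driven floor (", round(target_R4k + lo),
                " Ohm) for alpha = ", alpha)
  }
  if (hi < 0) stop_domain("target 4 kHz resistance unreachable for alpha = ", alpha)
  uniroot(fn, interval, tol = 1e-10)$root
}

#' Phase schedule of a simulated ECIS experiment
#'
#' Defaults reproduce the canonical epithelial maturation + wound-healing
#' trajectory at 4 kHz: rise to a 15 kOhm peak at day 2, slow decline over
#' 5.5 days to an 8.5 kOhm plateau, a wound at day 25 dropping the
#' electrode to its 2600 Ohm cell-free level, migration-driven recovery to
#' a 10 kOhm migration plateau, and a second maturation decline starting
#' 24 h post wound.
#'
#' @param coverage_rise_h initial attachment/spreading duration, h.
#' @param peak_h time of the resistance peak, h.
#' @param peak_R4k peak resistance, Ohm.
#' @param maturation_h duration of the maturation decline, h.
#' @param plateau_R4k mature plateau resistance, Ohm.
#' @param cellfree_R4k cell-free electrode resistance, Ohm.
#' @param wound_h wound time, h (must fall after maturation completes).
#' @param migration_R4k recovery (migration-phase) plateau resistance, Ohm.
#' @param post_heal_hold_h hold at the migration plateau before the second
#'   maturation decline, h.
#' @param total_h experiment duration, h.
#' @return a `phase_schedule` list.
#' @export
phase_schedule <- function(coverage_rise_h = 5, peak_h = 48,
                           peak_R4k = 15000, maturation_h = 132,
                           plateau_R4k = 8500, cellfree_R4k = 2600,
                           wound_h = 600, migration_R4k = 10000,
                           post_heal_hold_h = 24, total_h = 648) {
  s <- list(coverage_rise_h = coverage_rise_h, peak_h = peak_h,
            peak_R4k = peak_R4k, maturation_h = maturation_h,
            plateau_R4k = plateau_R4k, cellfree_R4k = cellfree_R4k,
            wound_h = wound_h, migration_R4k = migration_R4k,
            post_heal_hold_h = post_heal_hold_h, total_h = total_h)
  if (!(peak_R4k > plateau_R4k && plateau_R4k > cellfree_R4k)) {
    stop_domain("schedule requires peak > plateau > cell-free baseline")
  }
  if (wound_h < peak_h + maturation_h) {
    stop_domain("config error: wound at ", wound_h,
                " h precedes maturation completion at ", peak_h + maturation_h, " h")
  }
  structure(s, class = "phase_schedule")
}

#' Group description for the simulator
#'
#' @param n_wells number of replicate wells.
#' @param front_speed healing front speed, um/h.
#' @param alpha adhesion parameter, Ohm^1/2 cm. Default 2.5: with a
#'   CPE-type naked electrode the Giaever-Keese 4 kHz resistance floor at
#'   Rb -> 0 must stay below the 8.5 kOhm plateau for the barrier
#'   calibration to succeed, which bounds alpha well below the values
#'   typical of tightly adherent epithelia (see the methods vignette).
#' @param Cm per-membrane capacitance, F/cm^2.
#' @param well_sd_ohm SD of the per-well random offset applied to the
#'   resistance levels of the schedule, Ohm (inter-well variability).
#' @return a `sim_group` list.
#' @export
sim_group <- function(n_wells = 2, front_speed = 10.69, alpha = 2.5,
                      Cm = 1e-6, well_sd_ohm = 0) {
  if (front_speed <= 0) stop_domain("front_speed must be > 0")
  structure(list(n_wells = n_wells, front_speed = front_speed,
                 alpha = alpha, Cm = Cm, well_sd_ohm = well_sd_ohm),
            class = "sim_group")
}

#' Simulation configuration
#'
#' Everything needed to generate a reproducible synthetic ECIS experiment.
#'
#' @param seed integer RNG seed; the simulation is a pure function of the
#'   configuration including this seed.
#' @param dt_s acquisition interval, s (default 160).
#' @param frequencies acquisition frequencies, Hz.
#' @param electrode a `gk_electrode` (default: CPE electrode calibrated to
#'   a 2600 Ohm cell-free 4 kHz resistance).
#' @param groups named list of [sim_group()] objects.
#' @param schedule a [phase_schedule()].
#' @param wound_radius_um wound radius, um.
#' @param pulse wound pulse descriptor carried as metadata.
#' @param micromotion list: `enabled`, `high_var` / `low_var` (variance of
#'   the relative barrier-resistance fluctuation in the active and
#'   quiescent states), `midpoint_h` (transition half-time after
#'   activity-triggering events), `width_h`, `ar_tau` (AR(1)
#'   autocorrelation time in samples).
#' @param noise_sd relative SD of multiplicative complex measurement noise
#'   on the impedance (0 = noise-free).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, dt_s = 160,
                       frequencies = ecis_frequencies(),
                       electrode = calibrate_naked_electrode(),
                       groups = list(control = sim_group(front_speed = 10.69,
                                                         well_sd_ohm = 479.6),
                                     case = sim_group(front_speed = 8.6,
                                                      well_sd_ohm = 609.6)),
                       schedule = phase_schedule(),
                       wound_radius_um = 125,
                       pulse = list(amplitude_mA = 3, frequency_kHz = 40,
                                    duration_s = 30),
                       micromotion = list(enabled = TRUE, high_var = 4e-4,
                                          low_var = 4e-6, midpoint_h = 11.5,
                                          width_h = 1.5, ar_tau = 5),
                       noise_sd = 0) {
  if (dt_s <= 0) stop_domain("dt_s must be > 0")
  if (isTRUE(micromotion$enabled) &&
      micromotion$high_var < micromotion$low_var) {
    stop_domain("micromotion high_var must be >= low_var")
  }
  structure(list(seed = as.integer(seed), dt_s = dt_s,
                 frequencies = frequencies, electrode = electrode,
                 groups = groups, schedule = schedule,
                 wound_radius_um = wound_radius_um, pulse = pulse,
                 micromotion = micromotion, noise_sd = noise_sd),
            class = "sim_config")
}

# smooth 0 -> 1 cosine ramp on [0, 1]
cos_ramp <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  (1 - cos(pi * x)) / 2
}

# covered-electrode specific impedance at scalar f for a VECTOR of Rb
# (gamma does not depend on Rb, so one Bessel evaluation serves all times)
gk_covered_rbvec <- function(f, m, alpha, Rb, Cm) {
  Zn <- naked_electrode_impedance(f, m)
  Zm <- 2 / (1i * 2 * pi * f * Cm)
  ysum <- 1 / Zn + 1 / Zm
  g <- alpha * sqrt(ysum)
  ratio <- bessel_i01_ratio(g)
  invZc <- (1 / Zn) * (Zn / (Zn + Zm) +
                       (Zm / (Zn + Zm)) / ((g / 2) * ratio + Rb * ysum))
  1 / invZc
}

# AR(1) series with slowly varying marginal variance schedule
ar1_schedule <- function(varsched, tau) {
  phi <- exp(-1 / tau)
  n <- length(varsched)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sqrt(varsched[1]))
  innov <- rnorm(n)
  s <- sqrt(pmax(varsched, 0) * (1 - phi^2))
  for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i] * s[i]
  e
}

# micromotion relative-variance schedule over the experiment timeline:
# high during attachment/differentiation, descending-logistic transition
# after the resistance peak, re-armed by the wound.
micromotion_varsched <- function(t_h, sch, mm) {
  d1 <- 1 / (1 + exp((t_h - (sch$peak_h + mm$midpoint_h)) / mm$width_h))
  act <- d1
  post <- t_h >= sch$wound_h
  if (any(post)) {
    d2 <- 1 / (1 + exp((t_h[post] - (sch$wound_h + mm$midpoint_h)) / mm$width_h))
    act[post] <- pmax(act[post], d2)
  }
  mm$low_var + (mm$high_var - mm$low_var) * act
}

#' Simulate a complete multi-frequency ECIS experiment
#'
#' Generates an [impedance_timeseries()] with the canonical structure of
#' an epithelial wound-healing experiment: attachment and spreading
#' (coverage ramp), barrier formation to a day-2 resistance peak,
#' maturation decline to a plateau, an instantaneous electrical wound
#' (coverage to 0, resistance to the cell-free level), radial-front
#' recovery at each group's front speed, a migration plateau, a second
#' maturation decline, AR(1) micromotion on the barrier resistance, and
#' optional multiplicative complex measurement noise. All barrier
#' resistance levels are calibrated so the noise-free 4 kHz resistance
#' hits the schedule's peak, plateau and cell-free values exactly.
#'
#' The returned object carries a `ground_truth` attribute with the
#' per-well true front speeds, alpha and calibrated Rb levels.
#'
#' @param cfg a [sim_config()].
#' @return an `ecis_its`.
#' @export
simulate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sch <- cfg$schedule
  m <- cfg$electrode
  set.seed(cfg$seed)
  times_s <- seq(0, sch$total_h * 3600, by = cfg$dt_s)
  t_h <- times_s / 3600
  nt <- length(t_h)
  wells <- character(0)
  groups_of_well <- character(0)
  for (gname in names(cfg$groups)) {
    g <- cfg$groups[[gname]]
    w <- sprintf("%s_w%02d", gname, seq_len(g$n_wells))
    wells <- c(wells, w)
    groups_of_well <- c(groups_of_well, rep(gname, g$n_wells))
  }
  z <- array(NA_complex_, c(nt, length(wells), length(cfg$frequencies)))
  truth <- list(seed = cfg$seed, schedule = unclass(sch), wells = list())

  post_heal_end <- sch$wound_h + sch$post_heal_hold_h
  for (iw in seq_along(wells)) {
    g <- cfg$groups[[groups_of_well[iw]]]
    off <- if (g$well_sd_ohm > 0) rnorm(1, 0, g$well_sd_ohm) else 0
    Rb_peak <- calibrate_barrier_resistance(sch$peak_R4k + off, g$alpha, m, g$Cm)
    Rb_plat <- calibrate_barrier_resistance(sch$plateau_R4k + off, g$alpha, m, g$Cm)
    Rb_mig <- calibrate_barrier_resistance(sch$migration_R4k + off, g$alpha, m, g$Cm)

    # deterministic coverage and Rb trajectories
    coverage <- cos_ramp(t_h / sch$coverage_rise_h)
    Rb <- Rb_peak * cos_ramp(t_h / sch$peak_h)
    mat <- t_h > sch$peak_h
    Rb[mat] <- Rb_plat + (Rb_peak - Rb_plat) *
      (1 - cos_ramp((t_h[mat] - sch$peak_h) / sch$maturation_h))
    post <- t_h >= sch$wound_h
    coverage[post] <- simulate_wound_recovery_coverage(
      t_h[post] - sch$wound_h, g$front_speed, cfg$wound_radius_um)
    Rb[post] <- Rb_mig
    second <- t_h > post_heal_end
    Rb[second] <- Rb_plat + (Rb_mig - Rb_plat) *
      (1 - cos_ramp((t_h[second] - post_heal_end) / sch$maturation_h))

    # micromotion: mean-reverting multiplicative perturbation of Rb
    if (isTRUE(cfg$micromotion$enabled) && cfg$micromotion$high_var > 0) {
      vs <- micromotion_varsched(t_h, sch, cfg$micromotion)
      e <- ar1_schedule(vs, cfg$micromotion$ar_tau)
      Rb_eff <- Rb * (1 + e)
      Rb_eff <- pmax(Rb_eff, 1e-9)
    } else {
      Rb_eff <- Rb
    }

    for (jf in seq_along(cfg$frequencies)) {
      f <- cfg$frequencies[jf]
      Zc <- gk_covered_rbvec(f, m, g$alpha, Rb_eff, g$Cm)
      Zn <- naked_electrode_impedance(f, m)
      zmix <- 1 / (coverage / Zc + (1 - coverage) / Zn) / m$area
      z[, iw, jf] <- zmix
    }
    truth$wells[[wells[iw]]] <- list(
      group = groups_of_well[iw], front_speed = g$front_speed,
      alpha = g$alpha, Cm = g$Cm, well_offset_ohm = off,
      Rb_peak = Rb_peak, Rb_plateau = Rb_plat, Rb_migration = Rb_mig)
  }

  if (cfg$noise_sd > 0) {
    nz <- length(z)
    fac <- 1 + complex(real = rnorm(nz), imaginary = rnorm(nz)) *
      cfg$noise_sd / sqrt(2)
    z <- z * array(fac, dim(z))
  }

  out <- impedance_timeseries(times_s, wells, cfg$frequencies, z,
                              metadata = list(
                                electrode_area_cm2 = m$area,
                                electrode_diameter_um = 250,
                                pulse = cfg$pulse))
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate a covered-electrode impedance spectrum
#'
#' Forward Giaever-Keese spectrum at the standard frequency grid, with
#' optional partial coverage and multiplicative complex Gaussian noise.
#' Used as test input for [fit_alpha()].
#'
#' @param p a `gk_cell_params`.
#' @param m a `gk_electrode`.
#' @param coverage covered fraction (default 1).
#' @param noise_sd relative noise SD (default 0).
#' @param seed optional RNG seed.
#' @param frequencies frequency grid, Hz.
#' @return data.frame `frequency_hz`, `z_real_ohm`, `z_imag_ohm`
#'   (absolute Ohm).
#' @export
simulate_spectrum <- function(p, m, coverage = 1, noise_sd = 0, seed = NULL,
                              frequencies = ecis_frequencies()) {
  if (!is.null(seed)) set.seed(seed)
  zspec <- mixed_coverage_impedance(frequencies, m, p, coverage) / m$area
  if (noise_sd > 0) {
    fac <- 1 + complex(real = rnorm(length(zspec)),
                       imaginary = rnorm(length(zspec))) * noise_sd / sqrt(2)
    zspec <- zspec * fac
  }
  data.frame(frequency_hz = frequencies,
             z_real_ohm = Re(zspec), z_imag_ohm = Im(zspec))
}

#' Simulate a logistic healing curve
#'
#' Direct four-parameter logistic resistance recovery with optional
#' additive Gaussian noise scaled to the dynamic range; the elementary
#' fixture for sigmoid-fit validation.
#'
#' @param t50 inflection point, h.
#' @param hill_slope steepness, 1/h.
#' @param R_base post-wound floor, Ohm.
#' @param R_plateau healed plateau, Ohm.
#' @param hours duration, h.
#' @param dt_s sampling interval, s.
#' @param noise_frac additive noise SD as a fraction of
#'   `R_plateau - R_base`.
#' @param seed optional RNG seed.
#' @return an `ecis_channel` resistance trace (time origin 0 = wound).
#' @export
simulate_healing_curve <- function(t50 = 7.06, hill_slope = 0.54,
                                   R_base = 2600, R_plateau = 8500,
                                   hours = 24, dt_s = 160, noise_frac = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, hours, by = dt_s / 3600)
  R <- R_base + (R_plateau - R_base) / (1 + exp(-hill_slope * (t - t50)))
  if (noise_frac > 0) {
    R <- R + rnorm(length(R), 0, noise_frac * (R_plateau - R_base))
  }
  channel_trace(t, R, kind = "R", well = "sim", frequency_hz = 4000)
}

#' Simulate a linear attachment segment
#'
#' @param slope attachment slope, Ohm/h.
#' @param intercept resistance at t = 0, Ohm.
#' @param hours duration, h.
#' @param dt_s sampling interval, s.
#' @param noise_sd additive Gaussian noise SD, Ohm.
#' @param seed optional RNG seed.
#' @return an `ecis_channel` resistance trace.
#' @export
simulate_attachment_trace <- function(slope = 9.43, intercept = 2600,
                                      hours = 12, dt_s = 160, noise_sd = 0,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, hours, by = dt_s / 3600)
  R <- intercept + slope * t
  if (noise_sd > 0) R <- R + rnorm(length(R), 0, noise_sd)
  channel_trace(t, R, kind = "R", well = "sim", frequency_hz = 4000)
}

#' Simulate a post-wound micromotion trace
#'
#' Plateau-level resistance trace carrying AR(1) relative fluctuations
#' whose variance follows a descending logistic schedule: the signature
#' of an epithelial layer transitioning from a migratory/high-activity
#' state to a quiescent one. The schedule is specified on the variance
#' (power) scale, which is what the moving-variance pipeline estimates.
#'
#' @param hours duration, h (default covers one 512-sample segment plus
#'   margin).
#' @param base_R plateau resistance, Ohm.
#' @param high_var,low_var relative-fluctuation variance in the active /
#'   quiescent states.
#' @param midpoint_h schedule midpoint, h from trace start.
#' @param width_h logistic width, h.
#' @param ar_tau AR(1) autocorrelation time, samples.
#' @param dt_s sampling interval, s.
#' @param seed optional RNG seed.
#' @return an `ecis_channel` resistance trace.
#' @export
simulate_micromotion_trace <- function(hours = 24.9, base_R = 8500,
                                       high_var = 4e-4, low_var = 4e-6,
                                       midpoint_h = 11.5, width_h = 1.5,
                                       ar_tau = 5, dt_s = 160, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, hours, by = dt_s / 3600)
  vs <- low_var + (high_var - low_var) / (1 + exp((t - midpoint_h) / width_h))
  e <- ar1_schedule(vs, ar_tau)
  channel_trace(t, base_R * (1 + e), kind = "R", well = "sim",
                frequency_hz = 4000)
}
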