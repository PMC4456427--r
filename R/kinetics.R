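#' Detect an electrical wound event in a resistance trace
#'
#' A wound is the signature of the elevated current pulse: the monolayer
#' resistance, previously well above the cell-free reference, collapses to
#' the cell-free level. `t_wound` is the first time the trace falls within
#' `tol` (fractional) of `cellfree_R` after having exceeded
#' `2 * cellfree_R`; the post-wound baseline is the trace minimum in the
#' following 30 minutes.
#'
#' @param trace an `ecis_channel` resistance trace (R at 4 kHz).
#' @param cellfree_R cell-free electrode resistance, Ohm (default 2600).
#' @param tol fractional tolerance around `cellfree_R` (default 0.1).
#' @param pulse optional pulse descriptor metadata (e.g.
#'   `list(amplitude_mA = 3, frequency_kHz = 40, duration_s = 30)`).
#' @return a `wound_event`: list with `t_wound` (h), `baseline` (Ohm),
#'   `pulse`.
#' @export
detect_wound <- function(trace, cellfree_R = 2600, tol = 0.1, pulse = NULL) {
  if (cellfree_R <= 0) stop_domain("cellfree_R must be > 0")
  ok <- !is.na(trace$value)
  t <- trace$time_h[ok]; v <- trace$value[ok]
  high <- v > 2 * cellfree_R
  near <- abs(v - cellfree_R) <= tol * cellfree_R
  if (!any(high)) stop_domain("no wound detected: trace never exceeds 2x cell-free level")
  first_high <- which(high)[1]
  cand <- which(near & seq_along(v) > first_high)
  if (!length(cand)) stop_domain("no wound detected: no drop to the cell-free level")
  iw <- cand[1]
  t_wound <- t[iw]
  after <- v[t >= t_wound & t <= t_wound + 0.5]
  structure(list(t_wound = t_wound,
                 baseline = min(after),
                 pulse = pulse),
            class = "wound_event")
}

#' Fit a four-parameter logistic to the post-wound healing curve
#'
#' Least-squares fit of
#' `R(t) = R_base + (R_plateau - R_base) / (1 + exp(-hill_slope (t - t50)))`
#' with `t` in hours measured from the wound time, over
#' `[t_wound, t_wound + window]`. The inflection point `t50` and the hill
#' slope summarise the healing kinetics. Multi-start on t50 at 25/50/75%
#' of the window.
#'
#' @param trace an `ecis_channel` resistance trace.
#' @param wound a `wound_event` (or a numeric wound time in hours).
#' @param window fit window length in hours (default 24; choose it to end
#'   before the post-healing maturation decline).
#' @return a `sigmoid_fit`: `R_base`, `R_plateau`, `hill_slope` (1/h),
#'   `t50` (h from wound), `residual_sd` (Ohm), `converged`.
#' @export
fit_healing_sigmoid <- function(trace, wound, window = 24) {
  t0 <- if (inherits(wound, "wound_event")) wound$t_wound else as.numeric(wound)
  keep <- !is.na(trace$value) & trace$time_h >= t0 & trace$time_h <= t0 + window
  tt <- trace$time_h[keep] - t0
  R <- trace$value[keep]
  if (length(tt) < 20) stop_domain("fewer than 20 samples in the fit window")

  rng <- diff(range(R))
  if (rng < max(1e-9, 1e-6 * max(abs(R)))) {
    return(structure(list(R_base = mean(R), R_plateau = mean(R),
                          hill_slope = NA_real_, t50 = NA_real_,
                          residual_sd = sd(R), converged = FALSE),
                     class = "sigmoid_fit"))
  }

  best <- NULL
  for (t50s in quantile(tt, c(0.25, 0.5, 0.75), names = FALSE)) {
    fit <- tryCatch(suppressWarnings(
      nls(R ~ lo + (hi - lo) / (1 + exp(-k * (tt - t50))),
          start = list(lo = min(R), hi = max(R), k = 4 / diff(range(tt)),
                       t50 = t50s),
          control = nls.control(maxiter = 1000, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(R_base = NA_real_, R_plateau = NA_real_,
                          hill_slope = NA_real_, t50 = NA_real_,
                          residual_sd = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  cf <- coef(best)
  nls_ok <- isTRUE(best$convInfo$isConv)
  if (!nls_ok) {
    # nls can stall on sharp-cornered curves (singular gradient near the
    # plateau); polish with a quasi-Newton pass on the same objective
    obj <- function(p) {
      pred <- p[1] + (p[2] - p[1]) / (1 + exp(-exp(p[3]) * (tt - p[4])))
      sum((R - pred)^2)
    }
    o <- tryCatch(
      optim(c(cf[["lo"]], cf[["hi"]], log(max(cf[["k"]], 1e-6)), cf[["t50"]]),
            obj, method = "BFGS", control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o)) {
      cf <- c(lo = o$par[1], hi = o$par[2], k = exp(o$par[3]), t50 = o$par[4])
      dev <- o$value
      nls_ok <- o$convergence == 0
    } else dev <- deviance(best)
  } else dev <- deviance(best)
  converged <- nls_ok &&
    cf[["k"]] > 0 && cf[["hi"]] > cf[["lo"]] && cf[["t50"]] > 0
  structure(list(R_base = cf[["lo"]], R_plateau = cf[["hi"]],
                 hill_slope = cf[["k"]], t50 = cf[["t50"]],
                 residual_sd = sqrt(dev / max(length(R) - 4, 1)),
                 converged = converged),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> t50 = %.3f h, hill slope = %.3f 1/h\n",
              x$t50, x$hill_slope))
  cat(sprintf("  R: %.0f -> %.0f Ohm; residual SD %.1f; converged: %s\n",
              x$R_base, x$R_plateau, x$residual_sd, x$converged))
  invisible(x)
}

#' Healing completion time from a sigmoid fit
#'
#' Smallest t (hours from the wound) at which the fitted curve has
#' recovered a fraction `threshold` of its dynamic range; in closed form
#' `t = t50 + log(threshold / (1 - threshold)) / hill_slope`.
#'
#' @param fit a converged `sigmoid_fit`.
#' @param threshold recovery fraction in (0, 1), default 0.95.
#' @return time in hours.
#' @export
healing_time <- function(fit, threshold = 0.95) {
  if (!inherits(fit, "sigmoid_fit") || !isTRUE(fit$converged)) {
    stop_domain("healing_time requires a converged sigmoid fit")
  }
  if (threshold <= 0 || threshold >= 1) stop_domain("threshold must be in (0, 1)")
  fit$t50 + log(threshold / (1 - threshold)) / fit$hill_slope
}

#' Migration rate from a healing time
#'
#' `rate = wound_radius / healing_time`. The radius convention treats the
#' wound as closing radially inward from the edge of the circular wound
#' (125 um for the 250 um ECIS electrode); the diameter convention uses
#' the full 250 um.
#'
#' @param healing_time healing (repopulation) time in hours.
#' @param wound_radius wound radius in um (default 125).
#' @param convention `"radius"` (default) or `"diameter"`.
#' @return migration rate in um/h.
#' @export
migration_rate <- function(healing_time, wound_radius = 125,
                           convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  if (any(healing_time <= 0) || any(wound_radius <= 0)) {
    stop_domain("healing_time and wound_radius must be > 0")
  }
  d <- if (convention == "radius") wound_radius else 2 * wound_radius
  d / healing_time
}

#' Migration result for one well
#'
#' Bundles healing time, wound radius and the implied migration rate
#' (invariant: `rate = wound_radius / healing_time`).
#'
#' @inheritParams migration_rate
#' @return a `migration_result` list.
#' @export
migration_result <- function(healing_time, wound_radius = 125) {
  structure(list(healing_time = healing_time, wound_radius = wound_radius,
                 rate = migration_rate(healing_time, wound_radius)),
            class = "migration_result")
}

#' Fractional cell coverage from the 64 kHz capacitance channel
#'
#' At high frequency most current crosses the cell layer capacitively and
#' the measured capacitance interpolates linearly between the cell-free
#' and confluent values, so coverage(t) = (C_free - C(t)) /
#' (C_free - C_confluent), clipped to \[0, 1\].
#'
#' @param trace an `ecis_channel` capacitance trace (C at 64 kHz).
#' @param C_free cell-free capacitance, F.
#' @param C_confluent confluent-layer capacitance, F; must be < `C_free`.
#' @return data.frame `time_h`, `coverage`, with attribute
#'   `clipping_fraction` (fraction of samples clipped into \[0, 1\]).
#' @export
coverage_from_capacitance <- function(trace, C_free, C_confluent) {
  if (!(C_free > C_confluent && C_confluent > 0)) {
    stop_domain("calibration error: need C_free > C_confluent > 0")
  }
  cov <- (C_free - trace$value) / (C_free - C_confluent)
  clipped <- !is.na(cov) & (cov < 0 | cov > 1)
  cov <- pmin(pmax(cov, 0), 1)
  structure(data.frame(time_h = trace$time_h, coverage = cov),
            clipping_fraction = mean(clipped, na.rm = TRUE),
            class = c("coverage_trace", "data.frame"))
}

#' Radial front speed from a coverage trace
#'
#' For a circular wound healed by an inward radial front with speed v, the
#' open-area fraction satisfies `sqrt(1 - coverage(t)) = (r - v t)/r`,
#' i.e. it decays linearly in time at rate v/r. The front speed is
#' estimated by ordinary least squares on `sqrt(1 - coverage)` against
#' time over the post-wound samples with coverage below `cov_max`, and the
#' repopulation (healing) time is the zero crossing of that line.
#'
#' This is the package's migration-rate estimator: unlike a threshold on
#' the fitted resistance sigmoid it is unbiased for the front model, whose
#' closure is tangential (zero slope) in the resistance channel.
#'
#' @param coverage a `coverage_trace` from [coverage_from_capacitance()].
#' @param wound a `wound_event` or numeric wound time (h).
#' @param wound_radius wound radius in um (default 125).
#' @param cov_min,cov_max coverage limits of the regression window
#'   (defaults 0.02 and 0.95: excludes the wound sample itself and the
#'   tangential closure region where sqrt is noise-amplifying).
#' @return a `migration_result` with elements `healing_time` (h),
#'   `wound_radius` (um), `rate` (um/h) plus `front_speed` and
#'   `n_samples`.
#' @export
front_speed_from_coverage <- function(coverage, wound, wound_radius = 125,
                                      cov_min = 0.02, cov_max = 0.95) {
  t0 <- if (inherits(wound, "wound_event")) wound$t_wound else as.numeric(wound)
  keep <- !is.na(coverage$coverage) & coverage$time_h >= t0
  tt <- coverage$time_h[keep] - t0
  cv <- coverage$coverage[keep]
  # stop at the first closure so post-plateau samples don't enter
  closed <- which(cv >= cov_max)
  if (length(closed)) {
    lim <- closed[1] - 1
    tt <- tt[seq_len(lim)]; cv <- cv[seq_len(lim)]
  }
  sel <- cv >= cov_min & cv <= cov_max
  if (sum(sel) < 5) stop_domain("too few samples on the healing front")
  g <- sqrt(1 - cv[sel])
  fit <- lm(g ~ tt[sel])
  slope <- coef(fit)[[2]]
  if (slope >= 0) stop_domain("coverage does not increase: no healing front")
  v <- -slope * wound_radius
  t_close <- -coef(fit)[[1]] / slope
  out <- migration_result(t_close, wound_radius)
  out$front_speed <- v
  out$n_samples <- sum(sel)
  out
}

#' Attachment-slope adhesion assay
#'
#' Cells seeded at confluency attach and spread during the first hours of
#' culture, driving a near-linear rise in the 4 kHz resistance; the slope
#' of that rise is an adhesion indicator. The fit is ordinary least
#' squares over the rising segment of the window: from the window start to
#' the first time the trace reaches 95% of its within-window rise
#' (min + 0.95 * range). For a constant trace the full window is used and
#' the slope is 0.
#'
#' @param trace an `ecis_channel` resistance trace.
#' @param window fit window in hours from the start of the trace
#'   (default 24; the assay is defined on the first 24 h of culture).
#' @return an `attachment_fit`: `slope` (Ohm/h), `intercept` (Ohm),
#'   `window` (h actually used), `r_squared`, `n`.
#' @export
attachment_slope <- function(trace, window = 24) {
  if (window > 24 + 1e-9) stop_domain("attachment window must lie within the first 24 h")
  t_start <- min(trace$time_h, na.rm = TRUE)
  keep <- !is.na(trace$value) & trace$time_h <= t_start + window
  tt <- trace$time_h[keep]; v <- trace$value[keep]
  rng <- max(v) - min(v)
  if (rng > 0) {
    thr <- min(v) + 0.95 * rng
    end <- which(v >= thr)[1]
    tt <- tt[seq_len(end)]; v <- v[seq_len(end)]
  }
  if (length(tt) < 10) stop_domain("fewer than 10 samples in the rising segment")
  fit <- lm(v ~ tt)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  structure(list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
                 window = max(tt) - min(tt),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(v)),
            class = "attachment_fit")
}

#' @export
print.attachment_fit <- function(x, ...) {
  cat(sprintf("<attachment_fit> slope = %.3f Ohm/h over %.1f h (n = %d, R^2 = %.3f)\n",
              x$slope, x$window, x$n, x$r_squared))
  invisible(x)
}
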