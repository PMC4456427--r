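#' Detrend and normalise a resistance segment
#'
#' Micromotion preprocessing: subtract the least-squares line (removing
#' the slow trend of the segment) and divide by the pre-detrend mean of
#' the series, yielding a dimensionless fluctuation signal with mean
#' approximately zero. The result is invariant to rescaling the input.
#'
#' @param values numeric series (Ohm); at least 3 samples.
#' @param times optional time stamps for the regression abscissa
#'   (defaults to the sample index).
#' @return dimensionless numeric series.
#' @export
detrend_normalize <- function(values, times = seq_along(values)) {
  if (length(values) < 3) stop_domain("need at least 3 samples")
  mu <- mean(values)
  if (abs(mu) < 1e-12 * max(1, max(abs(values)))) {
    stop_domain("normalization error: series mean is zero")
  }
  resid(lm(values ~ times)) / mu
}

#' Moving variance of a fluctuation series
#'
#' Unbiased sample variance in a sliding window, the micromotion summary
#' statistic: window of 150 samples, sliding step 1 over 512-sample
#' segments by convention (giving 363 output points per segment at the
#' 160 s acquisition interval, i.e. 22.75 h of data).
#'
#' @param values dimensionless series (typically [detrend_normalize()]
#'   output), length >= `window`.
#' @param window window length in samples (default 150).
#' @param step sliding step in samples (default 1).
#' @param dt_s sampling interval in seconds (default 160); used for the
#'   window-centre time stamps.
#' @param t0_h time of the first sample in hours (default 0).
#' @return a `variance_trace`: data.frame `time_h` (window centres),
#'   `variance`, with attributes `window`, `step`, `dt_s`.
#' @export
moving_variance <- function(values, window = 150L, step = 1L, dt_s = 160,
                            t0_h = 0) {
  n <- length(values)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2 || step < 1) stop_domain("window >= 2 and step >= 1 required")
  if (window > n) stop_domain("window longer than series (", n, " samples)")
  starts <- seq.int(1L, n - window + 1L, by = step)
  # running first and second moments via cumulative sums
  cs <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  s1 <- cs[starts + window] - cs[starts]
  s2 <- cs2[starts + window] - cs2[starts]
  v <- (s2 - s1^2 / window) / (window - 1)
  v <- pmax(v, 0)  # guard tiny negative round-off
  centre <- (starts - 1) + (window - 1) / 2
  structure(data.frame(time_h = t0_h + centre * dt_s / 3600, variance = v),
            window = window, step = step, dt_s = dt_s,
            class = c("variance_trace", "data.frame"))
}

# mean of a descending unit logistic 1/(1+exp((t-m)/w)) over [a, b]
# (closed form; used to model the moving-variance window smoothing)
window_mean_logistic <- function(tc, halfspan, m, w) {
  a <- tc - halfspan; b <- tc + halfspan
  if (halfspan <= 0) return(1 / (1 + exp((tc - m) / w)))
  (w * (softplus(-(a - m) / w) - softplus(-(b - m) / w))) / (b - a)
}

#' Transition half-time of a micromotion variance trace
#'
#' Fits a descending logistic (high plateau, low plateau, midpoint,
#' width) to the moving-variance trace and reports the fitted midpoint:
#' the half-time of the transition from a high-activity to a quiescent
#' state. Two refinements make the estimate identifiable on single
#' 512-sample segments: the logistic is convolved with the moving-variance
#' window (closed form) so the window smoothing does not bias the
#' midpoint, and residuals are taken on the log of the variance, which is
#' approximately homoscedastic for windowed variance estimates.
#'
#' @param vt a `variance_trace` from [moving_variance()].
#' @return a `transition_estimate`: `half_time` (h, same origin as the
#'   trace time stamps), `high`, `low` (variance plateau levels), `width`
#'   (h), `converged` (FALSE when the fit fails or high <= low).
#' @export
transition_half_time <- function(vt) {
  tc <- vt$time_h
  v <- pmax(vt$variance, 0)
  if (all(v <= 0) || length(v) < 10) {
    return(structure(list(half_time = NA_real_, high = NA_real_,
                          low = NA_real_, width = NA_real_,
                          converged = FALSE),
                     class = "transition_estimate"))
  }
  eps <- max(v) * 1e-9
  lv <- log(v + eps)
  halfspan <- (attr(vt, "window") - 1) / 2 * attr(vt, "dt_s") / 3600

  inner <- function(m, w) {
    s <- window_mean_logistic(tc, halfspan, m, w)
    o <- optim(c(log(max(v)), log(max(min(v), eps))),
               function(p) {
                 pr <- exp(p[2]) + (exp(p[1]) - exp(p[2])) * s
                 sum((lv - log(pr + eps))^2)
               }, method = "BFGS", control = list(maxit = 200))
    o
  }
  best <- NULL
  for (m in seq(min(tc), max(tc), length.out = 40)) {
    for (w in c(0.5, 1, 2, 4)) {
      o <- tryCatch(inner(m, w), error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) {
        best <- o; best$m <- m; best$w <- w
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(half_time = NA_real_, high = NA_real_,
                          low = NA_real_, width = NA_real_,
                          converged = FALSE),
                     class = "transition_estimate"))
  }
  span <- diff(range(tc))
  refine <- tryCatch(
    optim(c(best$par, best$m, log(best$w)),
          function(q) {
            pr <- exp(q[2]) + (exp(q[1]) - exp(q[2])) *
              window_mean_logistic(tc, halfspan, q[3], exp(q[4]))
            sum((lv - log(pr + eps))^2)
          },
          method = "L-BFGS-B",
          lower = c(log(eps), log(eps), min(tc) - span / 4, log(0.05)),
          upper = c(log(max(v) * 10), log(max(v) * 10), max(tc) + span / 4,
                    log(span)),
          control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(refine)) refine <- list(par = c(best$par, best$m, log(best$w)))
  hi <- exp(refine$par[1]); lo <- exp(refine$par[2])
  structure(list(half_time = refine$par[3], high = hi, low = lo,
                 width = exp(refine$par[4]),
                 converged = hi > lo),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("<transition_estimate> half-time = %.2f h (high %.3g -> low %.3g); converged: %s\n",
              x$half_time, x$high, x$low, x$converged))
  invisible(x)
}

#' Micromotion pipeline for a resistance trace
#'
#' Splits the trace into consecutive non-overlapping segments of
#' `segment` samples (trailing partial segment dropped), detrends and
#' normalises each segment, and computes the moving variance. Returns one
#' `variance_trace` per segment.
#'
#' @param trace an `ecis_channel` resistance trace (NA-free within the
#'   analysed span; flagged gaps should be windowed out beforehand).
#' @param window,step see [moving_variance()].
#' @param segment segment length in samples (default 512).
#' @return list of `variance_trace` objects.
#' @export
micromotion_analysis <- function(trace, window = 150L, step = 1L,
                                 segment = 512L) {
  ok <- !is.na(trace$value)
  t <- trace$time_h[ok]; v <- trace$value[ok]
  nseg <- length(v) %/% segment
  if (nseg < 1) stop_domain("trace shorter than one segment (", segment, " samples)")
  dt_s <- if (length(t) > 1) round(mean(diff(t)) * 3600) else 160
  lapply(seq_len(nseg), function(k) {
    i <- ((k - 1) * segment + 1):(k * segment)
    d <- detrend_normalize(v[i], t[i])
    moving_variance(d, window = window, step = step, dt_s = dt_s,
                    t0_h = t[i[1]])
  })
}
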