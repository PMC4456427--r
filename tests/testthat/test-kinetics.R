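test_that("detect_wound finds the wound sample on simulator output", {
  ts <- simulate_timecourse(quick_sim(wound_h = 200, total_h = 230))
  r4k <- extract_channel(ts, "g_w01", 4000, "R")
  w <- detect_wound(r4k, 2600)
  expect_s3_class(w, "wound_event")
  expect_equal(w$t_wound, 200, tolerance = 160 / 3600 / 200)  # within one sample
  expect_equal(w$baseline, 2600, tolerance = 1e-6)
})

test_that("detect_wound degenerate inputs", {
  up <- channel_trace(seq(0, 24, by = 0.1), seq(3000, 9000, length.out = 241))
  expect_error(detect_wound(up, 2600), "no wound detected")
  # two sequential wounds: first is returned, second discoverable by windowing
  t <- seq(0, 100, by = 160 / 3600)
  v <- rep(8000, length(t))
  v[t >= 30 & t < 40] <- 2600 + 500 * pmin(t[t >= 30 & t < 40] - 30, 8)
  v[t >= 70 & t < 80] <- 2600 + 500 * pmin(t[t >= 70 & t < 80] - 70, 8)
  tr <- channel_trace(t, v)
  w1 <- detect_wound(tr, 2600)
  expect_equal(w1$t_wound, 30, tolerance = 0.1)
  w2 <- detect_wound(window_channel(tr, 45, 100), 2600)
  expect_equal(w2$t_wound, 70, tolerance = 0.1)
})

test_that("sigmoid fit recovers noise-free control parameters to 1e-6", {
  tr <- simulate_healing_curve(t50 = 7.06, hill_slope = 0.54,
                               R_base = 2600, R_plateau = 8500)
  fit <- fit_healing_sigmoid(tr, 0)
  expect_true(fit$converged)
  expect_equal(fit$t50, 7.06, tolerance = 1e-6)
  expect_equal(fit$hill_slope, 0.54, tolerance = 1e-6)
  expect_equal(fit$R_base, 2600, tolerance = 1e-6)
  expect_equal(fit$R_plateau, 8500, tolerance = 1e-6)
})

test_that("sigmoid fit flags degenerate traces and short windows", {
  const <- channel_trace(seq(0, 24, by = 160 / 3600), rep(5000, 541))
  fit <- fit_healing_sigmoid(const, 0)
  expect_false(fit$converged)
  short <- channel_trace(seq(0, 0.5, by = 0.1), rep(5000, 6))
  expect_error(fit_healing_sigmoid(short, 0), "20 samples")
})

test_that("sigmoid fit equals a grid-search oracle on a noisy curve", {
  tr <- simulate_healing_curve(t50 = 8, hill_slope = 0.5, noise_frac = 0.02,
                               seed = 11)
  tt <- tr$time_h; R <- tr$value
  # oracle: grid over (t50, k) with closed-form linear solve of (lo, hi)
  ssq_lin <- function(t50, k) {
    s <- 1 / (1 + exp(-k * (tt - t50)))
    fit <- stats::lm.fit(cbind(1, s), R)
    sum(fit$residuals^2)
  }
  grid <- expand.grid(t50 = seq(2, 20, length.out = 200),
                      k = seq(0.05, 3, length.out = 200))
  val <- mapply(ssq_lin, grid$t50, grid$k)
  b <- grid[which.min(val), ]
  ref <- optim(c(b$t50, b$k), function(p) ssq_lin(p[1], p[2]),
               method = "BFGS")
  fit <- fit_healing_sigmoid(tr, 0)
  expect_equal(fit$t50, ref$par[1], tolerance = 1e-4)
  expect_equal(fit$hill_slope, ref$par[2], tolerance = 1e-4)
})

test_that("sigmoid recovery under noise stays within one printed SE (property)", {
  cases <- list(control = c(t50 = 7.06, k = 0.54, se_t50 = 0.27, se_k = 0.07),
                case = c(t50 = 8.94, k = 0.41, se_t50 = 0.29, se_k = 0.04))
  for (nm in names(cases)) {
    cc <- cases[[nm]]
    t50s <- ks <- numeric(20)
    for (s in 1:20) {
      tr <- simulate_healing_curve(cc[["t50"]], cc[["k"]], noise_frac = 0.02,
                                   seed = s)
      fit <- fit_healing_sigmoid(tr, 0)
      expect_true(fit$converged)
      t50s[s] <- fit$t50; ks[s] <- fit$hill_slope
    }
    expect_lt(abs(mean(t50s) - cc[["t50"]]), cc[["se_t50"]])
    expect_lt(abs(mean(ks) - cc[["k"]]), cc[["se_k"]])
  }
})

test_that("healing_time closed form and monotonicity", {
  fit <- structure(list(R_base = 2600, R_plateau = 8500, hill_slope = 0.54,
                        t50 = 7.06, residual_sd = 0, converged = TRUE),
                   class = "sigmoid_fit")
  expect_equal(healing_time(fit, 0.5), 7.06)  # symmetry of the logistic
  expect_equal(healing_time(fit, 0.95), 7.06 + log(19) / 0.54)
  expect_equal(healing_time(fit, 0.95), 12.51, tolerance = 1e-3)
  expect_gt(healing_time(fit, 0.99), healing_time(fit, 0.95))
  # strictly decreasing in hill slope at fixed t50 and threshold
  hts <- vapply(c(0.2, 0.4, 0.8, 1.6), function(k) {
    f2 <- fit; f2$hill_slope <- k
    healing_time(f2, 0.95)
  }, 0)
  expect_true(all(diff(hts) < 0))
  bad <- fit; bad$converged <- FALSE
  expect_error(healing_time(bad), "converged")
})

test_that("migration_rate arithmetic and conventions", {
  expect_equal(migration_rate(11.69, 125), 10.69, tolerance = 1e-3)
  expect_equal(migration_rate(14.53, 125), 8.60, tolerance = 1e-3)
  expect_equal(migration_rate(10, 250), 2 * migration_rate(10, 125))
  expect_equal(migration_rate(10, 125, convention = "diameter"),
               2 * migration_rate(10, 125))
  expect_error(migration_rate(-1, 125), "must be > 0")
  mr <- migration_result(11.69, 125)
  expect_equal(mr$rate, mr$wound_radius / mr$healing_time)
})

test_that("fit is equivariant under affine rescaling of the trace (property)", {
  tr <- simulate_healing_curve(t50 = 7, hill_slope = 0.5, noise_frac = 0.01,
                               seed = 3)
  fit1 <- fit_healing_sigmoid(tr, 0)
  tr2 <- tr; tr2$value <- 3 * tr$value + 1000
  fit2 <- fit_healing_sigmoid(tr2, 0)
  expect_equal(fit2$t50, fit1$t50, tolerance = 1e-5)
  expect_equal(fit2$hill_slope, fit1$hill_slope, tolerance = 1e-5)
  expect_equal(migration_rate(healing_time(fit2, 0.95), 125),
               migration_rate(healing_time(fit1, 0.95), 125),
               tolerance = 1e-5)
})

test_that("coverage_from_capacitance endpoints, midpoint and calibration errors", {
  tr <- channel_trace(0:2, c(3e-9, 2e-9, 1e-9), kind = "C",
                      frequency_hz = 64000)
  cov <- coverage_from_capacitance(tr, C_free = 3e-9, C_confluent = 1e-9)
  expect_equal(cov$coverage, c(0, 0.5, 1))
  expect_error(coverage_from_capacitance(tr, 1e-9, 3e-9), "calibration")
})

test_that("coverage channel reproduces the simulator front model", {
  v <- 10.69
  ts <- simulate_timecourse(quick_sim(v = v))
  gt <- attr(ts, "ground_truth")$wells[["g_w01"]]
  m <- default_electrode()
  c64 <- extract_channel(ts, "g_w01", 64000, "C")
  p_mig <- cell_model_params(alpha = gt$alpha, Rb = gt$Rb_migration,
                             Cm = gt$Cm)
  C_free <- complex_to_series_rc(
    naked_electrode_impedance(64000, m) / m$area, 64000)$C
  C_conf <- complex_to_series_rc(
    covered_electrode_impedance(64000, m, p_mig) / m$area, 64000)$C
  cov <- coverage_from_capacitance(c64, C_free, C_conf)
  post <- cov$time_h >= 200 & cov$time_h <= 200 + 125 / v
  truth <- simulate_wound_recovery_coverage(cov$time_h[post] - 200, v, 125)
  # series-RC extraction leaves a small (~7e-4) nonlinearity; see vignette
  expect_lt(max(abs(cov$coverage[post] - truth)), 5e-3)
})

test_that("front-speed estimator recovers configured speeds from coverage", {
  for (v in c(10.69, 8.6)) {
    ts <- simulate_timecourse(quick_sim(v = v))
    res <- analyze_well(ts, "g_w01",
                        pipeline_options(electrode = default_electrode()))
    expect_equal(res$migration$rate, v, tolerance = 0.005)
    expect_equal(res$migration$healing_time, 125 / v, tolerance = 0.005)
  }
})

test_that("attachment_slope recovers exact and noisy slopes", {
  # exact line at the case-line slope
  tr <- simulate_attachment_trace(slope = 9.43, intercept = 1000, hours = 12)
  fit <- attachment_slope(tr, 12)
  expect_equal(fit$slope, 9.43, tolerance = 1e-9)
  expect_equal(fit$intercept, 1000, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant trace: slope 0 over the full window
  const <- channel_trace(seq(0, 12, by = 160 / 3600), rep(4000, 271))
  expect_equal(attachment_slope(const, 12)$slope, 0)
  # closed-form OLS oracle on a 5-point fixture spread over >=10 samples
  t5 <- seq(0, 9, length.out = 10)
  v5 <- c(10, 12, 11, 15, 14, 16, 18, 17, 19, 21)  # max last: no truncation
  sxy <- sum((t5 - mean(t5)) * (v5 - mean(v5)))
  sxx <- sum((t5 - mean(t5))^2)
  tr5 <- channel_trace(t5, v5)
  expect_equal(attachment_slope(tr5, 24)$slope, sxy / sxx, tolerance = 1e-9)
  expect_error(attachment_slope(channel_trace(0:5, 1:6), 24), "10 samples")
  expect_error(attachment_slope(tr, 30), "24 h")
})
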