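test_that("long-dialect CSV reads into a fully populated series", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_long_csv(f, nt = 3, wells = c("A1", "A2"))
  ts <- read_timecourse(f)
  expect_s3_class(ts, "ecis_its")
  expect_equal(dim(ts$z), c(3, 2, 11))
  expect_equal(sum(!ts$missing), 66)  # 2 wells x 3 sweeps x 11 frequencies
  expect_false(any(ts$missing))
})

test_that("read/write round trip is lossless", {
  cfg <- quick_sim(noise_sd = 0.01, well_sd = 50, seed = 9)
  ts <- simulate_timecourse(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(ts, f)
  ts2 <- read_timecourse(f)
  expect_identical(ts2$z, ts$z)
  expect_identical(ts2$times, ts$times)
  expect_identical(ts2$frequencies, ts$frequencies)
})

test_that("malformed input is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- make_long_csv(f, nt = 2, wells = "A1")
  # duplicated (time, well, frequency) row
  utils::write.csv(rbind(rows, rows[1, ]), f, row.names = FALSE, quote = FALSE)
  expect_error(read_timecourse(f), "duplicated")
  # missing column
  utils::write.csv(rows[, -3], f, row.names = FALSE, quote = FALSE)
  expect_error(read_timecourse(f), "frequency_hz")
  # non-monotone time within a well
  rows2 <- make_long_csv(f, nt = 3, wells = "A1")
  rows2$time_s[rows2$time_s == 160] <- 1000
  utils::write.csv(rows2, f, row.names = FALSE, quote = FALSE)
  expect_error(read_timecourse(f), "non-monotone")
  expect_error(read_timecourse(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("wide-dialect CSV converts R/C(nF) pairs to impedance", {
  f <- withr::local_tempfile(fileext = ".csv")
  # one sweep, one well, two frequencies; C in nF
  df <- data.frame(time_s = 0, well = "A1",
                   R_4000 = 2600, C_4000 = 10,
                   R_64000 = 300, C_64000 = 3)
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  ts <- read_timecourse(f, dialect = "wide")
  expect_equal(ts$frequencies, c(4000, 64000))
  z4 <- ts$z[1, 1, 1]
  expect_equal(Re(z4), 2600)
  expect_equal(Im(z4), -1 / (2 * pi * 4000 * 10e-9))
  expect_error(read_timecourse(f, dialect = "long"), "missing column")
})

test_that("series-RC conversion matches its construction and flags degenerates", {
  # Z built from R = 2600 Ohm, C = 10 nF at 4 kHz
  z <- complex(real = 2600, imaginary = -1 / (2 * pi * 4000 * 1e-8))
  rc <- complex_to_series_rc(z, 4000)
  expect_equal(rc$R, 2600)
  expect_equal(rc$C, 1e-8, tolerance = 1e-12)
  # hand-evaluated example
  rc2 <- complex_to_series_rc(complex(real = 1000, imaginary = -3978.87), 4000)
  expect_equal(rc2$C, 1e-8, tolerance = 1e-5)
  # purely real impedance: capacitance undefined, flagged
  rc3 <- complex_to_series_rc(1000 + 0i, 4000)
  expect_true(is.na(rc3$C))
  expect_false(rc3$capacitive)
})

test_that("series-RC conversion is self-inverse (property)", {
  set.seed(1)
  for (i in 1:25) {
    R <- runif(1, 100, 20000)
    C <- runif(1, 1, 100) * 1e-9
    f <- sample(ecis_frequencies(), 1)
    z <- complex(real = R, imaginary = -1 / (2 * pi * f * C))
    rc <- complex_to_series_rc(z, f)
    expect_equal(rc$R, R, tolerance = 1e-9)
    expect_equal(rc$C, C, tolerance = 1e-9)
  }
})

test_that("extract_channel converts units and commutes with windowing", {
  ts <- simulate_timecourse(quick_sim())
  r4k <- extract_channel(ts, "g_w01", 4000, "R")
  expect_identical(attr(r4k, "kind"), "R@4kHz")
  expect_identical(attr(r4k, "units"), "Ohm")
  expect_equal(r4k$time_h, ts$times / 3600)
  c64 <- extract_channel(ts, "g_w01", 64000, "C")
  expect_identical(attr(c64, "kind"), "C@64kHz")
  expect_identical(attr(c64, "units"), "F")
  expect_true(all(c64$value > 0 & c64$value < 1e-6))
  # extract-then-slice == slice-then-extract
  win <- window_channel(r4k, 50, 100)
  keep <- ts$times / 3600 >= 50 & ts$times / 3600 <= 100
  ts_cut <- impedance_timeseries(ts$times[keep], ts$wells, ts$frequencies,
                                 ts$z[keep, , , drop = FALSE], ts$metadata)
  win2 <- extract_channel(ts_cut, "g_w01", 4000, "R")
  expect_equal(win$value, win2$value)
  expect_equal(win$time_h, win2$time_h)
  # unknown lookups
  expect_error(extract_channel(ts, "nope", 4000, "R"), "unknown well")
  expect_error(extract_channel(ts, "g_w01", 5000, "R"), "not in acquisition grid")
})

test_that("missing sweeps propagate as flagged gaps", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- make_long_csv(f, nt = 3, wells = "A1", freqs = c(4000, 64000))
  rows <- rows[-2, ]  # drop one (time, frequency) cell
  utils::write.csv(rows, f, row.names = FALSE, quote = FALSE)
  ts <- read_timecourse(f)
  expect_equal(sum(ts$missing), 1)
  tr <- extract_channel(ts, "A1", 4000, "R")
  expect_equal(sum(is.na(tr$value)), 1)
})
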