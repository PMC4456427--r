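test_that("alpha_from_geometry matches hand arithmetic and scaling laws", {
  # sqrt(54 / 1.5e-6) = 6000, times rc = 1e-3 cm
  expect_equal(alpha_from_geometry(1e-3, 54, 1.5e-6), 6.0)
  # alpha ~ h^(-1/2): quadrupling h halves alpha
  a1 <- alpha_from_geometry(1e-3, 54, 1e-6)
  a4 <- alpha_from_geometry(1e-3, 54, 4e-6)
  expect_equal(a4, a1 / 2)
  # inversion for h at the case-line alpha
  h <- height_from_alpha(7.8, rc = 1e-3, rho = 54)
  expect_equal(h, 54 * 1e-6 / 7.8^2, tolerance = 1e-12)
  expect_equal(h, 8.88e-7, tolerance = 2e-3)
  expect_error(alpha_from_geometry(-1, 54, 1e-6), "must be > 0")
})

test_that("cell_model_params enforces the alpha/geometry invariant", {
  p <- cell_model_params(rc = 1e-3, rho = 54, h = 1.5e-6, Rb = 2)
  expect_equal(p$alpha, 6.0)
  expect_silent(cell_model_params(alpha = 6, rc = 1e-3, rho = 54, h = 1.5e-6))
  expect_error(cell_model_params(alpha = 7, rc = 1e-3, rho = 54, h = 1.5e-6),
               "inconsistent")
  expect_error(cell_model_params(alpha = -1), "strictly positive")
})

test_that("naked electrode model has the right limits and calibration", {
  # n = 1 reduces to ideal capacitor + resistor: Im part ~ 1/f
  m1 <- naked_electrode_model(A = 1000, n = 1, Rsol = 0.5)
  z1 <- naked_electrode_impedance(c(100, 200), m1)
  expect_equal(Re(z1), c(0.5, 0.5))
  expect_equal(Im(z1[1]) / Im(z1[2]), 2, tolerance = 1e-12)
  # f -> Inf: CPE vanishes, Zn -> Rsol
  m <- default_electrode()
  expect_equal(as.complex(naked_electrode_impedance(1e15, m)),
               complex(real = m$Rsol, imaginary = 0), tolerance = 1e-6)
  # calibration: absolute series resistance at 4 kHz is 2600 Ohm
  expect_equal(Re(naked_electrode_impedance(4000, m)) / m$area, 2600)
  expect_error(naked_electrode_model(n = 1.2), "n must be")
})

test_that("complex Bessel ratio I0/I1 matches independent oracle values", {
  # frozen oracle values computed with scipy.special.iv (AMOS)
  z <- c(0.5 + 0.2i, 3 - 1i, 8 + 6i, 25 + 10i, 28 + 3i, 40 + 20i,
         120 - 30i, 2.5 + 2.5i)
  expected <- c(3.57258967137647 - 1.33076189907691i,
                1.19017765636291 + 0.093596782914656i,
                1.04086662521653 - 0.0339747378475579i,
                1.0176239513667 - 0.00727173235855258i,
                1.01813332643133 - 0.00199737068009857i,
                1.01011321210866 - 0.00515424666386186i,
                1.00394334310856 + 0.000992060823695133i,
                1.07684803755778 - 0.127183505466967i)
  got <- ecisr:::bessel_i01_ratio(z)
  expect_equal(got, expected, tolerance = 1e-10)
  # real-argument cross-check against base besselI across the branch switch
  for (x in c(0.1, 1, 5, 29.9, 30.1, 60, 300)) {
    expect_equal(Re(ecisr:::bessel_i01_ratio(complex(real = x))),
                 besselI(x, 0, expon.scaled = TRUE) /
                   besselI(x, 1, expon.scaled = TRUE),
                 tolerance = 1e-12, label = paste("x =", x))
  }
})

test_that("covered impedance has the analytic limits", {
  m <- default_electrode()
  f <- ecis_frequencies()
  zn <- naked_electrode_impedance(f, m)
  # alpha -> 0, Rb -> 0: covered = naked at every frequency
  p0 <- cell_model_params(alpha = 1e-9, Rb = 1e-12, Cm = 1e-6)
  zc0 <- covered_electrode_impedance(f, m, p0)
  expect_equal(zc0, zn, tolerance = 1e-6)
  # f -> Inf: membranes short out, Zc -> Zn
  p <- cell_model_params(alpha = 6.5, Rb = 5, Cm = 1e-6)
  expect_equal(covered_electrode_impedance(1e13, m, p),
               naked_electrode_impedance(1e13, m), tolerance = 1e-6)
  # increasing Rb strictly increases Re(Zc) at 4 kHz on the rising branch
  r4 <- vapply(c(1, 2, 5, 10), function(Rb) {
    Re(covered_electrode_impedance(4000, m,
                                   cell_model_params(alpha = 6.5, Rb = Rb)))
  }, 0)
  expect_true(all(diff(r4) > 0))
})

test_that("mixed coverage interpolates between naked and covered", {
  m <- default_electrode()
  p <- cell_model_params(alpha = 2.5, Rb = 3, Cm = 1e-6)
  zn <- naked_electrode_impedance(4000, m)
  zc <- covered_electrode_impedance(4000, m, p)
  expect_equal(mixed_coverage_impedance(4000, m, p, 0), zn)
  expect_equal(mixed_coverage_impedance(4000, m, p, 1), zc)
  rmix <- Re(mixed_coverage_impedance(4000, m, p, c(0, 0.25, 0.5, 0.75, 1)))
  expect_true(all(diff(rmix) >= 0))
  expect_true(rmix[3] > rmix[1] && rmix[3] < rmix[5])
  expect_error(mixed_coverage_impedance(4000, m, p, 1.2), "coverage")
})

test_that("fit_alpha recovers noise-free forward spectra", {
  m <- default_electrode()
  for (al in c(7.8, 6.5)) {
    p <- cell_model_params(alpha = al, Rb = 2, Cm = 1e-6)
    fit <- fit_alpha(simulate_spectrum(p, m), m)
    expect_true(fit$converged)
    expect_equal(fit$params$alpha, al, tolerance = 1e-3)
    expect_equal(fit$params$Rb, 2, tolerance = 1e-3)
    expect_equal(fit$params$Cm, 1e-6, tolerance = 1e-3)
    expect_true(all(is.finite(fit$se)))
  }
})

test_that("fit_alpha parameter recovery property over random draws", {
  m <- default_electrode()
  set.seed(42)
  for (i in 1:10) {
    al <- runif(1, 3, 10); Rb <- runif(1, 1, 10); Cm <- runif(1, 0.5, 4) * 1e-6
    p <- cell_model_params(alpha = al, Rb = Rb, Cm = Cm)
    fit <- fit_alpha(simulate_spectrum(p, m), m)
    expect_true(fit$converged, label = paste("draw", i))
    expect_equal(fit$params$alpha, al, tolerance = 1e-3)
    expect_equal(fit$params$Rb, Rb, tolerance = 1e-3)
    expect_equal(fit$params$Cm, Cm, tolerance = 1e-3)
  }
  # 1% multiplicative complex noise: alpha within 5%
  for (s in 1:10) {
    p <- cell_model_params(alpha = 7.8, Rb = 2, Cm = 1e-6)
    fit <- fit_alpha(simulate_spectrum(p, m, noise_sd = 0.01, seed = s), m)
    expect_true(abs(fit$params$alpha / 7.8 - 1) < 0.05)
  }
})

test_that("fit_alpha agrees with an exhaustive grid-search oracle", {
  m <- default_electrode()
  set.seed(7)
  f <- ecis_frequencies()
  zn <- naked_electrode_impedance(f, m)
  for (i in 1:3) {
    al <- runif(1, 3, 9); Rb <- runif(1, 1, 8); Cm <- 1e-6
    sp <- simulate_spectrum(cell_model_params(alpha = al, Rb = Rb, Cm = Cm),
                            m, noise_sd = 0.005, seed = 100 + i)
    robs <- complex(real = sp$z_real_ohm, imaginary = sp$z_imag_ohm) *
      m$area / zn
    ssq <- function(a, rb) {
      th <- list(alpha = a, Rb = rb, Cm = Cm)
      sum(ecisr:::gk_fit_residuals(f, m, th, robs)^2)
    }
    # coarse 50 x 50 grid, then local refinement: the independent oracle
    grid_a <- seq(1, 15, length.out = 50)
    grid_r <- seq(0.2, 15, length.out = 50)
    val <- outer(grid_a, grid_r, Vectorize(ssq))
    ij <- which(val == min(val), arr.ind = TRUE)[1, ]
    ref <- optim(c(grid_a[ij[1]], grid_r[ij[2]]),
                 function(p) ssq(p[1], p[2]), method = "BFGS")
    fit <- fit_alpha(sp, m, free = c("alpha", "Rb"), init = list(Cm = Cm))
    expect_equal(fit$params$alpha, ref$par[1], tolerance = 1e-3)
    expect_equal(fit$params$Rb, ref$par[2], tolerance = 1e-3)
    expect_lte(fit$objective, ref$value * (1 + 1e-6))
  }
})

test_that("fit_alpha flags degenerate cell-free spectra and bad input", {
  m <- default_electrode()
  sp <- simulate_spectrum(cell_model_params(alpha = 1, Rb = 1), m,
                          coverage = 0)
  fit <- fit_alpha(sp, m)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_error(fit_alpha(sp[1:4, ], m), "6 frequencies")
})
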