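#' Cell-electrode model parameters
#'
#' Parameters of the Giaever-Keese disk-cell model of a cell-covered
#' microelectrode. Cells are modelled as circular disks of radius `rc`
#' hovering at height `h` above the electrode in medium of resistivity
#' `rho`; current flows under the cells (constriction, summarised by
#' `alpha = rc * sqrt(rho / h)`), between them (paracellular barrier
#' resistance `Rb`) and through them (two cell membranes of specific
#' capacitance `Cm` in series).
#'
#' `alpha` may be given directly (geometry unresolved) or computed from
#' `rc`, `rho`, `h`. If all four are supplied they must be consistent.
#'
#' @param alpha adhesion parameter, Ohm^1/2 cm.
#' @param Rb cell-cell barrier resistance, Ohm cm^2.
#' @param Cm per-membrane specific capacitance, F/cm^2 (default 1 uF/cm^2).
#' @param rc cell radius, cm (optional).
#' @param rho medium resistivity, Ohm cm (optional).
#' @param h cell-substrate separation, cm (optional).
#' @return a `gk_cell_params` object.
#' @export
cell_model_params <- function(alpha = NULL, Rb = 1, Cm = 1e-6,
                              rc = NULL, rho = NULL, h = NULL) {
  geom <- !vapply(list(rc, rho, h), is.null, TRUE)
  if (is.null(alpha)) {
    if (!all(geom)) stop_domain("supply alpha, or all of rc, rho, h")
    alpha <- alpha_from_geometry(rc, rho, h)
  } else if (all(geom)) {
    if (abs(alpha - alpha_from_geometry(rc, rho, h)) > 1e-9 * alpha) {
      stop_domain("alpha inconsistent with rc*sqrt(rho/h)")
    }
  }
  vals <- c(alpha = alpha, Rb = Rb, Cm = Cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("alpha, Rb, Cm must be strictly positive")
  }
  structure(list(alpha = alpha, Rb = Rb, Cm = Cm,
                 rc = rc, rho = rho, h = h),
            class = "gk_cell_params")
}

#' Adhesion parameter from cell geometry
#'
#' `alpha = rc * sqrt(rho / h)` in Ohm^1/2 cm: the disk-cell model's summary
#' of how closely cells hug the electrode (small separation h, i.e. tight
#' adhesion, gives large alpha).
#'
#' @param rc cell radius, cm.
#' @param rho medium resistivity, Ohm cm.
#' @param h cell-substrate separation, cm.
#' @return alpha in Ohm^1/2 cm.
#' @export
alpha_from_geometry <- function(rc, rho, h) {
  if (any(c(rc, rho, h) <= 0)) stop_domain("rc, rho, h must be > 0")
  rc * sqrt(rho / h)
}

#' Cell-substrate separation implied by alpha
#'
#' Inverts [alpha_from_geometry()]: `h = rho * rc^2 / alpha^2`.
#'
#' @param alpha adhesion parameter, Ohm^1/2 cm.
#' @param rc cell radius, cm (default 1e-3 cm = 10 um, a typical epithelial
#'   cell radius).
#' @param rho medium resistivity, Ohm cm (default 54).
#' @return separation h in cm.
#' @export
height_from_alpha <- function(alpha, rc = 1e-3, rho = 54) {
  if (any(c(alpha, rc, rho) <= 0)) stop_domain("inputs must be > 0")
  rho * rc^2 / alpha^2
}

#' Naked (cell-free) microelectrode model
#'
#' The cell-free gold microelectrode is modelled as a constant-phase
#' element in series with a solution/constriction resistance:
#' `Zn(f) = A (j 2 pi f)^-n + Rsol`, in specific units (Ohm cm^2).
#' Dividing by the electrode area gives absolute Ohm.
#'
#' @param A CPE magnitude, Ohm cm^2 s^-n.
#' @param n CPE exponent in (0, 1]; 1 is an ideal capacitor. Default 0.9,
#'   typical for sputtered gold microelectrodes.
#' @param Rsol solution (spreading) resistance, Ohm cm^2. The default 0.54
#'   corresponds to rho/(2 d) for a 250 um disk in 54 Ohm cm medium.
#' @param area electrode area in cm^2 (default 5e-4, i.e. 0.05 mm^2).
#' @return a `gk_electrode` object.
#' @export
naked_electrode_model <- function(A = 4.433e4, n = 0.9, Rsol = 0.54,
                                  area = 5e-4) {
  if (n <= 0 || n > 1) stop_domain("n must be in (0, 1]")
  if (A <= 0 || Rsol <= 0 || area <= 0) {
    stop_domain("A, Rsol, area must be > 0")
  }
  structure(list(A = A, n = n, Rsol = Rsol, area = area),
            class = "gk_electrode")
}

#' Calibrate the naked-electrode model to a cell-free 4 kHz resistance
#'
#' Chooses the CPE magnitude `A` so that the absolute series resistance of
#' the cell-free electrode at 4 kHz equals `R4k_ohm` (2600 Ohm by default,
#' the cell-free reference of a 250 um ECIS electrode), for given exponent
#' `n`, solution resistance and area.
#'
#' @param R4k_ohm target cell-free series resistance at 4 kHz, Ohm.
#' @inheritParams naked_electrode_model
#' @return a calibrated `gk_electrode`.
#' @export
calibrate_naked_electrode <- function(R4k_ohm = 2600, n = 0.9, Rsol = 0.54,
                                      area = 5e-4) {
  w <- 2 * pi * 4000
  re_cpe <- R4k_ohm * area - Rsol
  if (re_cpe <= 0) stop_domain("Rsol exceeds the target specific resistance")
  A <- re_cpe / (cos(n * pi / 2) * w^-n)
  naked_electrode_model(A = A, n = n, Rsol = Rsol, area = area)
}

#' Naked-electrode specific impedance
#'
#' @param f frequency in Hz (vectorised).
#' @param m a `gk_electrode`.
#' @return complex specific impedance Zn in Ohm cm^2.
#' @export
naked_electrode_impedance <- function(f, m) {
  if (any(f <= 0)) stop_domain("f must be > 0")
  m$A * (1i * 2 * pi * f)^(-m$n) + m$Rsol
}

# I0(z)/I1(z) for complex z with Re(z) > 0, vectorised.
# Power series up to |z| <= 30; backward-recurrence continued fraction
# beyond (the series would overflow / lose accuracy, the ratio tends to 1).
bessel_i01_ratio <- function(z) {
  out <- complex(length(z))
  small <- Mod(z) <= 30
  if (any(small)) {
    zs <- z[small]
    q <- (zs / 2)^2
    term0 <- rep(1 + 0i, length(zs)); i0 <- term0
    term1 <- rep(1 + 0i, length(zs)); i1 <- term1
    for (k in 1:220) {
      term0 <- term0 * q / k^2
      i0 <- i0 + term0
      term1 <- term1 * q / (k * (k + 1))
      i1 <- i1 + term1
      if (all(Mod(term0) <= 1e-17 * Mod(i0))) break
    }
    i1 <- i1 * zs / 2
    if (any(!is.finite(Re(i1)) | Mod(i1) == 0)) {
      stop("bessel_i01_ratio: series evaluation failed", call. = FALSE)
    }
    out[small] <- i0 / i1
  }
  mid <- !small & Mod(z) <= 300
  if (any(mid)) {
    zl <- z[mid]
    # r_nu = I_{nu+1}/I_nu satisfies 1/r_nu = 2(nu+1)/z + r_{nu+1};
    # iterate backwards from a deep tail where r ~ z / (2(N+1)); the tail
    # must start beyond |z| for the recursion to converge
    N <- as.integer(60 + ceiling(1.5 * max(Mod(zl))))
    r <- zl / (2 * (N + 1))
    for (nu in (N - 1):0) r <- 1 / (2 * (nu + 1) / zl + r)
    if (any(!is.finite(Re(r)))) {
      stop("bessel_i01_ratio: continued fraction diverged", call. = FALSE)
    }
    out[mid] <- 1 / r
  }
  big <- !small & !mid
  if (any(big)) {
    # asymptotic ratio, relative error O(|z|^-4) < 1e-9 for |z| > 300
    zb <- z[big]
    out[big] <- 1 + 1 / (2 * zb) + 3 / (8 * zb^2) + 3 / (8 * zb^3)
  }
  out
}

#' Covered-electrode specific impedance (Giaever-Keese transfer function)
#'
#' Specific impedance of a confluently cell-covered microelectrode. With
#' `Zn` the naked-electrode and `Zm = 2/(j 2 pi f Cm)` the transcellular
#' (two membranes in series) specific impedances, and
#' `g = alpha * sqrt(1/Zn + 1/Zm)` (the parameter `gamma * rc` of the
#' disk-cell solution),
#' \deqn{1/Zc = (1/Zn) [ Zn/(Zn+Zm) + (Zm/(Zn+Zm)) /
#'       ( (g/2) I0(g)/I1(g) + Rb (1/Zn + 1/Zm) ) ]}
#' where I0, I1 are modified Bessel functions of the first kind of complex
#' argument (evaluated with an overflow-safe ratio).
#'
#' @param f frequency in Hz (vectorised).
#' @param m a `gk_electrode`.
#' @param p a `gk_cell_params` (alpha, Rb, Cm all required).
#' @return complex specific impedance Zc in Ohm cm^2.
#' @export
covered_electrode_impedance <- function(f, m, p) {
  if (any(f <= 0)) stop_domain("f must be > 0")
  Zn <- naked_electrode_impedance(f, m)
  Zm <- 2 / (1i * 2 * pi * f * p$Cm)
  ysum <- 1 / Zn + 1 / Zm
  g <- p$alpha * sqrt(ysum)
  ratio <- bessel_i01_ratio(g)
  invZc <- (1 / Zn) * (Zn / (Zn + Zm) +
                       (Zm / (Zn + Zm)) / ((g / 2) * ratio + p$Rb * ysum))
  1 / invZc
}

#' Impedance of a partially covered electrode
#'
#' Area-parallel admittance mixing of covered and naked patches:
#' `1/Zmix = coverage/Zc + (1 - coverage)/Zn`.
#'
#' @inheritParams covered_electrode_impedance
#' @param coverage covered area fraction in \[0, 1\] (vectorised; `f` and
#'   `coverage` are recycled against each other).
#' @return complex specific impedance in Ohm cm^2.
#' @export
mixed_coverage_impedance <- function(f, m, p, coverage) {
  if (any(coverage < 0 | coverage > 1)) {
    stop_domain("coverage must be in [0, 1]")
  }
  Zn <- naked_electrode_impedance(f, m)
  Zc <- covered_electrode_impedance(f, m, p)
  1 / (coverage / Zc + (1 - coverage) / Zn)
}

# internal: model spectrum ratio Zc/Zn on the default grid for fitting
gk_ratio <- function(f, m, theta) {
  p <- structure(list(alpha = theta[["alpha"]], Rb = theta[["Rb"]],
                      Cm = theta[["Cm"]]), class = "gk_cell_params")
  covered_electrode_impedance(f, m, p) / naked_electrode_impedance(f, m)
}

gk_fit_residuals <- function(f, m, theta, robs) {
  rmod <- gk_ratio(f, m, theta)
  c(log(Mod(rmod)) - log(Mod(robs)), Arg(rmod) - Arg(robs))
}

#' Fit the adhesion parameter alpha to a covered-electrode spectrum
#'
#' Weighted least squares on the normalised spectrum `Zc/Zn` (log-magnitude
#' and phase residuals across frequencies), which removes electrode area
#' and lead resistance as nuisance scales. Free parameters default to
#' alpha, Rb and Cm; fixed parameters are taken from `init`. Multi-start
#' initialisation over alpha in {2, 5, 10} Ohm^1/2 cm.
#'
#' @param spectrum data.frame with columns `frequency_hz` and either a
#'   complex `z_ohm` column or numeric `z_real_ohm` / `z_imag_ohm`,
#'   holding the absolute covered-electrode impedance in Ohm.
#' @param m a `gk_electrode` describing the cell-free reference.
#' @param free character subset of `c("alpha", "Rb", "Cm")` to optimise.
#' @param init named list of starting/fixed values (defaults: Rb = 2,
#'   Cm = 1e-6).
#' @return an `alpha_fit` object: fitted `params` (gk_cell_params),
#'   `se` (standard errors, delta method), per-frequency `residuals`,
#'   `objective`, `converged`, `degenerate` flags.
#' @export
fit_alpha <- function(spectrum, m, free = c("alpha", "Rb", "Cm"),
                      init = list()) {
  free <- match.arg(free, c("alpha", "Rb", "Cm"), several.ok = TRUE)
  f <- spectrum$frequency_hz
  if (length(f) < 6 || log10(max(f) / min(f)) < 2) {
    stop_domain("need >= 6 frequencies spanning >= 2 decades")
  }
  z <- if (!is.null(spectrum$z_ohm)) spectrum$z_ohm else
    complex(real = spectrum$z_real_ohm, imaginary = spectrum$z_imag_ohm)
  if (any(is.na(z))) stop_domain("spectrum contains missing values")
  robs <- z * m$area / naked_electrode_impedance(f, m)

  theta0 <- list(alpha = 5, Rb = 2, Cm = 1e-6)
  theta0[names(init)] <- init
  lower <- c(alpha = 1e-3, Rb = 1e-4, Cm = 1e-8)
  upper <- c(alpha = 50, Rb = 200, Cm = 1e-4)

  obj <- function(lp) {
    th <- theta0
    th[free] <- as.list(exp(lp))
    sum(gk_fit_residuals(f, m, th, robs)^2)
  }
  starts <- lapply(c(2, 5, 10), function(a0) {
    s <- theta0; s$alpha <- a0
    log(unlist(s[free]))
  })
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = log(lower[free]), upper = log(upper[free]),
            control = list(maxit = 2000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence != 0) {
      # polish: L-BFGS-B occasionally reports abnormal line-search exit at
      # an essentially converged point; a BFGS pass settles the flag
      o2 <- tryCatch(optim(o$par, obj, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-14)),
                     error = function(e) NULL)
      if (!is.null(o2) && o2$value <= o$value) o <- o2
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, se = NULL, residuals = NULL,
                          objective = NA_real_, converged = FALSE,
                          degenerate = FALSE),
                     class = "alpha_fit"))
  }
  th <- theta0
  th[free] <- as.list(exp(best$par))
  res <- gk_fit_residuals(f, m, th, robs)
  # degenerate: alpha driven to its lower boundary (cell-free-like spectrum)
  degenerate <- "alpha" %in% free && th$alpha <= lower[["alpha"]] * 1.5
  converged <- best$convergence == 0 && !degenerate

  # covariance via numerical Jacobian of residuals wrt log-parameters
  se <- rep(NA_real_, length(free)); names(se) <- free
  if (converged) {
    eps <- 1e-6
    J <- vapply(seq_along(free), function(k) {
      lp <- best$par; lp[k] <- lp[k] + eps
      th2 <- theta0; th2[free] <- as.list(exp(lp))
      (gk_fit_residuals(f, m, th2, robs) - res) / eps
    }, numeric(length(res)))
    dof <- max(length(res) - length(free), 1)
    s2 <- sum(res^2) / dof
    covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(covm)) {
      # delta method: se(theta) = theta * se(log theta)
      se <- sqrt(pmax(diag(covm), 0)) * unlist(th[free])
    }
  }
  structure(list(
    params = cell_model_params(alpha = th$alpha, Rb = th$Rb, Cm = th$Cm),
    se = se,
    residuals = res,
    objective = best$value,
    converged = converged,
    degenerate = degenerate),
    class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<alpha_fit> not converged\n"); return(invisible(x))
  }
  cat(sprintf("<alpha_fit> alpha = %.4g Ohm^1/2 cm, Rb = %.4g Ohm cm^2, Cm = %.4g F/cm^2\n",
              x$params$alpha, x$params$Rb, x$params$Cm))
  cat(sprintf("  objective %.3g; converged: %s%s\n", x$objective,
              x$converged, if (x$degenerate) " (degenerate: alpha at boundary)" else ""))
  invisible(x)
}
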