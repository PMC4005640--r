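# FCS: 3D-diffusion autocorrelation fits and Stokes-Einstein hydrodynamics.

#' Single-component 3D diffusion autocorrelation model
#'
#' `G(tau) = (1/N) * (1 + tau/tau_D)^-1 * (1 + tau/(kappa^2 tau_D))^-1/2`
#' for free diffusion through a 3D Gaussian focus with axial ratio `kappa`.
#'
#' @param lag lag time(s), seconds.
#' @param n_particles mean focal-volume occupancy N (> 0).
#' @param tau_D diffusion time, seconds (> 0).
#' @param kappa axial structure parameter (> 1).
#' @return autocorrelation amplitude(s).
#' @export
fcs_model <- function(lag, n_particles, tau_D, kappa) {
  .assert(is.numeric(lag) && all(lag >= 0), "lag must be non-negative")
  .assert(.is_number(n_particles) && n_particles > 0, "n_particles must be positive")
  .assert(.is_number(tau_D) && tau_D > 0, "tau_D must be positive")
  .assert(.is_number(kappa) && kappa > 1, "kappa must exceed 1")
  (1 / n_particles) / ((1 + lag / tau_D) * sqrt(1 + lag / (kappa^2 * tau_D)))
}

#' Fit the 3D diffusion model to an FCS curve
#'
#' Least-squares fit of [fcs_model()] with the axial ratio fixed (typical
#' confocal value 6) unless `fit_kappa = TRUE`. Warns when the fitted
#' diffusion time exceeds the largest measured lag (no decay information:
#' ill-conditioned fit).
#'
#' @param curve an `fcs_curve` (from [simulate_fcs_curve()]) or a data.frame
#'   with columns `lag_s` and `G`.
#' @param fix_kappa axial ratio held fixed during the fit.
#' @param fit_kappa also fit kappa (rarely identifiable; off by default).
#' @return an object of class `fcs_fit` with `n_particles`, `tau_D`,
#'   `kappa`, `rss`, and the data.
#' @export
fit_fcs <- function(curve, fix_kappa = 6.0, fit_kappa = FALSE) {
  if (inherits(curve, "fcs_curve")) {
    lag <- curve$lags; G <- curve$G
  } else {
    .assert(is.data.frame(curve) && all(c("lag_s", "G") %in% names(curve)),
            "curve must be an fcs_curve or a data.frame with lag_s and G")
    lag <- curve$lag_s; G <- curve$G
  }
  .assert(length(lag) >= 20, "need >= 20 lag points spanning the diffusion time")
  .assert(.is_number(fix_kappa) && fix_kappa > 1, "fix_kappa must exceed 1")

  n0 <- 1 / max(G[1], .Machine$double.eps)
  ihalf <- which.min(abs(G - G[1] / 2))
  t0 <- max(lag[ihalf], min(lag[lag > 0]))
  dat <- data.frame(lag = lag, G = G)
  fit <- if (fit_kappa) {
    nlsLM(G ~ (1 / N) / ((1 + lag / tD) * sqrt(1 + lag / (k2^2 * tD))),
          data = dat, start = list(N = n0, tD = t0, k2 = fix_kappa),
          lower = c(1e-12, 1e-12, 1 + 1e-6), control = list(maxiter = 300))
  } else {
    k2 <- fix_kappa
    nlsLM(G ~ (1 / N) / ((1 + lag / tD) * sqrt(1 + lag / (k2^2 * tD))),
          data = dat, start = list(N = n0, tD = t0),
          lower = c(1e-12, 1e-12), control = list(maxiter = 300))
  }
  cf <- coef(fit)
  tau_D <- unname(cf["tD"])
  if (tau_D > max(lag)) {
    warning(sprintf(
      "ill-conditioned fit: tau_D (%.3g s) exceeds the largest lag (%.3g s)",
      tau_D, max(lag)))
  }
  structure(list(n_particles = unname(cf["N"]), tau_D = tau_D,
                 kappa = if (fit_kappa) unname(cf["k2"]) else fix_kappa,
                 rss = sum((G - predict(fit))^2),
                 lags = lag, G = G, fitted = predict(fit)),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: N = %.3f, tau_D = %.4g s, kappa = %.2f, RSS = %.3g\n",
              x$n_particles, x$tau_D, x$kappa, x$rss))
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) {
  c(n_particles = object$n_particles, tau_D = object$tau_D, kappa = object$kappa)
}

#' @export
predict.fcs_fit <- function(object, newdata = NULL, ...) {
  lag <- if (is.null(newdata)) object$lags else
    (if (is.data.frame(newdata)) newdata$lag_s else newdata)
  fcs_model(lag, object$n_particles, object$tau_D, object$kappa)
}

#' @export
plot.fcs_fit <- function(x, ...) {
  plot(x$lags, x$G, log = "x", xlab = "lag (s)", ylab = "G(tau)",
       pch = 16, cex = 0.6, ...)
  lines(x$lags, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}

#' Hydrodynamic radius from a diffusion time
#'
#' Converts an FCS diffusion time to a diffusion coefficient using the
#' calibrated lateral focal radius, `D = w0^2 / (4 tau_D)`, and to a
#' hydrodynamic radius by Stokes-Einstein,
#' `R_h = k_B T / (6 pi eta D)`.
#'
#' @param tau_D diffusion time, seconds.
#' @param w0 lateral focal (1/e^2) radius from a calibration standard, meters.
#' @param T temperature, Kelvin (default 303.15 K, i.e. 30 C).
#' @param eta solvent viscosity, Pa s (default water at 30 C).
#' @return an object of class `hydro_result` with `D` (m^2/s) and `R_h_nm`.
#' @export
hydrodynamic_radius <- function(tau_D, w0, T = 303.15, eta = 7.972e-4) {
  .assert(.is_number(tau_D) && tau_D > 0, "tau_D must be positive")
  .assert(.is_number(w0) && w0 > 0, "w0 must be positive")
  .assert(.is_number(T) && T > 0, "T must be positive")
  .assert(.is_number(eta) && eta > 0, "eta must be positive")
  D <- w0^2 / (4 * tau_D)
  R_h <- .kB * T / (6 * pi * eta * D)
  structure(list(D = D, R_h_nm = R_h * 1e9, T = T, eta = eta, w0 = w0,
                 tau_D = tau_D),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("Hydrodynamics: D = %.3g m^2/s, R_h = %.2f nm (T = %.2f K, eta = %.3g Pa s)\n",
              x$D, x$R_h_nm, x$T, x$eta))
  invisible(x)
}
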