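## Closed-form autocorrelation models and derived quantities.

#' Scaled complementary error function
#'
#' `erfcx(x) = exp(x^2) * erfc(x)`, evaluated without overflow for large `x`
#' via the log-scale normal tail probability; the naive product overflows
#' beyond `x ~ 26`.
#'
#' @param x Numeric vector.
#' @return `exp(x^2) * erfc(x)`.
#' @examples
#' erfcx(0)   # 1
#' erfcx(50) * 50 * sqrt(pi)   # ~ 1 (asymptotic identity)
#' @export
erfcx <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  ## erfc(x) = 2*pnorm(-x*sqrt(2)); work in logs so exp(x^2) never overflows
  out[pos] <- exp(x[pos]^2 + log(2) +
                    pnorm(x[pos] * sqrt(2), lower.tail = FALSE, log.p = TRUE))
  if (any(!pos)) {
    xn <- x[!pos]
    out[!pos] <- 2 * exp(xn^2) - erfcx(-xn)  # reflection; overflows for xn << -26
  }
  out
}

check_tau <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("`tau` must be finite and >= 0")
  tau
}

#' Autocorrelation models for conventional FCS and NIFS
#'
#' Closed-form intensity autocorrelation functions `G(tau)` for the three
#' illumination scenarios.
#'
#' `acf_fcs3d()`: free 3D diffusion through a Gaussian-ellipsoid focus,
#' \deqn{G(\tau) = G_0\,(1+\tau/\tau_D)^{-1}(1+\tau/\kappa^2\tau_D)^{-1/2},}
#' with `G0 = 1/(Veff C)`, `tauD = r0^2/(4D)` and `kappa = z0/r0`.
#'
#' `acf_nifs3d()`: free diffusion in the half-space above the waveguide exit
#' (reflecting wall) under the laterally Gaussian, axially exponential
#' near-field profile,
#' \deqn{G(\tau) = G_0 (1+\tau/\tau_D)^{-1}
#'   \left[\sqrt{\tau/\pi\tau_z} +
#'   \left(1-\frac{\tau}{2\tau_z}\right)\mathrm{erfcx}\!\sqrt{\tau/4\tau_z}\right],}
#' with `G0 = 1/(2 Veff C)`, `Veff = pi r0^2 z0`, `tauD = r0^2/(4D)` and
#' `tauz = z0^2/(4D)`; the bracketed axial factor is the same form as in
#' TIR-FCS.
#'
#' `acf_nifs2d()`: 2D diffusion in a membrane plane under the annular rim
#' profile.  No closed form exists for all lags; the model is piecewise in
#' `tau`:
#' \deqn{G(\tau) = G_0 (1+\tau/\tau_D)^{-1/2}, \qquad \tau \le \tau_{crit},}
#' \deqn{G(\tau) = G_0 \sqrt{4\pi \frac{\tau_C}{\tau}\frac{\tau_D}{\tau}}
#'   \left[1+\Big(\frac{\tau_C}{\tau}\Big)^2 +
#'   \frac14\Big(\frac{\tau_C}{\tau}\Big)^4\right] e^{-2\tau_C/\tau},
#'   \qquad \tau > \tau_{crit},}
#' with `tauD = b0^2/(2D)` (diffusion across the rim width) and
#' `tauC = a0^2/(4D)` (diffusion around/across the annulus).  By default
#' `tau_crit` is the crossover where the two branches are equal
#' ([branch_crossover()]), about `8 tauC` for the nanowire geometry.
#'
#' @param tau Lag times (s), `>= 0`.
#' @param G0 Amplitude `G(0)` (dimensionless, > 0).
#' @param tauD Lateral diffusion time (s).
#' @param kappa Axial/lateral ratio (>= 1), conventional FCS only.
#' @param tauZ Axial diffusion time `z0^2/(4D)` (s), 3D NIFS only.
#' @param tauC Annulus diffusion time `a0^2/(4D)` (s), 2D NIFS only.
#' @param tau_crit Branch switch time (s), 2D NIFS only; `NULL` uses the
#'   branch crossover computed from `tauD` and `tauC`.
#' @return `G(tau)`, same length as `tau`.
#' @examples
#' acf_fcs3d(0, G0 = 0.2, tauD = 4.2e-3, kappa = 3)  # == G0
#' @export
acf_fcs3d <- function(tau, G0, tauD, kappa) {
  check_tau(tau)
  stopifnot(G0 > 0, tauD > 0, kappa >= 1)
  G0 / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
}

#' @rdname acf_fcs3d
#' @export
acf_nifs3d <- function(tau, G0, tauD, tauZ) {
  check_tau(tau)
  stopifnot(G0 > 0, tauD > 0, tauZ > 0)
  x <- tau / tauZ
  axial <- sqrt(x / pi) + (1 - x / 2) * erfcx(sqrt(x / 4))
  G0 * axial / (1 + tau / tauD)
}

#' @rdname acf_fcs3d
#' @export
acf_nifs2d <- function(tau, G0, tauD, tauC, tau_crit = NULL) {
  check_tau(tau)
  stopifnot(G0 > 0, tauD > 0, tauC > 0)
  if (is.null(tau_crit)) tau_crit <- branch_crossover(tauD, tauC)
  g <- acf_nifs2d_small(tau, G0, tauD)
  big <- tau > tau_crit
  g[big] <- acf_nifs2d_large(tau[big], G0, tauD, tauC)
  g
}

#' Individual branches of the piecewise 2D NIFS model
#'
#' Exposed separately for plotting and for locating the branch crossover.
#' `acf_nifs2d_small()` is the short-time (rim-width) branch,
#' `acf_nifs2d_large()` the long-time (whole-annulus) branch.
#'
#' @inheritParams acf_fcs3d
#' @keywords internal
#' @export
acf_nifs2d_small <- function(tau, G0, tauD) {
  G0 / sqrt(1 + tau / tauD)
}

#' @rdname acf_nifs2d_small
#' @export
acf_nifs2d_large <- function(tau, G0, tauD, tauC) {
  x <- tauC / tau
  G0 * sqrt(4 * pi * x * (tauD / tau)) * (1 + x^2 + 0.25 * x^4) * exp(-2 * x)
}

#' Crossover time of the piecewise 2D NIFS model
#'
#' Finds the lag `tau > tauC` at which the short- and long-time branches of
#' the 2D model intersect.  The amplitude `G0` cancels, so the crossover
#' depends only on the ratio `tauD/tauC`; for the nanowire rim geometry
#' (`tauD/tauC = 2 b0^2 / a0^2 = 0.32`) it falls near `8 tauC`.
#'
#' @inheritParams acf_fcs3d
#' @param upper Upper search bound, in multiples of `tauC`.
#' @return Crossover lag (s).
#' @export
branch_crossover <- function(tauD, tauC, upper = 1e4) {
  stopifnot(tauD > 0, tauC > 0)
  f <- function(tau) acf_nifs2d_small(tau, 1, tauD) -
    acf_nifs2d_large(tau, 1, tauD, tauC)
  lo <- tauC * (1 + 1e-9)
  if (f(lo) >= 0)  # branches already ordered at tauC: no crossover beyond it
    stop("branches do not intersect for tau > tauC (tauD/tauC = ",
         signif(tauD / tauC, 3), ")")
  uniroot(f, c(lo, upper * tauC), tol = 1e-10 * tauC)$root
}

#' Characteristic diffusion times
#'
#' Converts a diffusion constant and the illumination geometry into the model
#' timescales: conventional/3D `tauD = r0^2/(4D)` and `tauZ = z0^2/(4D)`;
#' 2D annular `tauD = b0^2/(2D)` and `tauC = a0^2/(4D)`.
#'
#' @param model `"fcs3d"`, `"nifs3d"` or `"nifs2d"`.
#' @param D Diffusion constant (m^2/s).
#' @param r0,z0,a0,b0 Profile geometry (m); which are needed depends on
#'   `model`.
#' @return Named numeric vector of times (s).
#' @examples
#' characteristic_times("fcs3d", D = 3e-11, r0 = 0.708e-6)["tauD"]  # 4.2 ms
#' @export
characteristic_times <- function(model = c("fcs3d", "nifs3d", "nifs2d"),
                                 D, r0 = NULL, z0 = NULL,
                                 a0 = NULL, b0 = NULL) {
  model <- match.arg(model)
  stopifnot(is.finite(D), D > 0)
  switch(model,
         fcs3d = {
           stopifnot(!is.null(r0))
           out <- c(tauD = r0^2 / (4 * D))
           if (!is.null(z0)) out <- c(out, tauZ = z0^2 / (4 * D))
           out
         },
         nifs3d = {
           stopifnot(!is.null(r0), !is.null(z0))
           c(tauD = r0^2 / (4 * D), tauZ = z0^2 / (4 * D))
         },
         nifs2d = {
           stopifnot(!is.null(a0), !is.null(b0))
           c(tauD = b0^2 / (2 * D), tauC = a0^2 / (4 * D))
         })
}

#' Effective illumination volume or area
#'
#' Closed-form normalisation size of each illumination profile:
#' conventional FCS `Veff = pi^{3/2} r0^2 z0` (m^3); 3D NIFS
#' `Veff = pi r0^2 z0` (m^3); 2D NIFS `Aeff = 2 pi^{3/2} a0 b0` (m^2).
#'
#' For the annular profile two conventions are in circulation and they differ
#' by `sqrt(2)`: `"area"` (the default, `2 pi^{3/2} a0 b0`) equals the plain
#' profile integral `\int W dA`, while `"amplitude"`
#' (`2 sqrt(2) pi^{3/2} a0 b0`) is `(\int W dA)^2 / \int W^2 dA`, the area
#' whose inverse is the true zero-lag amplitude `G(0) C`.  Both are reported
#' by [run_experiment()]; they are not silently reconciled.
#'
#' @inheritParams characteristic_times
#' @param convention For `model = "nifs2d"`: `"area"` or `"amplitude"`.
#' @return Scalar size in m^3 (3D models) or m^2 (2D).
#' @examples
#' effective_volume("fcs3d", r0 = 0.708e-6, z0 = 3 * 0.708e-6) / 1e-18 # fL
#' effective_volume("nifs3d", r0 = 60e-9, z0 = 12e-9) / 1e-24          # zL
#' @export
effective_volume <- function(model = c("fcs3d", "nifs3d", "nifs2d"),
                             r0 = NULL, z0 = NULL, a0 = NULL, b0 = NULL,
                             convention = c("area", "amplitude")) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  switch(model,
         fcs3d = {
           stopifnot(r0 > 0, z0 > 0)
           pi^1.5 * r0^2 * z0
         },
         nifs3d = {
           stopifnot(r0 > 0, z0 > 0)
           pi * r0^2 * z0
         },
         nifs2d = {
           stopifnot(a0 > 0, b0 > 0)
           2 * pi^1.5 * a0 * b0 * if (convention == "amplitude") sqrt(2) else 1
         })
}
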