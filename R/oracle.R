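## Brute-force numeric evaluation of the correlation integral
##
##   G(tau) = int int W(r) W(r') <dC(r,0) dC(r',tau)> dV dV' / [C (int W dV)^2]
##
## with <dC dC'> = C * P(r'|r, tau) for an ideal solution, used as an
## independent oracle for the closed-form models.  The free-space Gaussian
## propagator is used for `free3d`/`plane2d`; the method-of-images reflected
## propagator for the half-space above the waveguide (`halfspace3d`).
##
## All double integrals are evaluated in rotated coordinates u = a - b,
## v = a + b: the propagator rides the diagonal a ~ b as a narrow ridge, and
## rotating aligns it with the u axis so modest per-axis panel counts
## resolve it.  Panels are doubled until two successive estimates agree.

quad2_rect <- function(f, xlim, ylim, px, py, nodes = 8,
                       rel_tol = 1e-4, max_doublings = 5) {
  g <- pracma::gaussLegendre(nodes, 0, 1)
  eval_grid <- function(px, py) {
    bx <- seq(xlim[1], xlim[2], length.out = px + 1)
    by <- seq(ylim[1], ylim[2], length.out = py + 1)
    hx <- diff(bx)[1]; hy <- diff(by)[1]
    x <- as.vector(outer(g$x * hx, bx[-length(bx)], `+`))
    y <- as.vector(outer(g$x * hy, by[-length(by)], `+`))
    wx <- rep(g$w * hx, px); wy <- rep(g$w * hy, py)
    ## block over y to bound memory at ~ length(x) * 4000 doubles
    tot <- 0
    blk <- max(1L, as.integer(floor(4e7 / length(x))))
    for (j0 in seq(1L, length(y), by = blk)) {
      jj <- j0:min(j0 + blk - 1L, length(y))
      tot <- tot + as.numeric(t(wx) %*% outer(x, y[jj], f) %*% wy[jj])
    }
    tot
  }
  px <- max(4L, as.integer(px)); py <- max(4L, as.integer(py))
  prev <- eval_grid(px, py)
  for (i in seq_len(max_doublings)) {
    px <- px * 2L; py <- py * 2L
    cur <- eval_grid(px, py)
    if (abs(cur - prev) <= rel_tol * max(abs(cur), .Machine$double.xmin))
      return(cur)
    prev <- cur
  }
  stop("oracle quadrature did not converge to rel_tol = ", rel_tol,
       " (last relative change ", signif(abs(cur - prev) / abs(cur), 3), ")")
}

panels_for <- function(range, feature) {
  max(6L, min(240L, as.integer(ceiling(range / (2 * feature)))))
}

## Integral over the half-plane triangle v >= |u| (i.e. a, b >= 0 in the
## original coordinates), as int du int_{w>=0} f(u, |u| + w) dw.  The |u|
## kink sits on a panel edge (even panel count), so each panel sees a
## smooth integrand.
quad2_tri <- function(f, U, Wmax, pu, pw, rel_tol = 1e-4) {
  pu <- as.integer(pu) + as.integer(pu) %% 2L  # even: panel edge at u = 0
  quad2_rect(function(u, w) f(u, abs(u) + w),
             c(-U, U), c(0, Wmax), pu, pw, rel_tol = rel_tol)
}

#' Numeric autocorrelation oracle
#'
#' Evaluates the intensity autocorrelation by direct quadrature of the
#' correlation integral, independently of the closed-form models in
#' [acf_fcs3d()] and friends.  The concentration is factored out: the return
#' value is `G(tau) * C`, so e.g. `acf_oracle(...) * effective_volume(...)`
#' is directly comparable to the model shape `G(tau)/G0` for conventional
#' FCS.
#'
#' Supported combinations: `free3d` with a [profile_gaussian3d()] (free 3D
#' diffusion), `halfspace3d` with a [profile_nifs3d()] (reflecting wall at
#' z = 0, image-charge propagator), and `plane2d` with a [profile_annular()]
#' (free 2D in-plane diffusion; the angular integral is carried out
#' analytically via the modified Bessel function, the radial double integral
#' numerically).
#'
#' @inheritParams eval_profile
#' @param D Diffusion constant (m^2/s).
#' @param geometry `"free3d"`, `"halfspace3d"` or `"plane2d"`.
#' @param tau Lag times (s), > 0 (use small `tau` for the zero-lag limit).
#' @param rel_tol Relative quadrature tolerance; the quadrature panels are
#'   refined until two successive estimates agree to this tolerance, and an
#'   error is thrown if they never do.
#' @return `G(tau) * C` (units m^-3 for the 3D geometries, m^-2 for 2D).
#' @export
acf_oracle <- function(profile, D,
                       geometry = c("free3d", "halfspace3d", "plane2d"),
                       tau, rel_tol = 1e-4) {
  geometry <- match.arg(geometry)
  stopifnot(D > 0, all(tau > 0))
  fn <- switch(geometry,
               free3d = {
                 if (!inherits(profile, "profile_gaussian3d"))
                   stop("free3d oracle expects a Gaussian-ellipsoid profile")
                 function(t1) oracle_free3d(profile, D, t1, rel_tol)
               },
               halfspace3d = {
                 if (!inherits(profile, "profile_nifs3d"))
                   stop("halfspace3d oracle expects a 3D NIFS profile")
                 function(t1) oracle_halfspace(profile, D, t1, rel_tol)
               },
               plane2d = {
                 if (!inherits(profile, "profile_annular"))
                   stop("plane2d oracle expects an annular profile")
                 function(t1) oracle_plane2d(profile, D, t1, rel_tol)
               })
  vapply(tau, fn, numeric(1))
}

## All integrals below are evaluated in dimensionless coordinates (lengths
## in units of the relevant profile scale): quadrature tolerances are
## relative comparisons of partial sums, and O(1) magnitudes keep them
## meaningful where SI magnitudes of 1e-15 and below would not be.

## dimensionless 1D factor int int w(a) w(b) phi_sh(a - b) da db for a
## Gaussian-type profile of unit 1/e^2 half-width, in rotated coordinates;
## multiply by `scale` for the physical factor.
axis_factor_hat <- function(w, sh, rel_tol) {
  U <- min(6, 3 + 4 * sh)
  V <- 3 + 3 * sh
  f <- function(u, v) {
    a <- (v + u) / 2; b <- (v - u) / 2
    0.5 * w(a) * w(b) * dnorm(u, 0, sh)
  }
  quad2_rect(f, c(-U, U), c(-V, V),
             panels_for(2 * U, min(1, sh)), panels_for(2 * V, 1),
             rel_tol = rel_tol)
}

oracle_free3d <- function(p, D, tau, rel_tol) {
  s <- sqrt(2 * D * tau)
  wg <- function(x) exp(-2 * x^2)
  lat_hat <- axis_factor_hat(wg, s / p$r0, rel_tol)   # lengths in r0
  ax_hat <- axis_factor_hat(wg, s / p$z0, rel_tol)    # lengths in z0
  ihat <- sqrt(pi / 2)  # int exp(-2x^2) dx
  ## physical: lat = r0 * lat_hat etc.; the r0, z0 powers cancel into 1/volume
  lat_hat^2 * ax_hat / (ihat^4 * ihat^2) / (p$r0^2 * p$z0)
}

oracle_halfspace <- function(p, D, tau, rel_tol) {
  s <- sqrt(2 * D * tau)
  lat_hat <- axis_factor_hat(function(x) exp(-2 * x^2), s / p$r0, rel_tol)
  ## axial: z, z' >= 0 in units of z0, exponential profile, reflecting wall
  ## at z = 0: propagator phi(z - z') + phi(z + z'); rotated coordinates
  ## u = z - z', v = z + z', integrated over the triangle v >= |u|
  sh <- s / p$z0
  V <- 14 + 4 * sh
  f <- function(u, v) 0.5 * exp(-v) * (dnorm(u, 0, sh) + dnorm(v, 0, sh))
  U <- min(V, 6 * sh + 2)
  ax_hat <- quad2_tri(f, U, V,
                      panels_for(2 * U, min(1, sh)),
                      panels_for(V, min(1, sh)),
                      rel_tol = rel_tol)
  ihat <- sqrt(pi / 2)
  lat_hat^2 * ax_hat / (ihat^4 * 1) / (p$r0^2 * p$z0)  # int e^-z dz = 1
}

oracle_plane2d <- function(p, D, tau, rel_tol) {
  ## lengths in units of b0; a = a0/b0
  a <- p$a0 / p$b0
  s2 <- 4 * D * tau / p$b0^2
  s <- sqrt(s2)
  W <- function(r) exp(-(r - a)^2)
  ## radial double integral after the exact angular integral of the 2D
  ## Gaussian propagator: kernel (2/s2) exp(-(r-r')^2/s2) I0sc(2rr'/s2)
  f <- function(u, v) {
    r <- (v + u) / 2; rp <- (v - u) / 2
    x <- 2 * r * rp / s2
    0.5 * (2 * pi) * r * rp * W(r) * W(rp) *
      exp(-u^2 / s2) * (2 / s2) * besselI(x, 0, expon.scaled = TRUE)
  }
  U <- min(14, 7 + 4 * s)
  V <- 2 * a + 16 + 2 * s
  num <- quad2_tri(f, U, V,
                   panels_for(2 * U, min(1, s)),
                   panels_for(V, 1),
                   rel_tol = rel_tol)
  iw <- pracma::quadgk(function(r) 2 * pi * r * W(r), 0, a + 15,
                       tol = 1e-10)
  num / iw^2 / p$b0^2
}
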