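## Illumination profiles.
##
## All profiles are dimensionless shapes normalised to a peak intensity of 1;
## the absolute excitation amplitude lives in the simulator's `brightness`
## parameter.  Coordinates are in metres, with z = 0 the waveguide exit plane
## and z > 0 the sample half-space.

#' Gaussian-ellipsoid illumination profile (confocal FCS)
#'
#' The classical diffraction-limited focal volume,
#' \deqn{W(x,y,z) = e^{-2(x^2+y^2)/r_0^2}\, e^{-2 z^2/z_0^2},}
#' with `r0` the lateral and `z0` the axial 1/e^2 radius.  The oblateness
#' `kappa = z0/r0` may be given instead of `z0`.
#'
#' @param r0 Lateral 1/e^2 radius (m).
#' @param z0 Axial 1/e^2 half-length (m).  Exactly one of `z0`, `kappa`.
#' @param kappa Axial-to-lateral ratio `z0/r0` (dimensionless).
#' @return An object of class `c("profile_gaussian3d", "nifs_profile")`.
#' @seealso [profile_nifs3d()], [profile_annular()], [eval_profile()]
#' @examples
#' w <- profile_gaussian3d(r0 = 0.708e-6, kappa = 3)
#' eval_profile(w, c(0, 0, 0))          # 1 at the focus
#' @export
profile_gaussian3d <- function(r0 = 0.708e-6, z0 = NULL, kappa = NULL) {
  if (is.null(z0) && is.null(kappa)) kappa <- 3
  if (!is.null(z0) && !is.null(kappa))
    stop("give either `z0` or `kappa`, not both")
  if (is.null(z0)) z0 <- kappa * r0
  stopifnot(is.finite(r0), r0 > 0, is.finite(z0), z0 > 0)
  structure(list(r0 = r0, z0 = z0, kappa = z0 / r0),
            class = c("profile_gaussian3d", "nifs_profile"))
}

#' Nanowaveguide near-field illumination profile (3D NIFS)
#'
#' Intensity emerging from the exit face of a nanowire waveguide: laterally
#' Gaussian, exponentially decaying along z, and identically zero below the
#' exit plane (fluorophores cannot enter the waveguide),
#' \deqn{W(x,y,z) = e^{-2(x^2+y^2)/r_0^2}\, e^{-z/z_0} \quad (z > 0), \qquad
#'       W = 0 \quad (z < 0).}
#'
#' Defaults correspond to a 40-nm-diameter nanowire: lateral extent of about
#' 60 nm and an axial decay length of about 12 nm.
#'
#' @param r0 Lateral 1/e^2 extent (m).
#' @param z0 Axial decay length (m).
#' @return An object of class `c("profile_nifs3d", "nifs_profile")`.
#' @export
profile_nifs3d <- function(r0 = 60e-9, z0 = 12e-9) {
  stopifnot(is.finite(r0), r0 > 0, is.finite(z0), z0 > 0)
  structure(list(r0 = r0, z0 = z0),
            class = c("profile_nifs3d", "nifs_profile"))
}

#' Annular near-field profile at the waveguide exit surface (2D NIFS)
#'
#' Within a few nanometres of the exit plane the lightning-rod effect
#' concentrates the field at the rim of the nanowire, giving a ring-shaped
#' profile
#' \deqn{W(r) = e^{-(r-a_0)^2/b_0^2}, \qquad r = \sqrt{x^2+y^2},}
#' maximal on the circle \eqn{r = a_0} (the nanowire radius) with radial Gaussian
#' width `b0`.  Used for fluorophores confined to a membrane plane just above
#' the exit surface; the z coordinate is ignored.
#'
#' @param a0 Annulus (nanowire) radius (m).
#' @param b0 Radial Gaussian width (m).
#' @return An object of class `c("profile_annular", "nifs_profile")`.
#' @export
profile_annular <- function(a0 = 20e-9, b0 = 8e-9) {
  stopifnot(is.finite(a0), a0 > 0, is.finite(b0), b0 > 0)
  structure(list(a0 = a0, b0 = b0),
            class = c("profile_annular", "nifs_profile"))
}

#' Grid-sampled illumination profile
#'
#' Wraps a peak-normalised intensity sampled on a rectilinear (x, y, z) grid,
#' e.g. the output of an electromagnetic field solver.  Evaluation
#' interpolates multilinearly (`order = 1`, default) or takes the nearest
#' grid node (`order = 0`); positions outside the grid extent evaluate to 0.
#'
#' @param x,y,z Strictly increasing axis coordinates (m).
#' @param values Numeric array of non-negative intensities with
#'   `dim = c(length(x), length(y), length(z))`.  Rescaled so the maximum is 1.
#' @param order Interpolation order: 0 (nearest) or 1 (multilinear).
#' @return An object of class `c("profile_grid", "nifs_profile")`.
#' @seealso [read_profile_grid()] for the CSV interchange format.
#' @export
profile_grid <- function(x, y, z, values, order = 1) {
  values <- as.array(values)
  if (!identical(dim(values), c(length(x), length(y), length(z))))
    stop("dim(values) must be c(length(x), length(y), length(z))")
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid intensities must be finite and >= 0")
  for (ax in list(x, y, z))
    if (length(ax) < 2 || any(diff(ax) <= 0) || any(!is.finite(ax)))
      stop("axis coordinates must be finite, strictly increasing, length >= 2")
  if (!order %in% c(0, 1)) stop("`order` must be 0 or 1")
  mx <- max(values)
  if (mx <= 0) stop("grid profile is identically zero")
  structure(list(x = x, y = y, z = z, values = values / mx, order = order),
            class = c("profile_grid", "nifs_profile"))
}

#' @export
print.nifs_profile <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  p <- x[names(x) %in% c("r0", "z0", "kappa", "a0", "b0", "order")]
  for (nm in names(p))
    cat(sprintf("  %-6s %s\n", nm,
                if (nm %in% c("kappa", "order")) format(p[[nm]])
                else sprintf("%.4g nm", p[[nm]] * 1e9)))
  if (inherits(x, "profile_grid"))
    cat(sprintf("  grid   %d x %d x %d nodes\n",
                length(x$x), length(x$y), length(x$z)))
  invisible(x)
}

#' Evaluate an illumination profile
#'
#' @param profile A profile created by [profile_gaussian3d()],
#'   [profile_nifs3d()], [profile_annular()] or [profile_grid()].
#' @param pos A length-3 position `c(x, y, z)` in metres, or an n-by-3 matrix
#'   of positions.
#' @return Normalised intensity in `[0, 1]`, one value per position.
#' @examples
#' eval_profile(profile_nifs3d(), c(0, 0, 12e-9))   # exp(-1)
#' eval_profile(profile_nifs3d(), c(0, 0, -1e-9))   # 0: inside the waveguide
#' @export
eval_profile <- function(profile, pos) {
  pos <- as_pos_matrix(pos)
  UseMethod("eval_profile")
}

as_pos_matrix <- function(pos) {
  if (is.null(dim(pos))) {
    if (length(pos) != 3L) stop("`pos` must be length 3 or an n-by-3 matrix")
    pos <- matrix(pos, 1L, 3L)
  }
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stop("`pos` must have 3 columns (x, y, z)")
  if (any(!is.finite(pos))) stop("non-finite position")
  pos
}

#' @export
eval_profile.profile_gaussian3d <- function(profile, pos) {
  pos <- as_pos_matrix(pos)
  exp(-2 * (pos[, 1]^2 + pos[, 2]^2) / profile$r0^2 -
        2 * pos[, 3]^2 / profile$z0^2)
}

#' @export
eval_profile.profile_nifs3d <- function(profile, pos) {
  pos <- as_pos_matrix(pos)
  w <- exp(-2 * (pos[, 1]^2 + pos[, 2]^2) / profile$r0^2 -
             pos[, 3] / profile$z0)
  w[pos[, 3] < 0] <- 0
  w
}

#' @export
eval_profile.profile_annular <- function(profile, pos) {
  pos <- as_pos_matrix(pos)
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  exp(-(r - profile$a0)^2 / profile$b0^2)
}

#' @export
eval_profile.profile_grid <- function(profile, pos) {
  pos <- as_pos_matrix(pos)
  grid_interp(profile, pos[, 1], pos[, 2], pos[, 3])
}

## Multilinear / nearest-neighbour interpolation on the rectilinear grid;
## zero outside the grid extent.
grid_interp <- function(p, x, y, z) {
  n <- length(x)
  out <- numeric(n)
  inside <- x >= p$x[1] & x <= p$x[length(p$x)] &
    y >= p$y[1] & y <= p$y[length(p$y)] &
    z >= p$z[1] & z <= p$z[length(p$z)]
  if (!any(inside)) return(out)
  loc <- function(ax, v) {
    i <- findInterval(v, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ax) - 1L)
    t <- (v - ax[i]) / (ax[i + 1L] - ax[i])
    list(i = i, t = t)
  }
  lx <- loc(p$x, x[inside]); ly <- loc(p$y, y[inside]); lz <- loc(p$z, z[inside])
  if (p$order == 0) {
    ix <- lx$i + (lx$t > 0.5); iy <- ly$i + (ly$t > 0.5); iz <- lz$i + (lz$t > 0.5)
    out[inside] <- p$values[cbind(ix, iy, iz)]
    return(out)
  }
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) lx$t else 1 - lx$t) *
      (if (dy) ly$t else 1 - ly$t) *
      (if (dz) lz$t else 1 - lz$t)
    acc <- acc + w * p$values[cbind(lx$i + dx, ly$i + dy, lz$i + dz)]
  }
  out[inside] <- acc
  out
}

#' Integral of an illumination profile
#'
#' Numerically integrates `W` over its support: a volume integral (m^3) for
#' the 3D profiles and an in-plane area integral (m^2) for the annular
#' profile.  Used to cross-check the closed-form effective volume / area
#' expressions; see [effective_volume()].
#'
#' @inheritParams eval_profile
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return Scalar integral, with attribute `"units"` set to `"m^3"` or
#'   `"m^2"`.
#' @export
profile_integral <- function(profile, rel_tol = 1e-8) {
  UseMethod("profile_integral")
}

## All quadratures run in dimensionless coordinates (lengths scaled by the
## profile's own scale) so that absolute quadrature tolerances are
## meaningful; SI magnitudes of these integrals are ~1e-15 and below.

#' @export
profile_integral.profile_gaussian3d <- function(profile, rel_tol = 1e-8) {
  f1 <- function(rho) 2 * pi * rho * exp(-2 * rho^2)
  fz <- function(z) exp(-2 * z^2)
  v <- pracma::quadgk(f1, 0, 8, tol = rel_tol) * profile$r0^2 *
    pracma::quadgk(fz, -8, 8, tol = rel_tol) * profile$z0
  structure(v, units = "m^3")
}

#' @export
profile_integral.profile_nifs3d <- function(profile, rel_tol = 1e-8) {
  f1 <- function(rho) 2 * pi * rho * exp(-2 * rho^2)
  fz <- function(z) exp(-z)
  v <- pracma::quadgk(f1, 0, 8, tol = rel_tol) * profile$r0^2 *
    pracma::quadgk(fz, 0, 60, tol = rel_tol) * profile$z0
  structure(v, units = "m^3")
}

#' @export
profile_integral.profile_annular <- function(profile, rel_tol = 1e-8) {
  a <- profile$a0 / profile$b0
  f <- function(r) 2 * pi * r * exp(-(r - a)^2)
  v <- pracma::quadgk(f, 0, a + 15, tol = rel_tol) * profile$b0^2
  structure(v, units = "m^2")
}

#' @export
profile_integral.profile_grid <- function(profile, rel_tol = 1e-8) {
  ## trapezoidal rule along each axis of the rectilinear grid
  wts <- function(ax) {
    d <- diff(ax)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  }
  wx <- wts(profile$x); wy <- wts(profile$y); wz <- wts(profile$z)
  v <- 0
  for (k in seq_along(wz))
    v <- v + wz[k] * sum((wx %o% wy) * profile$values[, , k])
  structure(v, units = "m^3")
}

#' Read / write grid-sampled profiles as plain CSV
#'
#' Interchange format for externally computed intensity maps.  The file is a
#' CSV whose first three rows give the axis coordinates (`x,...`, `y,...`,
#' `z,...`, in metres) and whose remaining rows hold the intensity values
#' row-major: one row of `length(x)` values per `(y, z)` pair, with `y`
#' varying fastest.
#'
#' @param file Path to a CSV file.
#' @param profile A [profile_grid()] object.
#' @param order Interpolation order passed to [profile_grid()].
#' @return `read_profile_grid()` returns a [profile_grid()] object;
#'   `write_profile_grid()` returns `file` invisibly.
#' @export
read_profile_grid <- function(file, order = 1) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parse_row <- function(l) as.numeric(strsplit(l, ",")[[1]][-1])
  tag <- function(l) trimws(strsplit(l, ",")[[1]][1])
  if (!identical(sapply(lines[1:3], tag, USE.NAMES = FALSE), c("x", "y", "z")))
    stop("grid profile file must start with x, y and z axis rows")
  x <- parse_row(lines[1]); y <- parse_row(lines[2]); z <- parse_row(lines[3])
  vals <- lapply(lines[-(1:3)], function(l) as.numeric(strsplit(l, ",")[[1]]))
  if (length(vals) != length(y) * length(z))
    stop("expected ", length(y) * length(z), " value rows, got ", length(vals))
  arr <- array(0, dim = c(length(x), length(y), length(z)))
  k <- 1L
  for (iz in seq_along(z)) for (iy in seq_along(y)) {
    if (length(vals[[k]]) != length(x)) stop("value row ", k, " has wrong length")
    arr[, iy, iz] <- vals[[k]]
    k <- k + 1L
  }
  profile_grid(x, y, z, arr, order = order)
}

#' @rdname read_profile_grid
#' @export
write_profile_grid <- function(profile, file) {
  stopifnot(inherits(profile, "profile_grid"))
  con <- file(file, "w")
  on.exit(close(con))
  fmt <- function(v) paste(format(v, digits = 12), collapse = ",")
  writeLines(c(paste0("x,", fmt(profile$x)),
               paste0("y,", fmt(profile$y)),
               paste0("z,", fmt(profile$z))), con)
  for (iz in seq_along(profile$z)) for (iy in seq_along(profile$y))
    writeLines(fmt(profile$values[, iy, iz]), con)
  invisible(file)
}

## Internal dispatch code used by the compiled simulation kernel.
profile_kernel_id <- function(profile) {
  if (inherits(profile, "profile_gaussian3d")) 1L
  else if (inherits(profile, "profile_nifs3d")) 2L
  else if (inherits(profile, "profile_annular")) 3L
  else if (inherits(profile, "profile_grid")) 4L
  else stop("unknown profile class")
}
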