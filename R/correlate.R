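## Autocorrelation estimation from binned photon-count traces.

#' Quasi-logarithmic lag grid
#'
#' Builds a set of lag times that are integer multiples of the bin width
#' `dt`, approximately log-spaced from `dt` up to a tenth of the trace
#' duration (beyond which the estimator variance grows sharply).
#'
#' @param dt Bin width (s).
#' @param n_steps Trace length in bins.
#' @param points_per_decade Target lag density (>= 1).
#' @param max_lag Optional cap on the largest lag (s).
#' @return Sorted unique lag times (s), all integer multiples of `dt`.
#' @export
make_lag_grid <- function(dt, n_steps, points_per_decade = 12, max_lag = NULL) {
  stopifnot(dt > 0, n_steps >= 20, points_per_decade >= 1)
  kmax <- floor(n_steps / 10)
  if (!is.null(max_lag)) kmax <- min(kmax, floor(max_lag / dt))
  stopifnot(kmax >= 1)
  decades <- log10(kmax)
  k <- unique(round(10^seq(0, decades, length.out =
                             max(2, ceiling(decades * points_per_decade) + 1))))
  k <- k[k >= 1 & k <= kmax]
  k * dt
}

new_corr_curve <- function(lag, G, sd = rep(NA_real_, length(lag)),
                           n_runs = 1L, dt = NA_real_) {
  stopifnot(length(lag) == length(G), !is.unsorted(lag), all(lag > 0))
  structure(data.frame(lag = lag, G = G, sd = sd),
            n_runs = as.integer(n_runs), dt = dt,
            class = c("corr_curve", "data.frame"))
}

#' Autocorrelation of an intensity trace
#'
#' Direct-summation estimator of the normalised fluorescence autocorrelation
#' \deqn{G(\tau) = \langle \delta F(t)\, \delta F(t+\tau)\rangle /
#'       \langle F\rangle^2}
#' at the requested lags, averaging over all valid start times.  The mean is
#' taken over the full trace (the simulation is stationary; no bleaching
#' correction).  The zero lag is excluded: its shot-noise term is not part of
#' the diffusion models.
#'
#' @param trace An `intensity_trace` from [run_simulation()] (integer
#'   counts per bin with a `dt` attribute) or a plain numeric vector plus
#'   `dt`.
#' @param lags Lag times (s), integer multiples of `dt`, each at most a tenth
#'   of the trace duration.  Default: [make_lag_grid()].
#' @param dt Bin width (s); taken from the trace attribute when present.
#' @return A `corr_curve` data frame with columns `lag`, `G`, `sd` (NA for a
#'   single trace).
#' @export
autocorrelate <- function(trace, lags = NULL, dt = attr(trace, "dt")) {
  if (is.null(dt)) stop("bin width `dt` is required")
  f <- as.numeric(trace)
  n <- length(f)
  m <- mean(f)
  if (m == 0) stop("trace is identically zero; G is undefined")
  if (is.null(lags)) lags <- make_lag_grid(dt, n)
  k <- lags / dt
  if (any(abs(k - round(k)) > 1e-6))
    stop("lags must be integer multiples of the bin width")
  k <- as.integer(round(k))
  if (any(k < 1) || any(k > n / 10))
    stop("lags must lie in [dt, n_steps*dt/10]")
  G <- .autocorr_kernel(f, k) / m^2 - 1
  new_corr_curve(lags, G, dt = dt)
}

#' Average correlation curves across simulation runs
#'
#' Per-lag mean and sample standard deviation (n - 1 denominator, the
#' convention used to normalise residuals) across repeat runs with identical
#' parameters but different seeds.
#'
#' @param curves List of `corr_curve` objects on identical lag grids.
#' @return A `corr_curve` with `sd` filled in and `n_runs` set.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "corr_curve")))
  lag <- curves[[1]]$lag
  for (cv in curves[-1])
    if (!isTRUE(all.equal(cv$lag, lag)))
      stop("curves have mismatched lag grids")
  Gs <- vapply(curves, function(cv) cv$G, numeric(length(lag)))
  Gs <- matrix(Gs, nrow = length(lag))
  new_corr_curve(lag,
                 G = rowMeans(Gs),
                 sd = if (length(curves) > 1) apply(Gs, 1, sd)
                      else rep(NA_real_, length(lag)),
                 n_runs = length(curves),
                 dt = attr(curves[[1]], "dt"))
}

#' Normalised residuals of a curve against model values
#'
#' `(G - model) / sd` per lag, the standard residual display for FCS fits.
#' Lags with `sd == 0` or missing `sd` are returned as `NA` and flagged with
#' a warning.
#'
#' @param curve A `corr_curve` with per-lag standard deviations.
#' @param model_values Model `G` evaluated at `curve$lag`.
#' @return Numeric vector of normalised residuals.
#' @export
curve_residuals <- function(curve, model_values) {
  stopifnot(inherits(curve, "corr_curve"),
            length(model_values) == nrow(curve))
  bad <- !is.finite(curve$sd) | curve$sd == 0
  if (any(bad))
    warning(sum(bad), " lag(s) with zero/missing sd excluded from residuals")
  out <- rep(NA_real_, nrow(curve))
  out[!bad] <- (curve$G[!bad] - model_values[!bad]) / curve$sd[!bad]
  out
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("Correlation curve: %d lags in [%.3g, %.3g] s, %d run(s)\n",
              nrow(x), min(x$lag), max(x$lag), attr(x, "n_runs")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.corr_curve <- function(x, ..., add = FALSE, col = 1, pch = 1,
                            xlab = expression(tau ~ "(s)"),
                            ylab = expression(G(tau))) {
  if (!add)
    plot(x$lag, x$G, log = "x", xlab = xlab, ylab = ylab, col = col,
         pch = pch, ...)
  else points(x$lag, x$G, col = col, pch = pch, ...)
  if (any(is.finite(x$sd))) {
    up <- x$G + x$sd; lo <- x$G - x$sd
    segs <- is.finite(up) & is.finite(lo)
    arrows(x$lag[segs], lo[segs], x$lag[segs], up[segs], angle = 90,
           code = 3, length = 0.02, col = adjustcolor(col, 0.6))
  }
  invisible(x)
}

#' Correlation curve CSV I/O
#'
#' Columns `lag_s, G, sd, n_runs`.
#'
#' @param curve A `corr_curve`.
#' @param file Path.
#' @return `read_curve()` returns a `corr_curve`; `write_curve()` the path,
#'   invisibly.
#' @export
write_curve <- function(curve, file) {
  stopifnot(inherits(curve, "corr_curve"))
  df <- data.frame(lag_s = curve$lag, G = curve$G, sd = curve$sd,
                   n_runs = attr(curve, "n_runs"))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file) {
  df <- read.csv(file)
  new_corr_curve(df$lag_s, df$G, df$sd, n_runs = df$n_runs[1])
}
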