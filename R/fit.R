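## Weighted nonlinear least-squares fitting of correlation curves.

model_par_names <- function(model) {
  switch(model,
         fcs3d = c("G0", "tauD", "kappa"),
         nifs3d = c("G0", "tauD", "tauZ"),
         nifs2d = c("G0", "tauD", "tauC"))
}

eval_model <- function(model, tau, par, tau_crit = NULL) {
  switch(model,
         fcs3d = acf_fcs3d(tau, par[["G0"]], par[["tauD"]], par[["kappa"]]),
         nifs3d = acf_nifs3d(tau, par[["G0"]], par[["tauD"]], par[["tauZ"]]),
         nifs2d = acf_nifs2d(tau, par[["G0"]], par[["tauD"]], par[["tauC"]],
                             tau_crit = tau_crit))
}

## Expected downward offset of the direct ACF estimator for a finite trace
## of duration T (the mean is estimated from the same trace) and, when the
## simulation volume holds a fixed number N of particles, the closed-box
## anticorrelation:
##
##   E[Ghat(tau)] ~ G(tau) - (2/T) int_0^T (1 - t/T) G(t) dt - 1/N.
##
## Both terms are exactly computable from the model parameters, so fits can
## account for them instead of absorbing them into distorted timescales.
finite_size_offset <- function(model, par, tau_crit, T_trace, n_box) {
  f <- function(t) (1 - t / T_trace) * eval_model(model, t, par, tau_crit)
  b <- tryCatch(
    stats::integrate(f, 0, T_trace, subdivisions = 1000L,
                     rel.tol = 1e-7)$value,
    error = function(e) {
      ## integrand is flat near 0 and tiny near T; fall back to a log grid
      tt <- exp(seq(log(T_trace * 1e-9), log(T_trace), length.out = 4000))
      sum(diff(c(0, tt)) * f(tt))
    })
  2 * b / T_trace + if (is.null(n_box) || !is.finite(n_box)) 0 else 1 / n_box
}

#' Heuristic starting values for a correlation-curve fit
#'
#' `G0` starts at the smallest-lag amplitude, `tauD` at the lag where the
#' curve has decayed to half of it; the second timescale starts at a
#' geometry-scaled multiple of `tauD` (`tauZ = tauD/25`, the default
#' near-field aspect `(z0/r0)^2`; `tauC = 3 tauD`, the default rim aspect
#' `a0^2/(2 b0^2)`), and `kappa` at the common confocal value 3.
#'
#' @param curve A `corr_curve` spanning at least two decades with >= 10 lags.
#' @param model `"fcs3d"`, `"nifs3d"` or `"nifs2d"`.
#' @return Named vector of starting parameters.
#' @export
initial_guess <- function(curve, model = c("fcs3d", "nifs3d", "nifs2d")) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "corr_curve"))
  if (nrow(curve) < 10 || max(curve$lag) / min(curve$lag) < 100)
    stop("need >= 10 lags spanning >= 2 decades for an initial guess")
  G0 <- curve$G[1]
  if (!is.finite(G0) || G0 <= 0 || min(curve$G) > 0.6 * G0)
    stop("curve does not decay; cannot locate a diffusion time")
  i <- which(curve$G <= G0 / 2)[1]
  tauD <- if (i > 1) {
    ## log-linear interpolation to G0/2 between the bracketing lags
    g1 <- curve$G[i - 1]; g2 <- curve$G[i]
    l1 <- log(curve$lag[i - 1]); l2 <- log(curve$lag[i])
    exp(l1 + (l2 - l1) * (g1 - G0 / 2) / (g1 - g2))
  } else curve$lag[1]
  switch(model,
         fcs3d = c(G0 = G0, tauD = tauD, kappa = 3),
         nifs3d = c(G0 = G0, tauD = tauD, tauZ = tauD / 25),
         nifs2d = c(G0 = G0, tauD = tauD, tauC = 3 * tauD))
}

#' Fit a correlation curve to an FCS / NIFS autocorrelation model
#'
#' Weighted nonlinear least squares of a measured (or simulated) correlation
#' curve against one of the closed-form models ([acf_fcs3d()],
#' [acf_nifs3d()], [acf_nifs2d()]).  Parameters are optimised on the log
#' scale (enforcing positivity) with Levenberg-Marquardt, restarting from
#' jittered initial guesses if a run fails to converge.  For the piecewise
#' 2D model the branch switch time is iterated to the crossover of the two
#' fitted branches (fixed-point loop, tolerance 1% in `tau_crit`).
#'
#' @param curve A `corr_curve` (see [autocorrelate()], [average_curves()]).
#' @param model `"fcs3d"`, `"nifs3d"` or `"nifs2d"`.
#' @param weights `"sd"` (weights `1/sd`, requiring per-lag standard
#'   deviations from multi-run averaging; lags with `sd == 0` are dropped)
#'   or `"uniform"`.
#' @param start Optional named starting values; default [initial_guess()].
#' @param fixed Optional named list/vector of parameters to hold fixed
#'   (e.g. `c(kappa = 3)`).
#' @param concentration Known mean concentration (m^-3, or m^-2 for the 2D
#'   model); when supplied, effective volume/area and mean occupancy are
#'   derived from the fitted amplitude (see [derive_quantities()]).
#' @param finite_size Optional finite-sample offset model, a list
#'   `list(T = <trace duration, s>, N = <particles in the box>)`.  The
#'   direct estimator normalised by the same trace's mean sits below the
#'   true ACF by `(2/T) int (1 - t/T) G dt`, and a simulation box holding a
#'   fixed number of particles contributes a further `-1/N` (occupancy
#'   anticorrelation in a closed system).  When supplied, the fit subtracts
#'   this parameter-dependent offset from the model instead of letting it
#'   distort the fitted timescales; both terms vanish as `T` and `N` grow.
#'   `N = NULL` drops the closed-box term.
#' @param max_restarts Maximum jittered restarts after a failed convergence.
#' @return An object of class `fcs_fit` with `print()`, `summary()`,
#'   `coef()`, `vcov()`, `predict()`, `fitted()`, `residuals()` and `plot()`
#'   methods.
#' @examples
#' tau <- make_lag_grid(1e-7, 1e6)
#' g <- acf_fcs3d(tau, G0 = 0.17, tauD = 4.2e-3, kappa = 3)
#' curve <- nifs:::new_corr_curve(tau, g, rep(0.002, length(tau)), n_runs = 20)
#' fit <- fcs_fit(curve, "fcs3d")
#' coef(fit)["tauD"]
#' @export
fcs_fit <- function(curve, model = c("fcs3d", "nifs3d", "nifs2d"),
                    weights = c("sd", "uniform"), start = NULL,
                    fixed = NULL, concentration = NULL, finite_size = NULL,
                    max_restarts = 5) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "corr_curve"))

  keep <- is.finite(curve$G)
  n_runs <- attr(curve, "n_runs") %||% 1L
  w <- if (weights == "sd") {
    if (!any(is.finite(curve$sd)))
      stop("weights = \"sd\" needs per-lag standard deviations ",
           "(average multiple runs first)")
    keep <- keep & is.finite(curve$sd) & curve$sd > 0
    ## the fitted curve is the mean of n_runs runs, so its per-lag error is
    ## sd/sqrt(n); the scale only matters for chi-square and standard errors
    sqrt(max(n_runs, 1L)) / curve$sd[keep]
  } else rep(1, sum(keep))
  tau <- curve$lag[keep]
  G <- curve$G[keep]

  pn <- model_par_names(model)
  start <- c(start)
  if (is.null(start)) start <- initial_guess(curve, model)
  start <- start[pn]
  names(start) <- pn
  if (any(!is.finite(start)) || any(start <= 0))
    stop("starting values must be finite and positive for: ",
         paste(pn[!is.finite(start) | start <= 0], collapse = ", "))
  fixed <- unlist(fixed)
  free <- setdiff(pn, names(fixed))
  if (length(free) == 0) stop("no free parameters")
  if (!is.null(fixed)) start[names(fixed)] <- fixed

  tau_crit <- if (model == "nifs2d")
    branch_crossover(start[["tauD"]], start[["tauC"]]) else NULL

  if (!is.null(finite_size))
    stopifnot(is.list(finite_size), is.numeric(finite_size$T),
              finite_size$T > 0)

  ## The finite-size offset is held constant within each least-squares run
  ## and updated by an outer fixed-point loop below: making it depend on
  ## the trial parameters inside the objective opens a spurious branch
  ## where amplitude, timescale and offset inflate together.
  offset <- 0

  fit_once <- function(theta0, tau_crit) {
    resid_fn <- function(theta) {
      par <- start
      par[free] <- exp(theta)
      (eval_model(model, tau, par, tau_crit) - offset - G) * w
    }
    minpack.lm::nls.lm(par = log(start[free] * theta0),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  }

  run_fit <- function(tau_crit) {
    jit <- 1
    ## fixed restart-jitter stream, without disturbing the caller's RNG
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(20211)
    for (try in 0:max_restarts) {
      fit <- fit_once(jit, tau_crit)
      ok <- fit$info %in% 1:4 && all(is.finite(fit$par))
      if (ok) return(fit)
      jit <- exp(rnorm(length(free), 0, 0.5))
    }
    warning("fit did not converge after ", max_restarts,
            " restarts; returning best effort")
    fit
  }

  run_fit_tc <- function() {
    fit <- run_fit(tau_crit)
    if (model == "nifs2d") {
      for (it in seq_len(10)) {
        par <- start
        par[free] <- exp(fit$par)
        tc_new <- branch_crossover(par[["tauD"]], par[["tauC"]])
        if (abs(tc_new - tau_crit) <= 0.01 * tau_crit) {
          tau_crit <<- tc_new
          break
        }
        tau_crit <<- tc_new
        fit <- run_fit(tau_crit)
      }
    }
    fit
  }

  fit <- run_fit_tc()
  if (!is.null(finite_size)) {
    for (it in seq_len(6)) {
      par <- start
      par[free] <- exp(fit$par)
      off_new <- finite_size_offset(model, par, tau_crit,
                                    finite_size$T, finite_size$N)
      done <- abs(off_new - offset) <= 0.02 * max(abs(off_new), 1e-12)
      offset <- off_new
      if (done) break
      fit <- run_fit_tc()
    }
  }

  par <- start
  par[free] <- exp(fit$par)
  pred <- eval_model(model, tau, par, tau_crit) - offset
  dof <- length(tau) - length(free)
  chisq_red <- sum(((G - pred) * w)^2) / max(dof, 1)

  ## delta-method SEs from the log-scale covariance at the optimum;
  ## approximate (weighted Jacobian, local curvature only)
  se <- rep(NA_real_, length(pn))
  names(se) <- pn
  vc <- matrix(NA_real_, length(free), length(free),
               dimnames = list(free, free))
  hins <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(hins, "try-error")) {
    vc_log <- hins * chisq_red  # (J'J)^-1 * resvar on the log scale
    vc <- diag(par[free], length(free)) %*% vc_log %*%
      diag(par[free], length(free))
    dimnames(vc) <- list(free, free)
    se[free] <- sqrt(pmax(diag(vc), 0))
  }

  ## residuals normalised by the standard error of the fitted (averaged)
  ## curve: ~N(0, 1) per lag when the model is right, so "most points
  ## within 1" is the consistency display
  norm_resid <- if (weights == "sd") (G - pred) * w else
    tryCatch(suppressWarnings(
      curve_residuals(curve[keep, , drop = FALSE], pred)),
      error = function(e) G - pred)

  out <- structure(list(
    model = model, par = par, se = se, vcov = vc, free = free,
    fixed = fixed, tau_crit = tau_crit,
    finite_size = finite_size, offset = offset,
    curve = curve, used = which(keep), weights = weights,
    fitted = pred, norm_resid = norm_resid,
    chisq_red = chisq_red, dof = dof,
    converged = fit$info %in% 1:4, info = fit$info,
    message = fit$message), class = "fcs_fit")
  if (!is.null(concentration))
    out$derived <- derive_quantities(out, concentration)
  out
}

#' Effective volume / area and occupancy from a fitted amplitude
#'
#' Inverts the amplitude relation of each model at a known concentration:
#' conventional FCS `Veff = 1/(G0 C)`; 3D NIFS `Veff = 1/(2 G0 C)`; 2D NIFS
#' `Aeff = 1/(G0 C)`.  Also reports the mean number of molecules
#' `N = Veff C` (or `Aeff C`).
#'
#' @param fit An `fcs_fit`.
#' @param concentration Mean concentration (m^-3, or m^-2 for 2D).
#' @return Named list with `Veff` (m^3) or `Aeff` (m^2), `N` and `C`.
#' @export
derive_quantities <- function(fit, concentration) {
  stopifnot(inherits(fit, "fcs_fit"), concentration > 0)
  G0 <- fit$par[["G0"]]
  if (!is.finite(G0) || G0 <= 0) stop("fitted amplitude G0 must be positive")
  switch(fit$model,
         fcs3d = {
           V <- 1 / (G0 * concentration)
           list(Veff = V, N = V * concentration, C = concentration)
         },
         nifs3d = {
           V <- 1 / (2 * G0 * concentration)
           list(Veff = V, N = V * concentration, C = concentration)
         },
         nifs2d = {
           A <- 1 / (G0 * concentration)
           list(Aeff = A, N = A * concentration, C = concentration)
         })
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS model fit: %s (%s weights)%s\n", x$model, x$weights,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- format(signif(x$par, 4))
  se <- ifelse(is.finite(x$se), paste0(" +/- ", signif(x$se, 2)), "")
  fixed_tag <- ifelse(names(x$par) %in% names(x$fixed), " (fixed)", "")
  cat(paste0("  ", format(names(x$par), width = 6), " ", est, se, fixed_tag,
             collapse = "\n"), "\n")
  if (!is.null(x$tau_crit))
    cat(sprintf("  tau_crit %.4g s (branch crossover)\n", x$tau_crit))
  if (!is.null(x$finite_size))
    cat(sprintf("  finite-size offset %.3g subtracted (T = %.3g s%s)\n",
                x$offset, x$finite_size$T,
                if (is.null(x$finite_size$N)) "" else
                  sprintf(", N = %g", x$finite_size$N)))
  cat(sprintf("  reduced chi-square %.3g on %d dof\n", x$chisq_red, x$dof))
  if (!is.null(x$derived)) {
    d <- x$derived
    if (!is.null(d$Veff))
      cat(sprintf("  Veff = %.4g m^3 (%.4g fL, %.4g zL), N = %.4g\n",
                  d$Veff, d$Veff / M3_PER_FL, d$Veff / M3_PER_ZL, d$N))
    else
      cat(sprintf("  Aeff = %.4g m^2 (%.4g um^2), N = %.4g\n",
                  d$Aeff, d$Aeff / M2_PER_UM2, d$N))
  }
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$par,
                    std_error = object$se,
                    fixed = names(object$par) %in% names(object$fixed))
  structure(list(model = object$model, coefficients = tab,
                 chisq_red = object$chisq_red, dof = object$dof,
                 tau_crit = object$tau_crit, derived = object$derived,
                 converged = object$converged),
            class = "summary.fcs_fit")
}

#' @export
print.summary.fcs_fit <- function(x, ...) {
  cat("Model:", x$model, if (!x$converged) "[NOT CONVERGED]", "\n")
  print(x$coefficients)
  cat(sprintf("Reduced chi-square: %.3g on %d dof\n", x$chisq_red, x$dof))
  if (!is.null(x$tau_crit)) cat(sprintf("tau_crit: %.4g s\n", x$tau_crit))
  if (!is.null(x$derived)) str(x$derived, give.attr = FALSE)
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) object$par

#' @export
vcov.fcs_fit <- function(object, ...) object$vcov

#' @export
fitted.fcs_fit <- function(object, ...) object$fitted

#' @rdname fcs_fit
#' @param object,x An `fcs_fit`.
#' @param newdata Optional vector of lag times at which to evaluate the
#'   fitted model (default: the fitted lags).  Predictions are the ideal
#'   (infinite-trace) model; the finite-size offset that was subtracted
#'   during fitting, if any, is in `$offset`.
#' @param ... Unused.
#' @export
predict.fcs_fit <- function(object, newdata = NULL, ...) {
  tau <- newdata %||% object$curve$lag[object$used]
  eval_model(object$model, tau, object$par, object$tau_crit)
}

#' @export
residuals.fcs_fit <- function(object, type = c("normalized", "raw"), ...) {
  type <- match.arg(type)
  if (type == "normalized") object$norm_resid
  else object$curve$G[object$used] - object$fitted
}

#' @rdname fcs_fit
#' @export
plot.fcs_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  cv <- x$curve[x$used, , drop = FALSE]
  plot(cv$lag, cv$G, log = "x", xlab = "", ylab = expression(G(tau)), ...)
  tt <- exp(seq(log(min(cv$lag)), log(max(cv$lag)), length.out = 300))
  lines(tt, predict(x, tt), col = 2, lwd = 2)
  if (x$model == "nifs2d") {
    lines(tt, acf_nifs2d_small(tt, x$par[["G0"]], x$par[["tauD"]]),
          col = 4, lty = 3)
    lines(tt, acf_nifs2d_large(tt, x$par[["G0"]], x$par[["tauD"]],
                               x$par[["tauC"]]), col = 3, lty = 2)
    abline(v = x$tau_crit, col = "grey", lty = 2)
  }
  plot(cv$lag, x$norm_resid, log = "x", xlab = expression(tau ~ "(s)"),
       ylab = "residual / sd", pch = 20)
  abline(h = 0, col = "grey")
  invisible(x)
}
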