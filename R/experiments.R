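## Config-driven end-to-end experiments: simulate -> correlate -> fit ->
## compare recovered parameters against the analytic inputs.

#' Built-in simulated-experiment specifications
#'
#' Three standard in-silico experiments, one per illumination scenario:
#'
#' * `"fcs3d"` — conventional confocal FCS: Gaussian-ellipsoid focus
#'   (`r0 = 0.708` um, `kappa = 3`), 1000 fluorophores in a 1000-fL box
#'   (1 particle/fL), `D` of 3e-11 and 3e-10 m^2/s.
#' * `"nifs3d"` — near-field illumination above the waveguide
#'   (`r0 = 60` nm, `z0 = 12` nm, reflecting exit plane), 1000 fluorophores
#'   in a 2-fL box, `D` of 1e-13, 3e-13 and 1e-12 m^2/s.
#' * `"nifs2d"` — membrane plane at z = 2.3 nm under the annular rim profile
#'   (`a0 = 20` nm, `b0 = 8` nm), 400 fluorophores on 4 um^2, same `D` set.
#'
#' Full scale means 1e7 steps of 100 ns and 20 runs per diffusion constant;
#' `scale` shrinks steps and runs proportionally (floors: 1e5 steps,
#' 4 runs).  `n_particles` may be reduced for desk-scale work; the box is
#' then shrunk to preserve the concentration (keeping the lateral extent at
#' least 10 lateral profile widths).
#'
#' @param experiment `"fcs3d"`, `"nifs3d"` or `"nifs2d"`.
#' @param D Diffusion constants (m^2/s); defaults per experiment.
#' @param scale Desk-scale factor in (0, 1].
#' @param seed Base RNG seed.
#' @param n_particles Override of the fluorophore count (concentration
#'   preserved).
#' @param n_steps,n_runs Optional overrides of the full-scale step and run
#'   counts (applied before `scale`).
#' @param target_rate Photon count-rate target (photons/s) for brightness
#'   calibration; capped at what the Bernoulli emission cap allows.
#' @param fit_fixed Parameters held fixed in the model fit: a named vector,
#'   or a function of `(D, profile)` returning one, or `NULL` to fit
#'   everything.  Defaults pin the parameters that are set by the known
#'   illumination geometry and are nearly degenerate with `tauD` over
#'   desk-scale lag ranges: `kappa = 3` for the conventional experiment and
#'   `tauZ = z0^2/(4 D)` for the 3D near-field experiment.  The membrane
#'   experiment fits all of `G0`, `tauD`, `tauC`.
#' @return An object of class `experiment_spec`.
#' @seealso [run_experiment()], [input_parameter_table()]
#' @export
experiment_spec <- function(experiment = c("fcs3d", "nifs3d", "nifs2d"),
                            D = NULL, scale = 1, seed = 1,
                            n_particles = NULL, n_steps = 1e7, n_runs = 20,
                            target_rate = 1e5,
                            fit_fixed = switch(match.arg(experiment),
                              fcs3d = c(kappa = 3),
                              nifs3d = function(D, profile)
                                c(tauZ = profile$z0^2 / (4 * D)),
                              nifs2d = NULL)) {
  experiment <- match.arg(experiment)
  stopifnot(scale > 0, scale <= 1, target_rate > 0)
  def <- switch(experiment,
                fcs3d = list(D = c(3e-11, 3e-10),
                             profile = profile_gaussian3d(0.708e-6, kappa = 3),
                             n = 1000L,
                             conc = 1 / M3_PER_FL,      # 1 per fL
                             mode = "3d", lat_scale = 0.708e-6),
                nifs3d = list(D = c(1e-13, 3e-13, 1e-12),
                              profile = profile_nifs3d(60e-9, 12e-9),
                              n = 1000L,
                              conc = 500 / M3_PER_FL,   # 1000 per 2 fL
                              mode = "3d", lat_scale = 60e-9),
                nifs2d = list(D = c(1e-13, 3e-13, 1e-12),
                              profile = profile_annular(20e-9, 8e-9),
                              n = 400L,
                              conc = 100 / 1e-12,       # 100 per um^2
                              mode = "2d", lat_scale = 44e-9))
  D <- D %||% def$D
  stopifnot(all(D > 0))
  n <- as.integer(n_particles %||% def$n)
  ## Prefer a cube (square in 2D): lateral truncation of the profiles is
  ## negligible beyond ~4 lateral widths, while squeezing the axial extent
  ## to buy lateral room truncates the Gaussian focus and inflates the
  ## amplitude.  The lateral floor only binds for very small particle
  ## counts.
  if (def$mode == "2d") {
    A <- n / def$conc
    L <- max(sqrt(A), 8 * def$lat_scale)
    box <- c(L, A / L)
  } else {
    V <- n / def$conc
    L <- max(V^(1 / 3), 8 * def$lat_scale)
    box <- c(L, L, V / L^2)
  }
  ax <- switch(experiment, fcs3d = 2.5 * def$profile$z0,
               nifs3d = 10 * def$profile$z0, 0)
  if (def$mode == "3d" && box[3] < ax)
    warning("axial box extent (", signif(box[3] * 1e6, 3), " um) truncates ",
            "the illumination profile; increase n_particles to keep the ",
            "box closer to a cube")
  structure(list(experiment = experiment, D = D, scale = scale, seed = seed,
                 profile = def$profile, n_particles = n, box = box,
                 mode = def$mode, concentration = def$conc,
                 n_steps = n_steps, n_runs = n_runs,
                 target_rate = target_rate, fit_fixed = fit_fixed),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec: %s>\n", x$experiment))
  cat(sprintf("  D          %s m^2/s\n", paste(x$D, collapse = ", ")))
  cat(sprintf("  particles  %d, box %s um, concentration %.3g\n",
              x$n_particles, paste(signif(x$box * 1e6, 4), collapse = " x "),
              x$concentration))
  cat(sprintf("  scale      %g (%g steps x %d runs effective)\n", x$scale,
              max(1e5, round(x$n_steps * x$scale)),
              max(4, round(x$n_runs * x$scale))))
  invisible(x)
}

sim_config_for <- function(spec, D, seed) {
  sim_config(spec$profile, box = spec$box, n_particles = spec$n_particles,
             D = D, dt = 1e-7, n_steps = spec$n_steps,
             brightness = 0, n_runs = spec$n_runs, seed = seed,
             mode = spec$mode)
}

#' Analytic input parameters of an experiment
#'
#' The characteristic times and effective sizes implied by each diffusion
#' constant and the profile geometry, with no simulation: the "input" column
#' of the parameter-recovery comparison.
#'
#' @param spec An [experiment_spec()].
#' @return A data frame, one row per diffusion constant, times in ms and
#'   sizes in the natural display unit (fL, zL or um^2; the annular area is
#'   reported under both conventions, see [effective_volume()]).
#' @export
input_parameter_table <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  p <- spec$profile
  rows <- lapply(spec$D, function(D) {
    switch(spec$experiment,
           fcs3d = data.frame(
             D = D,
             tauD_ms = 1e3 * characteristic_times("fcs3d", D, r0 = p$r0)[["tauD"]],
             Veff_fL = effective_volume("fcs3d", r0 = p$r0, z0 = p$z0) / M3_PER_FL),
           nifs3d = {
             ct <- characteristic_times("nifs3d", D, r0 = p$r0, z0 = p$z0)
             data.frame(
               D = D, tauD_ms = 1e3 * ct[["tauD"]], tauZ_ms = 1e3 * ct[["tauZ"]],
               Veff_zL = effective_volume("nifs3d", r0 = p$r0, z0 = p$z0) / M3_PER_ZL)
           },
           nifs2d = {
             ct <- characteristic_times("nifs2d", D, a0 = p$a0, b0 = p$b0)
             data.frame(
               D = D, tauD_ms = 1e3 * ct[["tauD"]], tauC_ms = 1e3 * ct[["tauC"]],
               Aeff_um2 = effective_volume("nifs2d", a0 = p$a0, b0 = p$b0) / M2_PER_UM2,
               Aeff_amplitude_um2 = effective_volume("nifs2d", a0 = p$a0, b0 = p$b0,
                                                     convention = "amplitude") / M2_PER_UM2)
           })
  })
  do.call(rbind, rows)
}

#' Run a full simulated experiment and compare fits with inputs
#'
#' For each diffusion constant: calibrate the brightness to the target count
#' rate (bounded by the Bernoulli cap), simulate `n_runs` traces, estimate
#' and average their autocorrelations, fit the matching model with `1/sd`
#' weights, and derive the effective volume or area from the fitted
#' amplitude at the known concentration.  Fits account for the two known
#' finite-sample offsets of the estimator (finite trace duration, fixed
#' particle number in a closed box; see [fcs_fit()]'s `finite_size`
#' argument), which matter at desk scale and vanish at full scale.
#' Deterministic for a fixed base seed.
#'
#' @param spec An [experiment_spec()].
#' @param out_dir Optional directory; when given, per-D curves
#'   (`curve_<i>.csv`), a comparison table (`comparison.csv`) and fit
#'   summaries (`fits.txt`) are written there.
#' @param verbose Print progress.
#' @return An object of class `nifs_experiment`: list with `comparison`
#'   (data frame of input vs fitted parameters and relative deviations),
#'   `inputs`, `fits`, `curves` and `spec`.
#' @export
run_experiment <- function(spec, out_dir = NULL, verbose = interactive()) {
  stopifnot(inherits(spec, "experiment_spec"))
  inputs <- input_parameter_table(spec)
  model <- spec$experiment
  fits <- list(); curves <- list(); rows <- list()
  for (i in seq_along(spec$D)) {
    D <- spec$D[i]
    if (verbose) message(sprintf("[%s] D = %g m^2/s", model, D))
    cfg <- sim_config_for(spec, D, seed = spec$seed + 1000 * (i - 1))
    rate <- min(spec$target_rate, 0.95 * max_count_rate(cfg))
    cfg$brightness <- calibrate_brightness(cfg, target_rate = rate)
    traces <- run_simulation(cfg, scale = spec$scale)
    eff_steps <- length(traces[[1]])
    lags <- make_lag_grid(cfg$dt, eff_steps)
    curve <- average_curves(lapply(traces, autocorrelate, lags = lags))
    fixed <- if (is.function(spec$fit_fixed))
      spec$fit_fixed(D, spec$profile) else spec$fit_fixed
    fit <- tryCatch(
      fcs_fit(curve, model, weights = "sd", fixed = fixed,
              concentration = spec$concentration,
              finite_size = list(T = eff_steps * cfg$dt,
                                 N = cfg$n_particles)),
      error = function(e) e)
    fits[[i]] <- fit; curves[[i]] <- curve
    if (inherits(fit, "error")) {
      warning(sprintf("fit failed for D = %g: %s", D, conditionMessage(fit)))
      next
    }
    co <- coef(fit)
    row <- data.frame(D = D,
                      tauD_in_ms = inputs$tauD_ms[i],
                      tauD_fit_ms = 1e3 * co[["tauD"]])
    row$tauD_rel_dev <- row$tauD_fit_ms / row$tauD_in_ms - 1
    if (model == "nifs3d") {
      row$tauZ_in_ms <- inputs$tauZ_ms[i]
      row$tauZ_fit_ms <- 1e3 * co[["tauZ"]]
      row$tauZ_rel_dev <- row$tauZ_fit_ms / row$tauZ_in_ms - 1
    }
    if (model == "nifs2d") {
      row$tauC_in_ms <- inputs$tauC_ms[i]
      row$tauC_fit_ms <- 1e3 * co[["tauC"]]
      row$tauC_rel_dev <- row$tauC_fit_ms / row$tauC_in_ms - 1
    }
    if (model %in% c("fcs3d", "nifs3d")) {
      unit <- if (model == "fcs3d") M3_PER_FL else M3_PER_ZL
      row$Veff_in <- if (model == "fcs3d") inputs$Veff_fL[i] else inputs$Veff_zL[i]
      row$Veff_fit <- fit$derived$Veff / unit
      row$Veff_rel_dev <- row$Veff_fit / row$Veff_in - 1
    } else {
      row$Aeff_in_um2 <- inputs$Aeff_um2[i]
      row$Aeff_in_amplitude_um2 <- inputs$Aeff_amplitude_um2[i]
      row$Aeff_fit_um2 <- fit$derived$Aeff / M2_PER_UM2
    }
    row$G0_fit <- co[["G0"]]
    row$count_rate_Hz <- mean(vapply(traces, function(tr)
      mean(tr) / cfg$dt, numeric(1)))
    row$chisq_red <- fit$chisq_red
    rows[[i]] <- row
  }
  comparison <- do.call(rbind, rows)
  out <- structure(list(spec = spec, inputs = inputs,
                        comparison = comparison,
                        fits = fits, curves = curves),
                   class = "nifs_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    write.csv(inputs, file.path(out_dir, "inputs.csv"), row.names = FALSE)
    for (i in seq_along(curves))
      if (!is.null(curves[[i]]))
        write_curve(curves[[i]], file.path(out_dir, sprintf("curve_%d.csv", i)))
    sink(file.path(out_dir, "fits.txt"))
    for (f in fits) if (inherits(f, "fcs_fit")) print(f)
    sink()
  }
  out
}

#' @export
print.nifs_experiment <- function(x, ...) {
  cat(sprintf("Simulated %s experiment (scale %g, seed %g)\n",
              x$spec$experiment, x$spec$scale, x$spec$seed))
  if (is.null(x$comparison)) cat("  (no successful fits)\n")
  else print(format(x$comparison, digits = 3), row.names = FALSE)
  invisible(x)
}
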