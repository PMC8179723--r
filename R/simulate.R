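## Brownian-dynamics Monte Carlo simulation of fluorescence traces.
##
## Three-stage scheme: (1) draw initial particle positions uniformly over the
## box, (2) evolve overdamped Brownian motion (independent Gaussian
## displacements of per-axis variance 2 D dt) with periodic lateral
## boundaries and, for the near-field geometry, a specularly reflecting wall
## at the waveguide exit plane z = 0, (3) let each particle emit a photon
## with probability brightness * W(position) and record counts per time bin.
##
## At the 100 ns default step the solvent's viscous relaxation is long over;
## positional (overdamped) dynamics is statistically equivalent to
## velocity-based schemes and exactly diffusive at every step.

#' Simulation configuration
#'
#' Geometry, particle numbers, dynamics and emission parameters for one
#' simulated FCS experiment.
#'
#' Coordinates: lateral axes span `[-Lx/2, Lx/2] x [-Ly/2, Ly/2]` with the
#' illumination axis at the origin.  With `wall = "reflecting"` (3D NIFS)
#' the axial range is `[0, Lz]` with the waveguide exit plane at z = 0;
#' otherwise z is centred like the lateral axes.  In `mode = "2d"` particles
#' live on the plane `z = z_plane` and only `box[1:2]` are used.
#'
#' @param profile An illumination profile (see [profile_gaussian3d()]).
#' @param box Box edge lengths in metres: `c(Lx, Ly, Lz)` (3D) or
#'   `c(Lx, Ly)` (2D).
#' @param n_particles Number of fluorophores (>= 1).
#' @param D Diffusion constant (m^2/s).
#' @param dt Time step = bin width (s); default 100 ns.
#' @param n_steps Random-walk steps per run; default 1e7.
#' @param brightness Photon emission probability per step for a particle at
#'   the profile peak (W = 1).  Must be <= 0.1 so the per-step Bernoulli
#'   emission stays in the linear (rare-event) regime; see
#'   [calibrate_brightness()].
#' @param n_runs Number of independent repeats (distinct seeds).
#' @param seed Base RNG seed; run `i` uses `seed + i - 1`.
#' @param mode `"3d"` or `"2d"` (membrane plane).
#' @param wall `"periodic"` (all faces periodic; conventional FCS) or
#'   `"reflecting"` (hard wall at z = 0: axial coordinate reversed).
#' @param top For `wall = "reflecting"`: boundary at `z = Lz`, default
#'   `"reflecting"`.  A closed (doubly reflecting) column preserves the
#'   uniform equilibrium exactly.  `"periodic"` re-injection at the bottom
#'   is also available but is *not* detailed-balanced against a reflecting
#'   floor: top-crossers pile onto the wall boundary layer and inflate the
#'   near-field density (by a factor approaching two), so use it only to
#'   study that artefact.
#' @param z_plane Height of the membrane plane in 2D mode (m); default
#'   2.3 nm, just above the waveguide exit surface.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(profile_gaussian3d(0.708e-6, kappa = 3),
#'                   box = rep(10e-6, 3), n_particles = 1000, D = 3e-11,
#'                   brightness = 0.005, n_steps = 1e5, n_runs = 2, seed = 1)
#' @export
sim_config <- function(profile, box, n_particles, D, dt = 1e-7,
                       n_steps = 1e7, brightness = 0.01, n_runs = 20,
                       seed = 1, mode = c("3d", "2d"),
                       wall = if (inherits(profile, "profile_nifs3d"))
                         "reflecting" else "periodic",
                       top = c("reflecting", "periodic"),
                       z_plane = 2.3e-9) {
  mode <- match.arg(mode)
  top <- match.arg(top)
  wall <- match.arg(wall, c("periodic", "reflecting"))
  stopifnot(inherits(profile, "nifs_profile"),
            all(is.finite(box)), all(box > 0),
            length(box) == if (mode == "2d") 2L else 3L,
            n_particles >= 1, n_particles == round(n_particles),
            is.finite(D), D > 0, dt > 0, n_steps >= 1,
            brightness >= 0, n_runs >= 1, is.finite(seed))
  if (brightness > 0.1)
    stop("brightness > 0.1 violates the Bernoulli emission validity cap")
  sigma <- sqrt(2 * D * dt)
  if (6 * sigma > min(box))
    stop("sqrt(2 D dt) is not small compared with the box; ",
         "reduce dt or D or enlarge the box")
  structure(list(profile = profile, box = box, n_particles = as.integer(n_particles),
                 D = D, dt = dt, n_steps = n_steps, brightness = brightness,
                 n_runs = as.integer(n_runs), seed = seed, mode = mode,
                 wall = wall, top = top, z_plane = z_plane),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  profile     %s\n", class(x$profile)[1]))
  cat(sprintf("  mode        %s%s\n", x$mode,
              if (x$mode == "2d") sprintf(" (z = %.3g nm)", x$z_plane * 1e9) else ""))
  cat(sprintf("  box         %s um%s\n",
              paste(signif(x$box * 1e6, 4), collapse = " x "),
              if (x$mode == "2d") " (area)" else ""))
  cat(sprintf("  particles   %d   D = %.3g m^2/s\n", x$n_particles, x$D))
  cat(sprintf("  dt          %.3g s x %g steps x %d runs (seed %g)\n",
              x$dt, x$n_steps, x$n_runs, x$seed))
  cat(sprintf("  brightness  %.4g /step at W=1   wall %s\n",
              x$brightness, x$wall))
  invisible(x)
}

#' Concentration implied by a configuration
#'
#' `n_particles` divided by the box volume (3D, m^-3) or area (2D, m^-2).
#'
#' @param config A [sim_config()].
#' @export
sim_concentration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_particles / prod(config$box)
}

#' Elementary simulation stages
#'
#' The three Monte Carlo stages exposed individually (using R's RNG) for
#' statistical testing; [run_simulation()] runs the same scheme in compiled
#' code.
#'
#' `init_positions()` draws i.i.d. uniform positions over the box;
#' `step_particles()` adds independent Gaussian displacements of per-axis
#' variance `2 D dt`; `apply_boundaries()` wraps or reflects positions back
#' into the box; `emit_photons()` returns the total photon count for one
#' step, each particle emitting independently with probability
#' `brightness * W`.
#'
#' @param config A [sim_config()].
#' @param n Number of particles (defaults to the configured count).
#' @return `init_positions()`: an n-by-3 matrix (in 2D mode column 3 is the
#'   fixed plane height).
#' @export
init_positions <- function(config, n = config$n_particles) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$box
  x <- runif(n, -b[1] / 2, b[1] / 2)
  y <- runif(n, -b[2] / 2, b[2] / 2)
  z <- if (config$mode == "2d") rep(config$z_plane, n)
  else if (config$wall == "reflecting") runif(n, 0, b[3])
  else runif(n, -b[3] / 2, b[3] / 2)
  cbind(x = x, y = y, z = z)
}

#' @rdname init_positions
#' @param positions Matrix of positions (columns = coordinates).
#' @param D,dt Diffusion constant (m^2/s) and time step (s).
#' @return `step_particles()`: the displaced positions.
#' @export
step_particles <- function(positions, D, dt) {
  stopifnot(D >= 0, dt > 0)
  positions + rnorm(length(positions), 0, sqrt(2 * D * dt))
}

#' @rdname init_positions
#' @return `apply_boundaries()`: positions mapped back into the box.
#' @export
apply_boundaries <- function(positions, config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$box
  wrap <- function(v, L) v - L * floor(v / L + 0.5)
  lim <- c(b[1], b[2], if (config$mode == "2d") Inf else b[3])
  if (any(abs(positions) > 1.5 * rep(lim, each = nrow(positions))[
    seq_along(positions)]))
    stop("particle displaced by more than one box length in a single step; ",
         "D, dt and the box size are inconsistent")
  positions[, 1] <- wrap(positions[, 1], b[1])
  positions[, 2] <- wrap(positions[, 2], b[2])
  if (config$mode != "2d") {
    z <- positions[, 3]
    if (config$wall == "reflecting") {
      z <- ifelse(z < 0, -z, z)                       # specular reflection
      z <- ifelse(z > b[3],
                  if (config$top == "reflecting") 2 * b[3] - z else z - b[3],
                  z)
    } else {
      z <- wrap(z, b[3])
    }
    positions[, 3] <- z
  }
  positions
}

#' @rdname init_positions
#' @param profile Illumination profile.
#' @param brightness Peak emission probability per step.
#' @return `emit_photons()`: integer photon count for this step.
#' @export
emit_photons <- function(positions, profile, brightness) {
  stopifnot(brightness >= 0)
  p <- brightness * eval_profile(profile, positions)
  if (any(p > 1)) stop("emission probability exceeds 1")
  sum(runif(nrow(positions)) < p)
}

scale_config <- function(config, scale) {
  stopifnot(scale > 0, scale <= 1)
  if (scale == 1) return(config)
  config$n_steps <- max(min(1e5, config$n_steps), round(config$n_steps * scale))
  config$n_runs <- as.integer(max(min(4L, config$n_runs),
                                  round(config$n_runs * scale)))
  config
}

#' Run a simulated FCS experiment
#'
#' Executes `n_runs` independent simulations (seeds `seed + run - 1`) of the
#' configured scheme in compiled code and returns one binned photon-count
#' trace per run.  A given configuration and seed always reproduces the
#' identical traces: the kernel uses its own xoshiro256++ generator (polar
#' Box-Muller normals), so results do not depend on R's RNG state.
#'
#' @param config A [sim_config()].
#' @param scale Desk-scale factor in (0, 1]: multiplies `n_steps` and
#'   `n_runs` (floors: 1e5 steps, 4 runs) without touching the physics.
#' @return A list of `intensity_trace` objects (integer counts per bin with
#'   attributes `dt`, `seed`, `rng`), with the configuration attached as an
#'   attribute.
#' @export
run_simulation <- function(config, scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  config <- scale_config(config, scale)
  traces <- lapply(seq_len(config$n_runs), function(i)
    run_one(config, config$seed + i - 1))
  attr(traces, "config") <- config
  class(traces) <- "trace_list"
  traces
}

run_one <- function(config, seed, n_steps = config$n_steps,
                    brightness = config$brightness,
                    return_positions = FALSE) {
  p <- config$profile
  pars <- if (inherits(p, "profile_grid"))
    list(x = p$x, y = p$y, z = p$z, values = as.numeric(p$values),
         order = as.integer(p$order))
  else unclass(p)
  res <- .sim_kernel(profile_kernel_id(p), pars, config$mode == "2d",
                     as.numeric(config$box), config$z_plane,
                     config$n_particles, config$D, config$dt, n_steps,
                     brightness, config$wall == "reflecting",
                     config$top == "reflecting", seed, return_positions)
  if (return_positions) return(res)
  structure(res$counts, dt = config$dt, seed = seed,
            rng = "xoshiro256++/polar-BoxMuller", class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace: %g bins of %.3g s, %.4g counts total (%.4g kHz), seed %g\n",
              length(x), attr(x, "dt"), sum(as.numeric(x)),
              mean(x) / attr(x, "dt") / 1e3, attr(x, "seed")))
  invisible(x)
}

## Equilibrium mean of W over the box: the stage-1 pilot behind brightness
## calibration.  The spatial distribution is uniform at equilibrium for
## every boundary variant used here, so sampling initial positions suffices
## and, unlike a short dynamical pilot, is not wrecked by the rare-event
## statistics of nanoscopic profiles (a 2-fL box holds ~0.03 particles
## inside the near field at any instant).
mean_profile_intensity <- function(config, pilot_samples = 4e6) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed((as.numeric(config$seed) + 424243) %% 2^31)
  acc <- 0; m <- 0
  block <- 5e5
  while (m < pilot_samples) {
    k <- min(block, pilot_samples - m)
    acc <- acc + sum(eval_profile(config$profile, init_positions(config, k)))
    m <- m + k
  }
  acc / m
}

#' Calibrate the emission brightness to a target count rate
#'
#' Runs a stage-1 pilot (Monte Carlo sampling of the illumination intensity
#' over the equilibrium particle distribution) and exploits the linearity of
#' Bernoulli emission, `rate = n_particles * brightness * <W> / dt`, to set
#' the brightness so the mean photon count rate matches `target_rate` (to
#' well within 10% at the default pilot size).  Errors when the target would
#' require a peak emission probability above the Bernoulli validity cap.
#'
#' @param config A [sim_config()].
#' @param target_rate Desired mean count rate (photons/s); the conventional
#'   working point is of order 1e5 (100 kHz).
#' @param pilot_samples Position samples in the pilot.
#' @param cap Maximum admissible brightness (default 0.1).
#' @return Calibrated brightness (probability per step at W = 1).
#' @export
calibrate_brightness <- function(config, target_rate = 1e5,
                                 pilot_samples = 4e6, cap = 0.1) {
  stopifnot(inherits(config, "sim_config"), target_rate >= 0)
  if (target_rate == 0) return(0)
  if (target_rate * config$dt >= config$n_particles)
    stop("target rate implies more than one photon per particle per step")
  mw <- mean_profile_intensity(config, pilot_samples)
  if (mw <= 0)
    stop("profile is zero over the box; target rate unreachable")
  b <- target_rate * config$dt / (config$n_particles * mw)
  if (b > cap)
    stop(sprintf(paste0("target rate %.3g /s needs brightness %.3g > cap %.2g ",
                        "(max achievable ~%.3g /s)"),
                 target_rate, b, cap,
                 cap * config$n_particles * mw / config$dt))
  b
}

#' Maximum count rate achievable under the Bernoulli cap
#'
#' @inheritParams calibrate_brightness
#' @return Estimated count rate (photons/s) at `brightness = cap`.
#' @export
max_count_rate <- function(config, pilot_samples = 4e6, cap = 0.1) {
  cap * config$n_particles *
    mean_profile_intensity(config, pilot_samples) / config$dt
}

#' Intensity trace CSV I/O
#'
#' Plain CSV with columns `bin, counts`; the bin width, seed and RNG
#' identifier are stored in `#`-prefixed header comments.
#'
#' @param trace An `intensity_trace`.
#' @param file Path.
#' @export
write_trace <- function(trace, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g seed=%.17g rng=%s",
                     attr(trace, "dt"), attr(trace, "seed"),
                     attr(trace, "rng")), con)
  writeLines("bin,counts", con)
  writeLines(paste(seq_along(trace), as.integer(trace), sep = ","), con)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  hdr <- readLines(file, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  meta <- as.list(sub("^[a-z]+=", "", kv))
  names(meta) <- sub("=.*", "", kv)
  df <- read.csv(file, comment.char = "#")
  structure(as.integer(df$counts), dt = as.numeric(meta$dt),
            seed = as.numeric(meta$seed), rng = meta$rng,
            class = "intensity_trace")
}
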