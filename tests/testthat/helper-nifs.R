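## Shared helpers for the test suite.

## Model curve on a quasi-log lag grid, optionally with i.i.d. Gaussian
## noise and matching per-lag sd (emulating a multi-run average).
model_curve <- function(model, par, lags = NULL, noise = 0, n_runs = 1,
                        dt = 1e-7) {
  if (is.null(lags)) {
    tD <- par[["tauD"]]
    lags <- 10^seq(log10(tD) - 3, log10(tD) + 2, length.out = 60)
  }
  G <- switch(model,
              fcs3d = acf_fcs3d(lags, par[["G0"]], par[["tauD"]], par[["kappa"]]),
              nifs3d = acf_nifs3d(lags, par[["G0"]], par[["tauD"]], par[["tauZ"]]),
              nifs2d = acf_nifs2d(lags, par[["G0"]], par[["tauD"]], par[["tauC"]]))
  sdv <- rep(noise * par[["G0"]], length(lags))
  if (noise > 0) G <- G + rnorm(length(G), 0, sdv)
  nifs:::new_corr_curve(lags, G,
                        sd = if (noise > 0) sdv else rep(NA_real_, length(lags)),
                        n_runs = n_runs, dt = dt)
}

## Tiny conventional-FCS configuration for fast statistical checks.
tiny_fcs_config <- function(n_steps = 1e5, n_particles = 50, n_runs = 2,
                            D = 3e-10, seed = 11, brightness = 0.02) {
  sim_config(profile_gaussian3d(0.708e-6, kappa = 3), box = rep(5e-6, 3),
             n_particles = n_particles, D = D, n_steps = n_steps,
             brightness = brightness, n_runs = n_runs, seed = seed)
}

## Cache for expensive end-to-end pipelines shared between tests.
.pipeline_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .pipeline_cache)) assign(key, force(expr), .pipeline_cache)
  get(key, .pipeline_cache)
}
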