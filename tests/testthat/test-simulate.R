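test_that("configurations are validated", {
  p <- profile_gaussian3d()
  expect_error(sim_config(p, rep(10e-6, 3), n_particles = 0, D = 1e-11),
               "n_particles")
  expect_error(sim_config(p, rep(10e-6, 3), 10, D = 1e-11, brightness = 0.5),
               "Bernoulli")
  # a step comparable to the box flags an inconsistent dt/D/box choice
  expect_error(sim_config(p, rep(50e-9, 3), 10, D = 1e-9, dt = 1e-3),
               "box")
  expect_error(sim_config(p, c(10e-6, 10e-6), 10, D = 1e-11), "box")
})

test_that("initial positions are uniform over the box", {
  cfg <- tiny_fcs_config()
  set.seed(19)
  pos <- init_positions(cfg, n = 1e5)
  expect_true(all(abs(pos[, 1]) <= cfg$box[1] / 2))
  expect_true(all(abs(pos[, 3]) <= cfg$box[3] / 2))
  for (j in 1:3) {
    ks <- suppressWarnings(
      ks.test(pos[, j], "punif", -cfg$box[j] / 2, cfg$box[j] / 2))
    expect_gt(ks$p.value, 0.01)
  }
  # reflecting-wall geometry starts in [0, Lz]
  cfg2 <- sim_config(profile_nifs3d(), box = rep(0.8e-6, 3), n_particles = 10,
                     D = 1e-13, brightness = 0.05, seed = 1)
  z <- init_positions(cfg2, 1e4)[, 3]
  expect_true(all(z >= 0 & z <= cfg2$box[3]))
})

test_that("displacements follow the overdamped contract var = 2 D dt", {
  D <- 3e-11; dt <- 1e-7
  set.seed(8)
  pos <- matrix(0, 3.3e5, 3)
  d <- step_particles(pos, D, dt) - pos
  target <- sqrt(2 * D * dt)   # 2.449 nm at these parameters
  expect_equal(target, 2.449e-9, tolerance = 1e-3)
  for (j in 1:3) {
    se <- target / sqrt(2 * nrow(pos))
    expect_lt(abs(sd(d[, j]) - target), 3 * se)
    expect_lt(abs(mean(d[, j])), 3 * target / sqrt(nrow(pos)))
  }
  expect_identical(step_particles(pos, 0, dt), pos)
})

test_that("ensemble MSD grows linearly at slope 2 D per axis", {
  D <- 1e-12; dt <- 1e-7; n <- 100; nsteps <- 1e4
  set.seed(13)
  pos <- matrix(0, n, 3)
  snap_every <- 100L
  msd <- matrix(NA_real_, nsteps / snap_every, 3)
  for (k in seq_len(nsteps)) {
    pos <- step_particles(pos, D, dt)
    if (k %% snap_every == 0) msd[k / snap_every, ] <- colMeans(pos^2)
  }
  t_snap <- seq_len(nrow(msd)) * snap_every * dt
  for (j in 1:3) {
    slope <- sum(msd[, j] * t_snap) / sum(t_snap^2)  # origin-constrained fit
    expect_equal(slope, 2 * D, tolerance = 0.05)
  }
})

test_that("boundary rules wrap laterally and reflect at the exit plane", {
  cfg <- sim_config(profile_nifs3d(), box = c(0.8e-6, 0.8e-6, 0.6e-6),
                    n_particles = 4, D = 1e-13, brightness = 0.05, seed = 1)
  pos <- rbind(c(0.41e-6, 0, -3e-9),         # crossed the exit plane
               c(0, -0.45e-6, 0.55e-6),
               c(0.1e-6, 0.2e-6, 0.605e-6),  # above the top face
               c(0, 0, 1e-9))
  out <- apply_boundaries(pos, cfg)
  expect_equal(out[1, 3], 3e-9)              # specular reflection z -> -z
  expect_equal(out[1, 1], -0.39e-6)          # periodic lateral wrap
  expect_equal(out[2, 2], 0.35e-6)
  expect_equal(out[3, 3], 0.595e-6)          # reflecting top (default)
  expect_equal(out[4, ], pos[4, ])           # interior point untouched
  expect_true(all(out[, 3] >= 0))
  # periodic top re-injection (opt-in)
  cfg$top <- "periodic"
  expect_equal(apply_boundaries(pos, cfg)[3, 3], 0.005e-6)
  # a displacement beyond one box length signals inconsistency
  expect_error(apply_boundaries(rbind(c(2e-6, 0, 1e-9)), cfg), "box length")
})

test_that("reflected Brownian motion equilibrates to a uniform axial density", {
  # run past the axial relaxation time Lz^2/D (~4e3 steps here) so density
  # distortions would have time to develop
  cfg <- sim_config(profile_nifs3d(), box = c(0.8e-6, 0.8e-6, 0.2e-6),
                    n_particles = 2500, D = 1e-10, dt = 1e-7,
                    brightness = 0.05, seed = 1)
  set.seed(17)
  pos <- init_positions(cfg)
  ever_below <- FALSE
  for (k in 1:9000) {
    pos <- apply_boundaries(step_particles(pos, cfg$D, cfg$dt), cfg)
    ever_below <- ever_below || any(pos[, 3] < 0)
  }
  expect_false(ever_below)
  h <- table(cut(pos[, 3], seq(0, cfg$box[3], length.out = 11)))
  chi <- chisq.test(as.numeric(h))
  expect_gt(chi$p.value, 0.01)
})

test_that("photon emission is Bernoulli thinning of the local intensity", {
  p <- profile_gaussian3d()
  peak <- matrix(0, 1, 3)
  expect_identical(emit_photons(peak, p, 0), 0L)
  expect_error(emit_photons(peak, p, 1.5), "exceeds 1")

  # single stationary particle at the peak: mean count = brightness
  set.seed(3)
  n <- 2e5; b <- 0.01
  counts <- vapply(seq_len(n), function(i) emit_photons(peak, p, b),
                   integer(1))
  expect_lt(abs(mean(counts) - b), 3 * sqrt(b * (1 - b) / n))

  # below the waveguide exit plane nothing is excited
  below <- matrix(c(0, 0, -1e-9), 1)
  tot <- sum(vapply(1:200, function(i)
    emit_photons(below, profile_nifs3d(), 0.1), integer(1)))
  expect_identical(tot, 0L)
})

test_that("counts at fixed positions are binomial", {
  # 50 particles pinned at the peak: counts ~ Binomial(50, b)
  p <- profile_gaussian3d()
  pos <- matrix(0, 50, 3)
  b <- 0.05
  set.seed(23)
  counts <- vapply(seq_len(2e4), function(i) emit_photons(pos, p, b),
                   integer(1))
  ex <- dbinom(0:12, 50, b) * length(counts)
  obs <- tabulate(pmin(counts, 12) + 1L, 13)
  keep <- ex > 5
  chi <- sum((obs[keep] - ex[keep])^2 / ex[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("compiled kernel is deterministic and matches the analytic rate", {
  cfg <- tiny_fcs_config(n_steps = 4e5, n_particles = 100, n_runs = 2)
  cfg$brightness <- calibrate_brightness(cfg, target_rate = 1e5)
  traces <- run_simulation(cfg)
  expect_length(traces, 2)
  expect_length(traces[[1]], 4e5)
  expect_true(all(traces[[1]] >= 0))
  # distinct seeds give distinct traces; same seed reproduces bit-identically
  expect_false(identical(as.integer(traces[[1]]), as.integer(traces[[2]])))
  again <- run_simulation(cfg)
  expect_identical(as.integer(traces[[1]]), as.integer(again[[1]]))
  expect_identical(as.integer(traces[[2]]), as.integer(again[[2]]))
  # calibrated rate achieved within 10%
  rate <- mean(vapply(traces, function(tr) mean(tr) / cfg$dt, numeric(1)))
  expect_equal(rate, 1e5, tolerance = 0.1)
})

test_that("kernel honours geometry: plane height and reflecting wall", {
  cfg2 <- sim_config(profile_annular(), box = c(1e-6, 1e-6), n_particles = 40,
                     D = 1e-12, n_steps = 2e3, brightness = 0.05,
                     n_runs = 1, seed = 3, mode = "2d", z_plane = 2.3e-9)
  res <- nifs:::run_one(cfg2, seed = 3, return_positions = TRUE)
  expect_true(all(res$positions[, 3] == 2.3e-9))
  expect_true(all(abs(res$positions[, 1]) <= 0.5e-6))

  cfg3 <- sim_config(profile_nifs3d(), box = rep(0.5e-6, 3), n_particles = 50,
                     D = 1e-12, n_steps = 5e3, brightness = 0.05,
                     n_runs = 1, seed = 4)
  expect_identical(cfg3$wall, "reflecting")
  res3 <- nifs:::run_one(cfg3, seed = 4, return_positions = TRUE)
  expect_true(all(res3$positions[, 3] >= 0 &
                    res3$positions[, 3] <= cfg3$box[3]))
})

test_that("brightness calibration is linear and respects the Bernoulli cap", {
  cfg <- tiny_fcs_config()
  expect_identical(calibrate_brightness(cfg, 0), 0)
  b1 <- calibrate_brightness(cfg, 5e4)
  b2 <- calibrate_brightness(cfg, 1e5)
  expect_equal(b2 / b1, 2, tolerance = 1e-10)
  # the nanoscopic near field cannot reach 100 kHz under the cap
  nf <- sim_config(profile_nifs3d(), box = rep(0.794e-6, 3),
                   n_particles = 250, D = 1e-13, brightness = 0, seed = 1)
  expect_error(calibrate_brightness(nf, 1e5), "cap")
  expect_lt(max_count_rate(nf), 1e5)
})

test_that("traces round-trip through CSV with metadata", {
  cfg <- tiny_fcs_config(n_steps = 2e3, n_particles = 20, n_runs = 1)
  tr <- run_simulation(cfg)[[1]]
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_identical(as.integer(tr2), as.integer(tr))
  expect_identical(attr(tr2, "dt"), attr(tr, "dt"))
  expect_identical(attr(tr2, "seed"), attr(tr, "seed"))
  expect_identical(attr(tr2, "rng"), attr(tr, "rng"))
})
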