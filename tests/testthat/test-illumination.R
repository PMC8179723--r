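test_that("profiles are peak-normalised and evaluate their closed forms", {
  g <- profile_gaussian3d(r0 = 0.708e-6, kappa = 3)
  expect_equal(eval_profile(g, c(0, 0, 0)), 1)
  expect_equal(eval_profile(g, c(0.708e-6, 0, 0)), exp(-2))
  expect_equal(eval_profile(g, c(0, 0, 2.124e-6)), exp(-2))

  nf <- profile_nifs3d(r0 = 60e-9, z0 = 12e-9)
  expect_equal(eval_profile(nf, c(0, 0, 1e-15)), 1, tolerance = 1e-6)
  expect_equal(eval_profile(nf, c(0, 0, 12e-9)), exp(-1))
  # the half-space below the waveguide exit is dark
  expect_identical(eval_profile(nf, c(0, 0, -1e-9)), 0)
  expect_identical(eval_profile(nf, c(10e-9, 5e-9, -1e-12)), 0)

  an <- profile_annular(a0 = 20e-9, b0 = 8e-9)
  expect_equal(eval_profile(an, c(20e-9, 0, 0)), 1)
  expect_equal(eval_profile(an, c(0, 20e-9, 5e-9)), 1)  # z ignored
  expect_equal(eval_profile(an, c(0, 0, 0)), exp(-(20 / 8)^2))
})

test_that("profiles are cylindrically symmetric and even where claimed", {
  set.seed(42)
  profiles <- list(profile_gaussian3d(0.5e-6, kappa = 2),
                   profile_nifs3d(), profile_annular())
  for (p in profiles) {
    pos <- cbind(runif(50, -1e-7, 1e-7), runif(50, -1e-7, 1e-7),
                 runif(50, 0, 5e-8))
    rot <- cbind(-pos[, 2], pos[, 1], pos[, 3])   # 90-degree rotation
    expect_equal(eval_profile(p, pos), eval_profile(p, rot))
  }
  g <- profile_gaussian3d(0.5e-6, kappa = 2)
  pos <- cbind(runif(20, -1e-6, 1e-6), runif(20, -1e-6, 1e-6),
               runif(20, -1e-6, 1e-6))
  expect_equal(eval_profile(g, pos), eval_profile(g, -pos))
})

test_that("positions are validated", {
  g <- profile_gaussian3d()
  expect_error(eval_profile(g, c(0, 0, NA)), "non-finite")
  expect_error(eval_profile(g, c(0, Inf, 0)), "non-finite")
  expect_error(eval_profile(g, c(1, 2)), "length 3")
  expect_error(profile_gaussian3d(r0 = -1e-7, z0 = 1e-7))
  expect_error(profile_gaussian3d(0.7e-6, z0 = 1e-6, kappa = 3), "not both")
})

test_that("profile integrals match their closed forms", {
  g <- profile_gaussian3d(r0 = 0.708e-6, kappa = 3)
  expect_equal(as.numeric(profile_integral(g)),
               (pi / 2)^1.5 * g$r0^2 * g$z0, tolerance = 1e-6)
  nf <- profile_nifs3d()
  expect_equal(as.numeric(profile_integral(nf)),
               (pi / 2) * nf$r0^2 * nf$z0, tolerance = 1e-6)
  # annular integral approaches 2 pi^(3/2) a0 b0 as a0/b0 grows
  thin <- profile_annular(a0 = 200e-9, b0 = 2e-9)
  expect_equal(as.numeric(profile_integral(thin)),
               2 * pi^1.5 * thin$a0 * thin$b0, tolerance = 1e-6)
  # and is within a fraction of a percent even at the nanowire geometry
  an <- profile_annular(20e-9, 8e-9)
  expect_equal(as.numeric(profile_integral(an)),
               2 * pi^1.5 * an$a0 * an$b0, tolerance = 1e-3)
  expect_identical(attr(profile_integral(an), "units"), "m^2")
})

test_that("grid profiles reproduce the sampled analytic profile", {
  g <- profile_nifs3d()
  ax <- seq(-150e-9, 150e-9, length.out = 61)
  az <- seq(0, 60e-9, length.out = 41)
  vals <- array(0, c(61, 61, 41))
  for (k in seq_along(az))
    vals[, , k] <- outer(ax, ax, function(x, y)
      eval_profile(g, cbind(x, y, az[k])))
  gp <- profile_grid(ax, ax, az, vals)

  set.seed(7)
  pos <- cbind(runif(300, -120e-9, 120e-9), runif(300, -120e-9, 120e-9),
               runif(300, 1e-9, 50e-9))
  w_true <- eval_profile(g, pos)
  w_grid <- eval_profile(gp, pos)
  expect_lt(sqrt(mean((w_grid - w_true)^2)), 0.01)  # < 1% RMS
  # outside the grid extent the profile is dark
  expect_identical(eval_profile(gp, c(0, 0, 100e-9)), 0)
  expect_identical(eval_profile(gp, c(2e-7, 0, 1e-9)), 0)
  # nearest-neighbour interpolation hits grid nodes exactly
  gp0 <- profile_grid(ax, ax, az, vals, order = 0)
  expect_equal(eval_profile(gp0, c(ax[3], ax[5], az[2])), vals[3, 5, 2])
  # trapezoidal integral close to the analytic volume
  expect_equal(as.numeric(profile_integral(gp)),
               (pi / 2) * g$r0^2 * g$z0, tolerance = 0.02)
})

test_that("grid profile CSV round-trips", {
  ax <- seq(-40e-9, 40e-9, length.out = 9)
  az <- seq(0, 30e-9, length.out = 5)
  vals <- array(runif(9 * 9 * 5), c(9, 9, 5))
  gp <- profile_grid(ax, ax, az, vals)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_grid(gp, f)
  gp2 <- read_profile_grid(f)
  expect_equal(gp2$values, gp$values, tolerance = 1e-10)
  expect_equal(gp2$x, gp$x)
  set.seed(1)
  pos <- cbind(runif(20, -35e-9, 35e-9), runif(20, -35e-9, 35e-9),
               runif(20, 1e-9, 25e-9))
  expect_equal(eval_profile(gp2, pos), eval_profile(gp, pos))
})

test_that("grid profile constructor validates input", {
  ax <- c(0, 1e-9, 2e-9)
  expect_error(profile_grid(ax, ax, ax, array(1, c(3, 3, 2))), "dim")
  expect_error(profile_grid(ax, ax, ax, array(-1, c(3, 3, 3))), ">= 0")
  expect_error(profile_grid(rev(ax), ax, ax, array(1, c(3, 3, 3))),
               "increasing")
  expect_error(profile_grid(ax, ax, ax, array(0, c(3, 3, 3))), "zero")
})
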