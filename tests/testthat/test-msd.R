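test_that("ballistic and noise-only MSD limits are exact", {
  # straight-line motion at speed v: MSD(l) = (v l dt)^2
  v_nm <- 40                     # nm per timestep
  traj <- make_traj(x_nm = v_nm * (1:20), y_nm = rep(0, 20))
  msd <- compute_msd(traj, timestep_us = 500, max_lag = 5)
  expect_equal(msd$msd_um2, (v_nm * (1:5))^2 * 1e-6, tolerance = 1e-12)

  # stationary emitter with isotropic noise sigma: plateau at 4 sigma^2
  sigma <- 30
  traj2 <- withr::with_seed(51, {
    purrr::map_dfr(1:400, function(i) {
      make_traj(rnorm(12, 0, sigma), rnorm(12, 0, sigma), track_id = i)
    })
  })
  msd2 <- compute_msd(traj2, timestep_us = 500, max_lag = 4)
  expect_true(all(abs(msd2$msd_um2 / (4 * sigma^2 * 1e-6) - 1) < 0.05))
})

test_that("an exact linear MSD is fitted to machine precision", {
  t_lag_us <- (1:6) * 307.5
  msd <- tibble::tibble(
    lag = 1:6, t_lag_us = t_lag_us,
    msd_um2 = 4 * 50 * t_lag_us * 1e-6 + 0.01,
    se_um2 = 0, n_pairs = 1000, component = "iso"
  )
  fit <- suppressWarnings(fit_msd(msd, n_points = 4, dimensionality = 2))
  expect_equal(fit$D, 50, tolerance = 1e-12)
  expect_equal(fit$b, 0.01, tolerance = 1e-12)
  # 1D convention halves the slope factor
  fit1 <- suppressWarnings(fit_msd(msd, n_points = 4, dimensionality = 1))
  expect_equal(fit1$D, 100, tolerance = 1e-12)
  expect_error(fit_msd(msd[1:2, ]), "lags")
})

test_that("the intercept carries static error positively, blur negatively", {
  d <- 20; dt <- 500; n <- 2500; len <- 16
  base <- sim_brownian_tracks(n, d, dt, n_timepoints = len,
                              focal_depth_um = Inf, field_um = Inf,
                              start = "first", seed = 52)
  sigma <- 30
  noisy <- withr::with_seed(53, {
    dplyr::mutate(base, x_nm = x_nm + rnorm(dplyr::n(), 0, sigma),
                  y_nm = y_nm + rnorm(dplyr::n(), 0, sigma),
                  skipped = FALSE)
  })
  fitn <- fit_msd(compute_msd(noisy, dt, max_lag = 4))
  expect_equal(fitn$b, 4 * sigma^2 * 1e-6, tolerance = 0.2)
  expect_gt(fitn$b, 0)

  # full-exposure blur (positions averaged over the timestep), no noise
  blurred <- base |>
    dplyr::group_by(track_id) |>
    dplyr::mutate(x_nm = (x_nm + dplyr::lead(x_nm)) / 2,
                  y_nm = (y_nm + dplyr::lead(y_nm)) / 2) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(x_nm)) |>
    dplyr::mutate(skipped = FALSE)
  fitb <- fit_msd(compute_msd(blurred, dt, max_lag = 4))
  expect_lt(fitb$b, 0)
  # slope is unaffected by blur or noise (within sampling error)
  expect_equal(fitb$D, d, tolerance = 0.05)
  expect_equal(fitn$D, d, tolerance = 0.05)
})

test_that("per-track apparent D recovers generating coefficients", {
  # exact synthetic MSD track: linear displacements scaled for D = 10
  dt <- 500
  d_true <- 10
  step <- sqrt(2 * d_true * dt * 1e-6) * 1000
  traj <- withr::with_seed(54, {
    purrr::map_dfr(1:600, function(i) {
      make_traj(cumsum(rnorm(20, 0, step)), cumsum(rnorm(20, 0, step)),
                track_id = i)
    })
  })
  pt <- apparent_d(traj, dt, min_length = 12)
  expect_equal(nrow(pt), 600L)
  expect_lt(abs(median(pt$D_um2s) / d_true - 1), 0.15)

  # a mixture of slow and fast molecules separates into two modes
  slow <- sqrt(2 * 5 * dt * 1e-6) * 1000
  fast <- sqrt(2 * 150 * dt * 1e-6) * 1000
  mix <- withr::with_seed(55, {
    dplyr::bind_rows(
      purrr::map_dfr(1:300, function(i) {
        make_traj(cumsum(rnorm(20, 0, slow)), cumsum(rnorm(20, 0, slow)),
                  track_id = i)
      }),
      purrr::map_dfr(301:600, function(i) {
        make_traj(cumsum(rnorm(20, 0, fast)), cumsum(rnorm(20, 0, fast)),
                  track_id = i)
      })
    )
  })
  pm <- apparent_d(mix, dt, min_length = 12)
  lo <- pm$D_um2s[pm$track_id <= 300]
  hi <- pm$D_um2s[pm$track_id > 300]
  cut <- 40   # between the generating values 5 and 150
  expect_gt(mean(lo < cut), 0.9)
  expect_gt(mean(hi > cut), 0.9)

  # short tracks are excluded, not an error
  short <- make_traj(1:5, 1:5)
  expect_equal(nrow(apparent_d(short, dt, min_length = 12)), 0L)
})

test_that("principal direction averages bidirectional displacements", {
  # all displacements along +/- x: orientation 0 (mod pi)
  pd <- principal_direction(c(5, -3, 8, -2), c(0, 0, 0, 0))
  expect_equal(pd$theta %% pi, 0, tolerance = 1e-12)
  expect_true(pd$defined)
  # antiparallel pair at +45 and -135 degrees: orientation 45 degrees
  pd2 <- principal_direction(c(1, -1), c(1, -1))
  expect_equal(pd2$theta, pi / 4, tolerance = 1e-12)
  # isotropic displacements: resultant near zero, flagged undefined
  iso <- withr::with_seed(56, {
    phi <- runif(4000, 0, 2 * pi)
    principal_direction(cos(phi), sin(phi))
  })
  expect_lt(iso$resultant, 0.1)
  expect_false(iso$defined)
  expect_false(principal_direction(numeric(), numeric())$defined)
})

test_that("MSD decomposition satisfies the sum identity exactly", {
  disp <- withr::with_seed(57, {
    traj <- purrr::map_dfr(1:50, function(i) {
      make_traj(cumsum(rnorm(15, 0, 50)), cumsum(rnorm(15, 0, 120)),
                track_id = i)
    })
    compute_displacements(traj, 1:4)
  })
  theta <- 0.7
  comp <- decompose_msd(disp, theta, 500)
  msd_iso <- tapply((disp$dx_nm^2 + disp$dy_nm^2) * 1e-6, disp$lag, mean)
  sums <- tapply(comp$msd_um2, comp$lag, sum)
  expect_equal(unname(sums), unname(msd_iso), tolerance = 1e-12)

  # isotropic data: components share the total about equally
  par <- comp$msd_um2[comp$component == "par"]
  perp <- comp$msd_um2[comp$component == "perp"]
  expect_true(all(abs(par / (par + perp) - 0.5) < 0.25))
})

test_that("tube fixtures separate into linear parallel and flat perpendicular", {
  trk <- sim_tube_tracks(300, 8.7, 500, tube_width_nm = 100,
                         tube_axis_deg = 30, n_timepoints = 40, seed = 58)
  disp <- compute_displacements(trk, 1:6)
  d4 <- disp[disp$lag == 4, ]
  pd <- principal_direction(d4$dx_nm, d4$dy_nm)
  expect_true(pd$defined)
  expect_equal(pd$theta, 30 * pi / 180, tolerance = 0.03)
  comp <- decompose_msd(disp, pd$theta, 500)
  par <- comp[comp$component == "par", ]
  perp <- comp[comp$component == "perp", ]
  # parallel component grows linearly: R^2 of a linear fit ~ 1
  expect_gt(summary(lm(par$msd_um2 ~ par$t_lag_us))$r.squared, 0.995)
  # perpendicular component is flat at the confinement plateau
  expect_lt(max(perp$msd_um2[3:6]) - min(perp$msd_um2[3:6]),
            0.1 * mean(perp$msd_um2[3:6]))
  fitp <- fit_msd(par, n_points = 4, dimensionality = 1)
  expect_equal(fitp$D, 8.7, tolerance = 0.1)
})

test_that("power-law fitting recovers exponents", {
  t_lag_us <- (1:6) * 500
  t_s <- t_lag_us * 1e-6
  mk <- function(K, alpha, b) {
    tibble::tibble(lag = 1:6, t_lag_us = t_lag_us,
                   msd_um2 = 2 * K * t_s^alpha + b,
                   se_um2 = 0, n_pairs = 1000, component = "par")
  }
  # the full nonlinear fit is exact on exact power-law input
  fit <- fit_msd(mk(5, 1.5, 0.002), model = "powerlaw", method = "nls",
                 dimensionality = 1)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-6)
  expect_equal(fit$K, 5, tolerance = 1e-6)
  expect_equal(fit$b, 0.002, tolerance = 1e-8)

  # the two-step procedure is exact for normal diffusion
  fit1 <- suppressWarnings(
    fit_msd(mk(5, 1, 0.002), model = "powerlaw", method = "two_step",
            dimensionality = 1)
  )
  expect_equal(fit1$alpha, 1, tolerance = 1e-9)
  expect_equal(fit1$K, 5, tolerance = 1e-9)
  expect_equal(fit1$b, 0.002, tolerance = 1e-12)

  # for alpha != 1 the two-point intercept biases the two-step exponent
  # toward 1 (a known limitation of the procedure)
  fit2 <- suppressWarnings(
    fit_msd(mk(5, 1.5, 0.002), model = "powerlaw", method = "two_step",
            dimensionality = 1)
  )
  expect_gt(fit2$alpha, 1.05)
  expect_lt(fit2$alpha, 1.5)
})

test_that("pooled D with bootstrap CI matches trajectory-level simulation", {
  d <- 378; dt <- 57.5
  step <- sqrt(2 * d * dt * 1e-6) * 1000
  traj <- withr::with_seed(59, {
    purrr::map_dfr(1:800, function(i) {
      make_traj(cumsum(rnorm(10, 0, step)), cumsum(rnorm(10, 0, step)),
                track_id = i)
    })
  })
  est <- estimate_d(traj, dt, n_boot = 100, seed = 60)
  expect_lt(abs(est$D / d - 1), 0.05)
  expect_true(est$ci_D[1] < d && d < est$ci_D[2])
})
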