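test_that("FRET efficiency and classification follow the definitions", {
  expect_equal(fret_efficiency(100, 100), 0.5)
  expect_equal(fret_efficiency(0, 80), 1)
  expect_equal(fret_efficiency(80, 0), 0)
  expect_true(is.na(fret_efficiency(0, 0)))
  expect_equal(classify_fret(c(0.9, 0.2, 0.5, NA)),
               c("closed", "open", "excluded", "skipped"))
  # boundary values are excluded, not classified
  expect_equal(classify_fret(c(0.65, 0.45)), c("excluded", "excluded"))
})

test_that("shot-noise traces classify to the generating states", {
  tr <- sim_fret_traces(300, 150, 250, dt_us = 812.5, E_closed = 0.8,
                        E_open = 0.2, n_timepoints = 13, photon_rate = 400,
                        noise = "poisson", seed = 71)
  tr$state <- classify_fret(tr$E)
  cls <- tr[tr$state %in% c("closed", "open"), ]
  agree <- mean((cls$state == "closed") == (cls$state_true == "closed"))
  expect_gte(agree, 0.95)
})

test_that("channel pairing is the identity on identical channels", {
  locs <- tibble::tibble(frame = 1L, x_px = c(10, 40, 80),
                         y_px = c(20, 50, 90), photons = c(100, 200, 300),
                         precision_nm = 25)
  paired <- pair_channels(locs, locs, radius_px = 2)
  expect_equal(nrow(paired), 3L)
  expect_true(all(paired$channel == "both"))
  expect_equal(paired$I_D, paired$I_A)
  expect_equal(sort(paired$photons), sort(2 * locs$photons))
  expect_equal(sort(paired$x_px), sort(locs$x_px))
})

test_that("single-channel detections are kept with zero partner intensity", {
  donor <- tibble::tibble(frame = 1L, x_px = c(10, 40), y_px = c(20, 50),
                          photons = c(100, 150), precision_nm = 25)
  acceptor <- tibble::tibble(frame = 1L, x_px = 10.3, y_px = 20.2,
                             photons = 80, precision_nm = 25)
  paired <- pair_channels(donor, acceptor, radius_px = 2)
  expect_equal(nrow(paired), 2L)
  both <- paired[paired$channel == "both", ]
  expect_equal(both$I_A, 80)
  donly <- paired[paired$channel == "donor", ]
  expect_equal(donly$I_A, 0)
  # a donor-only molecule keeps E ~ 0 throughout its trace
  expect_equal(fret_efficiency(donly$I_D, donly$I_A), 0)
})

test_that("a known affine channel offset is corrected by the mapping", {
  donor <- tibble::tibble(frame = 1L, x_px = c(10, 40, 70),
                          y_px = c(20, 50, 80), photons = 100,
                          precision_nm = 25)
  shift <- function(x, y) list(x - 3.5, y + 2.0)   # acceptor -> donor frame
  acceptor <- dplyr::mutate(donor, x_px = x_px + 3.5, y_px = y_px - 2.0,
                            photons = 60)
  bad <- pair_channels(donor, acceptor, radius_px = 1)
  expect_equal(sum(bad$channel == "both"), 0L)
  good <- pair_channels(donor, acceptor, radius_px = 1, mapping = shift)
  expect_equal(sum(good$channel == "both"), 3L)
})

test_that("P_cc starts at 1 and matches the two-state closed form", {
  # all-closed traces: P_cc identically 1
  allc <- tidyr::expand_grid(track_id = 1:20, timepoint = 1:10)
  allc$state <- "closed"
  pcc0 <- fret_pcc(allc, 500, max_lag = 5, n_boot = 0)
  expect_equal(pcc0$p_cc, rep(1, 6))

  ko <- 200; kc <- 300; dt <- 812.5
  st <- sim_two_state(2500, ko, kc, dt_us = dt, n_timepoints = 25, seed = 72)
  pcc <- fret_pcc(st, dt, max_lag = 8, n_boot = 80, seed = 73)
  expect_equal(pcc$p_cc[pcc$lag == 0], 1)
  keff <- ko + kc; fc <- kc / keff
  pred <- fc + (1 - fc) * exp(-keff * pcc$t_lag_us * 1e-6)
  dev <- abs(pcc$p_cc - pred)[pcc$lag > 0]
  se <- pcc$se[pcc$lag > 0]
  expect_true(all(dev < 4 * se))

  # excluded/skipped timepoints enter neither numerator nor denominator
  st2 <- st
  st2$state[seq(1, nrow(st2), by = 7)] <- "excluded"
  pcc2 <- fret_pcc(st2, dt, max_lag = 4, n_boot = 0)
  expect_equal(pcc2$p_cc[1], 1)
})

test_that("an exact P_cc curve is fitted to machine precision", {
  keff <- 500; fc <- 0.6; dt <- 812.5
  t_us <- (0:9) * dt
  pcc <- tibble::new_tibble(
    tibble::tibble(lag = 0:9, t_lag_us = t_us,
                   p_cc = (1 - fc) * exp(-keff * t_us * 1e-6) + fc,
                   se = 0.01, n_pairs = 1000),
    timestep_us = dt, class = "pcc_result"
  )
  fit <- fit_fret_kinetics(pcc)
  expect_equal(fit$k_eff, keff, tolerance = 1e-6)
  expect_equal(fit$F_c, fc, tolerance = 1e-8)
  expect_equal(fit$k_open, (1 - fc) * keff, tolerance = 1e-5)
  expect_equal(fit$k_close, fc * keff, tolerance = 1e-5)
  # rate identities hold exactly on the fitted outputs
  expect_identical(fit$k_eff, fit$k_open + fit$k_close)
  expect_identical(fit$F_c, fit$k_close / fit$k_eff)
  # a non-decaying curve is flagged
  flat <- pcc
  flat$p_cc <- rep(1, 10)
  expect_warning(f2 <- fit_fret_kinetics(flat), "identified")
  expect_true(f2$flagged)
})

test_that("rates are recovered from simulated intensity traces", {
  ko <- 200; kc <- 300; dt <- 812.5
  tr <- sim_fret_traces(2500, ko, kc, dt_us = dt, E_closed = 0.8,
                        E_open = 0.2, n_timepoints = 13, photon_rate = 400,
                        seed = 74)
  tr$state <- classify_fret(tr$E)
  fit <- fit_fret_kinetics(fret_pcc(tr, dt, max_lag = 8, n_boot = 40,
                                    seed = 75))
  expect_lt(abs(fit$k_open / ko - 1), 0.15)
  expect_lt(abs(fit$k_close / kc - 1), 0.15)

  # opposite rate trends are resolved (ionic-strength-style comparison)
  tr2 <- sim_fret_traces(2500, 120, 380, dt_us = dt, E_closed = 0.8,
                         E_open = 0.2, n_timepoints = 13, photon_rate = 400,
                         seed = 76)
  tr2$state <- classify_fret(tr2$E)
  fit2 <- fit_fret_kinetics(fret_pcc(tr2, dt, max_lag = 8, n_boot = 40,
                                     seed = 77))
  expect_lt(fit2$k_open, fit$k_open)
  expect_gt(fit2$k_close, fit$k_close)
})

test_that("the FRET-diffusivity distribution separates molecular populations", {
  dt <- 307.5
  mk_pop <- function(ids, d, e_mean) {
    step <- sqrt(2 * d * dt * 1e-6) * 1000
    traj <- purrr::map_dfr(ids, function(i) {
      make_traj(cumsum(rnorm(20, 0, step)), cumsum(rnorm(20, 0, step)),
                track_id = i)
    })
    traces <- tidyr::expand_grid(track_id = ids, timepoint = 1:20)
    traces$E <- pmin(pmax(rnorm(nrow(traces), e_mean, 0.05), 0), 1)
    traces$state <- classify_fret(traces$E)
    list(traj = traj, traces = traces)
  }
  withr::with_seed(78, {
    hybridized <- mk_pop(1:150, d = 20, e_mean = 0.85)
    free_strand <- mk_pop(151:300, d = 150, e_mean = 0.15)
    donor_only <- mk_pop(301:380, d = 20, e_mean = 0.02)
  })
  traj <- dplyr::bind_rows(hybridized$traj, free_strand$traj, donor_only$traj)
  traces <- dplyr::bind_rows(hybridized$traces, free_strand$traces,
                             donor_only$traces)
  dist <- fret_d_distribution(traces, traj, dt, min_length = 12)
  expect_gt(nrow(dist), 300)
  hi_e <- dist[dist$mean_E > 0.5, ]
  lo_e_fast <- dist[dist$mean_E < 0.5 & dist$D_um2s > 60, ]
  lo_e_slow <- dist[dist$mean_E < 0.5 & dist$D_um2s < 60, ]
  # three resolvable populations: high-E/low-D, low-E/high-D, low-E/low-D
  expect_gt(nrow(hi_e), 100)
  expect_gt(nrow(lo_e_fast), 100)
  expect_gt(nrow(lo_e_slow), 40)
  expect_lt(median(hi_e$D_um2s), 60)
})
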