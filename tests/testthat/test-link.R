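test_that("search radius follows 2.55 sqrt(4 D' dt)", {
  expect_equal(search_radius(100, 307.5), 894.3, tolerance = 1e-3)
  expect_lt(search_radius(1e-6, 307.5), 1)          # D' -> 0 gives r -> 0
  # typical experiment settings give a radius on the order of 800 nm
  expect_gt(search_radius(80, 307.5), 700)
  expect_lt(search_radius(80, 307.5), 900)
  expect_error(search_radius(0, 300), "d_max")
  expect_error(search_radius(100, 0), "timestep")
})

test_that("a clean streak links into one complete trail", {
  locs <- make_streak_locs(y0 = 100, x0 = 30, slots = rep(TRUE, 6))
  lp <- link_params(90, 307.5)
  tr <- link_trails(locs, lp)
  expect_equal(dplyr::n_distinct(tr$trail_id), 1L)
  expect_equal(sum(tr$detected), 6L)
  expect_equal(sum(!tr$detected), 0L)
  # chip rows strictly increase along the trail
  expect_true(all(diff(tr$y_px) > 0))
})

test_that("a missing detection becomes a flagged skip excluded from MSD", {
  slots <- rep(TRUE, 6); slots[3] <- FALSE
  locs <- make_streak_locs(y0 = 100, x0 = 30, slots = slots)
  lp <- link_params(90, 307.5)
  tr <- link_trails(locs, lp)
  expect_equal(dplyr::n_distinct(tr$trail_id), 1L)
  expect_equal(tr$detected, slots)
  expect_true(is.na(tr$y_px[3]))
  traj <- collapse_trails(tr, lp)
  expect_true(traj$skipped[3])
  disp <- compute_displacements(traj, 1L)
  expect_equal(nrow(disp), 3L)   # pairs (0,1), (3,4), (4,5)
})

test_that("termination, minimum detections and skip domination are enforced", {
  lp <- link_params(90, 307.5)
  # two detections only -> below the 4-detection minimum -> discarded
  locs <- make_streak_locs(100, 30, c(TRUE, TRUE))
  tr <- link_trails(locs, lp)
  expect_equal(nrow(tr), 0L)
  expect_equal(length(attr(tr, "discarded")), 2L)

  # a gap of 3 slots terminates the trail (max_consecutive_skips = 3):
  # the far group is linked as its own trail
  slots <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
             TRUE)
  locs2 <- make_streak_locs(100, 30, slots)
  tr2 <- link_trails(locs2, lp)
  expect_equal(dplyr::n_distinct(tr2$trail_id), 2L)
  expect_true(all(tapply(tr2$detected, tr2$trail_id, function(d) !d[length(d)] == FALSE)))
  # no trailing skips and no skip run of length >= 3 inside
  for (id in unique(tr2$trail_id)) {
    d <- tr2$detected[tr2$trail_id == id]
    expect_true(d[length(d)])
    runs <- rle(!d)
    expect_true(all(runs$lengths[runs$values] < lp$max_consecutive_skips))
  }

  # a trail dominated by skips is discarded
  slots3 <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
              TRUE)
  locs3 <- make_streak_locs(100, 30, slots3)
  tr3 <- link_trails(locs3, lp)
  expect_equal(nrow(tr3), 0L)
})

test_that("every localization ends in exactly one trail or the discard pool", {
  withr::with_seed(21, {
    locs <- tibble::tibble(
      frame = 1L,
      x_px = runif(120, 0, 200),
      y_px = runif(120, 0, 900),
      photons = 300, background = 0.5, sigma_px = 1, precision_nm = 30
    )
  })
  lp <- link_params(90, 307.5)
  tr <- link_trails(locs, lp)
  used <- tr$loc_row[tr$detected]
  disc <- attr(tr, "discarded")
  expect_equal(sort(c(used, disc)), seq_len(nrow(locs)))
  expect_equal(anyDuplicated(used), 0L)
})

test_that("well-separated noiseless streaks are reconstructed perfectly", {
  lp <- link_params(90, 307.5)
  r_px <- lp$search_radius_nm / lp$pixel_nm
  xs <- seq(10, 190, by = 2.5 * r_px)   # lateral separation > 2r
  locs <- purrr::map_dfr(seq_along(xs), function(i) {
    make_streak_locs(y0 = 50 + 7 * i, x0 = xs[i], slots = rep(TRUE, 8))
  })
  tr <- link_trails(locs, lp)
  expect_equal(dplyr::n_distinct(tr$trail_id), length(xs))
  expect_equal(sum(tr$detected), nrow(locs))
  # each trail is one x position (perfect precision and recall)
  per <- tapply(tr$x_px[tr$detected], tr$trail_id[tr$detected],
                function(x) length(unique(x)))
  expect_true(all(per == 1))
})

test_that("collapsing subtracts the executed shifts exactly", {
  lp <- link_params(90, 307.5)
  # stationary emitter: rows y0, y0+15, y0+30 collapse to a single point
  locs <- make_streak_locs(100, 30, rep(TRUE, 4))
  traj <- collapse_trails(link_trails(locs, lp), lp)
  expect_equal(traj$y_nm, rep(0, 4))
  expect_equal(traj$x_nm, rep(0, 4))
  # chip reference keeps the absolute shift-subtracted coordinate
  traj2 <- collapse_trails(link_trails(locs, lp), lp, reference = "chip")
  expect_equal(traj2$y_nm, rep(100 * lp$pixel_nm, 4))

  # a moving emitter's collapsed displacements equal the true ones
  dy <- c(0, 2, -2, 3)   # px jitter about the shifted prediction (within r)
  dx <- c(0, 1, 2, 1)
  locs3 <- make_streak_locs(100, 30, rep(TRUE, 4), dx = dx, dy = dy)
  traj3 <- collapse_trails(link_trails(locs3, lp), lp)
  expect_equal(diff(traj3$y_nm), diff(dy) * lp$pixel_nm)
  expect_equal(diff(traj3$x_nm), diff(dx) * lp$pixel_nm)
})

test_that("ground-truth tracks are recovered faithfully from rendered frames", {
  cfg <- acq_preset("protein-pbs")
  trk <- sim_brownian_tracks(50, 90, cfg$timestep_us, photon_rate = 500,
                             seed = 31)
  lp <- link_params(90, cfg$timestep_us)
  run <- run_tracking_pipeline(trk, cfg, lp, tracks_per_frame = 25, seed = 32)
  truth <- run$truth[!run$truth$truncated, ]
  det <- run$trails[run$trails$detected, ]
  near <- vapply(seq_len(nrow(det)), function(i) {
    f <- run$localizations$frame[det$loc_row[i]]
    cand <- truth[truth$frame == f, ]
    d2 <- (cand$col_px - det$x_px[i])^2 + (cand$row_px - det$y_px[i])^2
    j <- which.min(d2)
    c(cand$track_id[j], sqrt(d2[j]))
  }, numeric(2))
  det$gt <- near[1, ]
  # majority-vote identity per trail; >= 95% of trail detections match it
  maj <- tapply(det$gt, det$trail_id, function(g) max(table(g)) / length(g))
  expect_gte(sum(tapply(det$gt, det$trail_id, function(g) max(table(g)))) /
               nrow(det), 0.95)
  expect_gte(mean(maj), 0.95)
})

test_that("linking stays reliable at the recommended density limit", {
  # ~500 single-molecule images in one readout frame over the chip-wide
  # field of view
  cfg <- acq_preset("protein-pbs")
  trk <- sim_brownian_tracks(90, 90, cfg$timestep_us, photon_rate = 500,
                             field_um = c(78, 34), seed = 33)
  trk$frame <- 1L
  expect_gt(nrow(trk), 450)
  lp <- link_params(90, cfg$timestep_us)
  run <- suppressWarnings(run_tracking_pipeline(trk, cfg, lp, seed = 34))
  truth <- run$truth[!run$truth$truncated, ]
  det <- run$trails[run$trails$detected, ]
  det <- det[order(det$trail_id, det$slot), ]
  det$gt <- vapply(seq_len(nrow(det)), function(i) {
    d2 <- (truth$col_px - det$x_px[i])^2 + (truth$row_px - det$y_px[i])^2
    truth$track_id[which.min(d2)]
  }, numeric(1))
  # mislinking rate = wrong links per linking step (consecutive detections
  # of one trail drawn from different ground-truth molecules)
  per <- split(det$gt, det$trail_id)
  wrong <- sum(vapply(per, function(g) sum(diff(g) != 0), numeric(1)))
  n_links <- sum(vapply(per, function(g) length(g) - 1L, numeric(1)))
  expect_lt(wrong / n_links, 0.05)
})
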