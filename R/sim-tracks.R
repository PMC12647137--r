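#' Simulate Brownian ground-truth tracks
#'
#' Generates 3D Brownian trajectories sampled at the acquisition timestep.
#' Per-axis increments are Gaussian with variance `2 * D * dt`. A track starts
#' at a uniformly random position inside the lateral field and (in depth) the
#' focal slab, and ends when it leaves the focal slab (`|z| > focal_depth/2`,
#' a hard cutoff) or the frame runs out of timepoints. Lateral positions are
#' reflected at the field boundary.
#'
#' @param n_tracks Number of tracks.
#' @param d_um2s Diffusion coefficient (um^2/s), >= 0.
#' @param dt_us Timestep (microseconds).
#' @param n_timepoints Timepoints per frame (tracks cannot outlive the frame).
#' @param focal_depth_um Focal slab thickness (um); `Inf` disables the z exit.
#' @param field_um Lateral field size (um); a scalar for a square field or
#'   `c(x, y)`. Positions are reflected at the field boundaries.
#' @param photon_rate Expected signal photons per exposure per molecule.
#' @param start Start timepoint policy: `"uniform"` draws the entry timepoint
#'   uniformly over the frame (molecules wander into focus at random times);
#'   `"first"` starts every track at timepoint 1.
#' @param seed Optional integer seed; all randomness in the call derives
#'   from it.
#'
#' @return A tibble with one row per live timepoint: `track_id`, `timepoint`
#'   (exposure index within the frame), `t_us`, `x_nm`, `y_nm`, `z_nm`,
#'   `photons`, `state` (`NA` for plain diffusion).
#' @examples
#' trk <- sim_brownian_tracks(5, d_um2s = 90, dt_us = 307.5, seed = 1)
#' head(trk)
#' @export
sim_brownian_tracks <- function(n_tracks, d_um2s, dt_us,
                                n_timepoints = 68L,
                                focal_depth_um = 1,
                                field_um = 35,
                                photon_rate = 250,
                                start = c("uniform", "first"),
                                seed = NULL) {
  check_number(n_tracks, "n_tracks")
  check_number(d_um2s, "d_um2s", allow_zero = TRUE)
  check_number(dt_us, "dt_us")
  start <- match.arg(start)
  n_timepoints <- as.integer(n_timepoints)
  field_nm <- rep_len(field_um * 1000, 2L)   # x, y
  half_depth_nm <- focal_depth_um * 1000 / 2
  step_nm <- sqrt(2 * d_um2s * dt_us * 1e-6) * 1000

  with_seed_maybe(seed, {
    start_tp <- if (start == "uniform") {
      sample.int(n_timepoints, n_tracks, replace = TRUE)
    } else {
      rep(1L, n_tracks)
    }
    max_len <- n_timepoints - start_tp + 1L
    start_at <- function(lo, hi) if (is.finite(lo) && is.finite(hi)) {
      runif(1, lo, hi)
    } else {
      0
    }
    purrr::map_dfr(seq_len(n_tracks), function(i) {
      len <- max_len[i]
      x <- start_at(0, field_nm[1]) +
        c(0, cumsum(rnorm(len - 1L, 0, step_nm)))
      y <- start_at(0, field_nm[2]) +
        c(0, cumsum(rnorm(len - 1L, 0, step_nm)))
      z <- start_at(-half_depth_nm, half_depth_nm) +
        c(0, cumsum(rnorm(len - 1L, 0, step_nm)))
      out <- which(abs(z) > half_depth_nm)
      keep <- if (length(out)) seq_len(out[1] - 1L) else seq_len(len)
      if (!length(keep)) keep <- 1L  # at least the entry point
      tibble::tibble(
        track_id = i,
        timepoint = start_tp[i] + keep - 1L,
        x_nm = reflect_into(x[keep], field_nm[1]),
        y_nm = reflect_into(y[keep], field_nm[2]),
        z_nm = z[keep]
      )
    }) |>
      dplyr::mutate(
        t_us = (.data$timepoint - 1) * dt_us,
        photons = photon_rate,
        state = NA_character_
      ) |>
      dplyr::select("track_id", "timepoint", "t_us", "x_nm", "y_nm", "z_nm",
                    "photons", "state")
  })
}

#' Simulate diffusion confined to a tube
#'
#' Motion is free Brownian along the tube axis and reflected at the walls of
#' a `tube_width_nm`-wide channel perpendicular to it, emulating diffusion in
#' a narrow membrane tubule. At long lags the perpendicular displacement
#' distribution reaches the uniform stationary state, so the perpendicular
#' MSD plateaus at `width^2 / 6`.
#'
#' @inheritParams sim_brownian_tracks
#' @param tube_width_nm Tube lumen width (nm); `Inf` recovers free 2D motion.
#' @param tube_axis_deg Tube axis orientation (degrees from the x axis).
#' @param tube_length_nm Length over which entry points are spread.
#' @param origin_nm Position of the tube entry end, `c(x, y)` in nm.
#' @return A tibble as in [sim_brownian_tracks()] (with `z_nm = 0`).
#' @export
sim_tube_tracks <- function(n_tracks, d_um2s, dt_us,
                            tube_width_nm = 100,
                            tube_axis_deg = 0,
                            tube_length_nm = 10000,
                            n_timepoints = 68L,
                            photon_rate = 250,
                            origin_nm = c(0, 0),
                            seed = NULL) {
  check_number(n_tracks, "n_tracks")
  check_number(d_um2s, "d_um2s", allow_zero = TRUE)
  check_number(dt_us, "dt_us")
  if (!is.numeric(tube_width_nm) || tube_width_nm <= 0) {
    abort("`tube_width_nm` must be > 0 (use Inf for unconfined).")
  }
  n_timepoints <- as.integer(n_timepoints)
  step_nm <- sqrt(2 * d_um2s * dt_us * 1e-6) * 1000
  th <- tube_axis_deg * pi / 180

  with_seed_maybe(seed, {
    purrr::map_dfr(seq_len(n_tracks), function(i) {
      u <- runif(1, 0, tube_length_nm) +
        c(0, cumsum(rnorm(n_timepoints - 1L, 0, step_nm)))
      v0 <- if (is.finite(tube_width_nm)) runif(1, 0, tube_width_nm) else 0
      v <- v0 + c(0, cumsum(rnorm(n_timepoints - 1L, 0, step_nm)))
      v <- reflect_into(v, tube_width_nm)
      if (is.finite(tube_width_nm)) v <- v - tube_width_nm / 2
      tibble::tibble(
        track_id = i,
        timepoint = seq_len(n_timepoints),
        x_nm = origin_nm[1] + u * cos(th) - v * sin(th),
        y_nm = origin_nm[2] + u * sin(th) + v * cos(th)
      )
    }) |>
      dplyr::mutate(
        t_us = (.data$timepoint - 1) * dt_us,
        z_nm = 0,
        photons = photon_rate,
        state = NA_character_
      ) |>
      dplyr::select("track_id", "timepoint", "t_us", "x_nm", "y_nm", "z_nm",
                    "photons", "state")
  })
}

#' Simulate two-state switching sequences
#'
#' States evolve as a continuous-time two-state Markov chain (closed -> open
#' at rate `k_open`, open -> closed at rate `k_close`) with exact exponential
#' waiting times, sampled at the acquisition timestep. The initial state is
#' drawn from the stationary distribution, whose closed fraction is
#' `k_close / (k_open + k_close)`.
#'
#' @param n_traces Number of independent state sequences.
#' @param k_open,k_close Opening and closing rates (1/s), >= 0.
#' @param dt_us Sampling interval (microseconds).
#' @param n_timepoints Samples per sequence (recycled across traces, or a
#'   vector of per-trace lengths).
#' @param seed Optional integer seed.
#' @return A tibble: `track_id`, `timepoint`, `state` (`"closed"`/`"open"`).
#' @export
sim_two_state <- function(n_traces, k_open, k_close, dt_us,
                          n_timepoints = 33L, seed = NULL) {
  check_number(k_open, "k_open", allow_zero = TRUE)
  check_number(k_close, "k_close", allow_zero = TRUE)
  check_number(dt_us, "dt_us")
  lens <- rep_len(as.integer(n_timepoints), n_traces)
  dt_s <- dt_us * 1e-6
  p_closed <- if (k_open + k_close > 0) k_close / (k_open + k_close) else 0.5

  with_seed_maybe(seed, {
    purrr::map_dfr(seq_len(n_traces), function(i) {
      len <- lens[i]
      total_s <- (len - 1L) * dt_s
      closed <- runif(1) < p_closed
      states <- logical(len)
      t_cur <- 0
      k <- 1L
      repeat {
        rate <- if (closed) k_open else k_close
        t_next <- if (rate > 0) t_cur + stats::rexp(1, rate) else Inf
        while (k <= len && (k - 1L) * dt_s < t_next) {
          states[k] <- closed
          k <- k + 1L
        }
        if (k > len || t_next > total_s) {
          while (k <= len) { states[k] <- closed; k <- k + 1L }
          break
        }
        t_cur <- t_next
        closed <- !closed
      }
      tibble::tibble(
        track_id = i,
        timepoint = seq_len(len),
        state = ifelse(states, "closed", "open")
      )
    })
  })
}

#' Simulate FRET-labelled diffusing tracks
#'
#' Combines [sim_brownian_tracks()] motion with [sim_two_state()] switching:
#' each live timepoint carries a conformational state and its true FRET
#' efficiency (`E_closed` when closed, `E_open` when open), which
#' [render_fret_frames()] uses to split the photon budget between the donor
#' and acceptor channels.
#'
#' @inheritParams sim_brownian_tracks
#' @inheritParams sim_two_state
#' @param E_closed,E_open True FRET efficiency in the closed / open state.
#' @return A tibble as [sim_brownian_tracks()] plus `state` and `E_true`.
#' @export
sim_fret_tracks <- function(n_tracks, d_um2s, k_open, k_close, dt_us,
                            E_closed = 0.75, E_open = 0.25,
                            n_timepoints = 68L,
                            focal_depth_um = 1, field_um = 35,
                            photon_rate = 400,
                            start = c("uniform", "first"),
                            seed = NULL) {
  with_seed_maybe(seed, {
    trk <- sim_brownian_tracks(
      n_tracks, d_um2s, dt_us,
      n_timepoints = n_timepoints, focal_depth_um = focal_depth_um,
      field_um = field_um, photon_rate = photon_rate, start = start
    )
    st <- sim_two_state(n_tracks, k_open, k_close, dt_us,
                        n_timepoints = n_timepoints)
    trk |>
      dplyr::select(-"state") |>
      dplyr::left_join(st, by = c("track_id", "timepoint")) |>
      dplyr::mutate(E_true = ifelse(.data$state == "closed", E_closed, E_open))
  })
}

#' Simulate smFRET intensity traces (no imaging)
#'
#' Trace-level generator for kinetics work: two-state switching plus
#' per-timepoint donor/acceptor intensities with detection noise, skipping the
#' imaging pipeline. Intensities are `photons * E` (acceptor) and
#' `photons * (1 - E)` (donor) passed through the EM-CCD noise cascade
#' (`noise = "emccd"`, the default), plain Poisson noise, or no noise.
#'
#' @inheritParams sim_two_state
#' @param E_closed,E_open True FRET efficiency per state.
#' @param photon_rate Expected total photons per timepoint.
#' @param noise `"emccd"`, `"poisson"` or `"none"`.
#' @param em_gain EM gain used for `noise = "emccd"`.
#' @param detect_prob Probability that a timepoint is detected at all;
#'   undetected timepoints are dropped (they become skips downstream).
#' @return A tibble: `track_id`, `timepoint`, `I_D`, `I_A`, `E`,
#'   `state_true`.
#' @export
sim_fret_traces <- function(n_traces, k_open, k_close, dt_us,
                            E_closed = 0.75, E_open = 0.25,
                            n_timepoints = 33L, photon_rate = 400,
                            noise = c("emccd", "poisson", "none"),
                            em_gain = 300, detect_prob = 1,
                            seed = NULL) {
  noise <- match.arg(noise)
  with_seed_maybe(seed, {
    st <- sim_two_state(n_traces, k_open, k_close, dt_us,
                        n_timepoints = n_timepoints)
    e_true <- ifelse(st$state == "closed", E_closed, E_open)
    lam_a <- photon_rate * e_true
    lam_d <- photon_rate * (1 - e_true)
    noisify <- switch(noise,
      none = function(lam) lam,
      poisson = function(lam) rpois(length(lam), lam),
      emccd = function(lam) {
        as.numeric(emccd_noise(lam, em_gain = em_gain, read_noise = 0)) /
          em_gain
      }
    )
    out <- tibble::tibble(
      track_id = st$track_id,
      timepoint = st$timepoint,
      I_D = noisify(lam_d),
      I_A = noisify(lam_a),
      state_true = st$state
    )
    if (detect_prob < 1) {
      out <- out[runif(nrow(out)) < detect_prob, ]
    }
    out$E <- fret_efficiency(out$I_D, out$I_A)
    out
  })
}
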