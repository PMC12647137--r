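#' Apply EM-CCD noise to an expected-photon map
#'
#' Models the EM-CCD detection cascade: Poisson photoelectron statistics,
#' gamma-distributed electron multiplication with mean `em_gain` per electron,
#' and additive Gaussian read noise. The multiplication doubles the shot-noise
#' variance (excess noise factor 2), so the output has mean
#' `em_gain * photons` and variance close to
#' `2 * em_gain^2 * photons + read_noise^2`. At `em_gain = 1` the register is
#' bypassed and the output is purely Poisson.
#'
#' @param photon_map Matrix (or vector) of expected photons per pixel, >= 0.
#' @param em_gain EM gain (>= 1, counts per photoelectron).
#' @param read_noise Read noise sd in counts.
#' @param seed Optional integer seed.
#' @return Integer counts with the same shape as `photon_map`, clamped to
#'   the 16-bit range.
#' @examples
#' x <- emccd_noise(matrix(100, 50, 50), em_gain = 300, read_noise = 30,
#'                  seed = 1)
#' mean(x) / 300  # ~100
#' @export
emccd_noise <- function(photon_map, em_gain = 300, read_noise = 30,
                        seed = NULL) {
  if (any(photon_map < 0, na.rm = TRUE)) abort("`photon_map` must be >= 0.")
  check_number(em_gain, "em_gain")
  if (em_gain < 1) abort("`em_gain` must be >= 1.")
  check_number(read_noise, "read_noise", allow_zero = TRUE)

  with_seed_maybe(seed, {
    n <- rpois(length(photon_map), as.numeric(photon_map))
    out <- numeric(length(n))
    if (em_gain > 1) {
      pos <- n > 0L
      out[pos] <- rgamma(sum(pos), shape = n[pos], scale = em_gain)
    } else {
      out <- as.numeric(n)
    }
    if (read_noise > 0) out <- out + rnorm(length(out), 0, read_noise)
    out <- pmin(pmax(round(out), 0), 65535)
    if (is.matrix(photon_map)) dim(out) <- dim(photon_map)
    storage.mode(out) <- "integer"
    out
  })
}

# Chip-coordinate bookkeeping shared by the renderers: returns the tracks
# tibble with frame assignment and 0-based chip coordinates per exposure,
# plus blur sub-sample positions.
place_tracks <- function(tracks, config, tracks_per_frame) {
  stopifnot(inherits(config, "acq_config"))
  need <- c("track_id", "timepoint", "x_nm", "y_nm", "photons")
  if (!all(need %in% names(tracks))) {
    abort(paste("`tracks` must have columns:", paste(need, collapse = ", ")))
  }
  if (any(tracks$timepoint > config$n_timepoints)) {
    abort("track timepoints exceed `n_timepoints` of the configuration.")
  }
  if (!"frame" %in% names(tracks)) {
    ids <- unique(tracks$track_id)
    tpf <- tracks_per_frame %||% length(ids)
    fmap <- setNames((seq_along(ids) - 1L) %/% tpf + 1L, ids)
    tracks$frame <- unname(fmap[as.character(tracks$track_id)])
  }
  shift_rows <- cum_shift_rows(config)
  tracks$col_px <- tracks$x_nm / config$pixel_nm
  tracks$row_px <- tracks$y_nm / config$pixel_nm + shift_rows[tracks$timepoint]
  tracks$truncated <- tracks$row_px > config$chip_rows - 0.5 |
    tracks$row_px < -0.5
  tracks
}

#' Render tracks into streak frames
#'
#' Produces synthetic readout frames for the exposure--vertical-shift
#' acquisition: at exposure k each live molecule deposits a pixel-integrated
#' Gaussian PSF with its expected photon budget at chip row
#' `true_row + shift_height * (cumulative shift multiples before k)`, so a
#' molecule's successive images appear staggered down the chip. A uniform
#' background of `background_rate` photons per pixel accumulates for every
#' exposure in the frame, then the EM-CCD noise cascade is applied.
#'
#' Motion blur is approximated by depositing `blur_samples` sub-spots evenly
#' spaced along the straight segment from the current to the next timepoint
#' position, covering the exposed fraction of the timestep.
#'
#' @param tracks Ground-truth track tibble (see [sim_brownian_tracks()]). An
#'   optional `frame` column assigns tracks to frames; otherwise tracks are
#'   chunked `tracks_per_frame` at a time.
#' @param config An [acq_config()].
#' @param seed Optional integer seed (noise only; placement is deterministic).
#' @param tracks_per_frame Number of tracks per readout frame when `tracks`
#'   has no `frame` column.
#' @param blur_samples Sub-exposure position samples (1 = no blur).
#' @param noise Apply EM-CCD noise (`TRUE`) or return expected photons.
#' @return A `frame_stack`: list with `frames` (list of matrices),
#'   `config`, and `truth` (the tracks with `frame`, chip coordinates and a
#'   `truncated` flag for images falling off the chip).
#' @export
render_frames <- function(tracks, config, seed = NULL,
                          tracks_per_frame = NULL, blur_samples = 10L,
                          noise = TRUE) {
  tracks <- place_tracks(tracks, config, tracks_per_frame)
  if (any(tracks$truncated)) {
    warn(sprintf(
      "%d single-molecule images fall off the chip and are truncated.",
      sum(tracks$truncated)
    ))
  }
  frames <- with_seed_maybe(seed, {
    lapply(sort(unique(tracks$frame)), function(f) {
      render_one_frame(tracks[tracks$frame == f, ], config, blur_samples,
                       noise)
    })
  })
  structure(
    list(frames = frames, config = config, truth = tracks),
    class = "frame_stack"
  )
}

render_one_frame <- function(trk, config, blur_samples, noise,
                             photon_col = "photons") {
  img <- matrix(config$n_timepoints * config$background_rate,
                config$chip_rows, config$chip_cols)
  trk <- trk[!trk$truncated & trk[[photon_col]] > 0, , drop = FALSE]
  if (nrow(trk)) {
    duty <- config$exposure_us[trk$timepoint] / config$timestep_us
    trk <- dplyr::arrange(trk, .data$track_id, .data$timepoint)
    nxt <- dplyr::lead(trk$timepoint) == trk$timepoint + 1L &
      dplyr::lead(trk$track_id) == trk$track_id
    nxt[is.na(nxt)] <- FALSE
    s <- max(1L, as.integer(blur_samples))
    if (s == 1L) {
      rows <- trk$row_px
      cols <- trk$col_px
      ph <- trk[[photon_col]]
    } else {
      frac <- (seq_len(s) - 0.5) / s
      drow <- ifelse(nxt, dplyr::lead(trk$row_px) - trk$row_px -
                       config$shift_height * config$shift_multiples[trk$timepoint],
                     0)
      dcol <- ifelse(nxt, dplyr::lead(trk$col_px) - trk$col_px, 0)
      rows <- rep(trk$row_px, each = s) +
        rep(drow * duty, each = s) * rep(frac, nrow(trk))
      cols <- rep(trk$col_px, each = s) +
        rep(dcol * duty, each = s) * rep(frac, nrow(trk))
      ph <- rep(trk[[photon_col]] / s, each = s)
    }
    img <- add_psf_cpp(img, rows, cols, ph, config$psf_sigma_px)
  }
  if (noise) {
    emccd_noise(img, em_gain = config$em_gain, read_noise = config$read_noise)
  } else {
    img
  }
}

#' Render two-channel FRET frames
#'
#' Renders the same tracks into a donor and an acceptor frame stack, with the
#' per-timepoint photon budget split by the true FRET efficiency: the
#' acceptor channel receives `photons * E_true`, the donor
#' `photons * (1 - E_true)`. The channel mapping is the identity (both
#' channels share chip coordinates).
#'
#' @param tracks Tracks with an `E_true` column (see [sim_fret_tracks()]).
#' @inheritParams render_frames
#' @return A list with `donor` and `acceptor` frame stacks.
#' @export
render_fret_frames <- function(tracks, config, seed = NULL,
                               tracks_per_frame = NULL, blur_samples = 10L,
                               noise = TRUE) {
  if (!"E_true" %in% names(tracks)) abort("`tracks` needs an `E_true` column.")
  tracks <- place_tracks(tracks, config, tracks_per_frame)
  tracks$ph_d <- tracks$photons * (1 - tracks$E_true)
  tracks$ph_a <- tracks$photons * tracks$E_true
  with_seed_maybe(seed, {
    fids <- sort(unique(tracks$frame))
    donor <- lapply(fids, function(f) {
      render_one_frame(tracks[tracks$frame == f, ], config, blur_samples,
                       noise, photon_col = "ph_d")
    })
    acceptor <- lapply(fids, function(f) {
      render_one_frame(tracks[tracks$frame == f, ], config, blur_samples,
                       noise, photon_col = "ph_a")
    })
    list(
      donor = structure(list(frames = donor, config = config, truth = tracks),
                        class = "frame_stack"),
      acceptor = structure(list(frames = acceptor, config = config,
                                truth = tracks),
                           class = "frame_stack")
    )
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf(
    "<frame_stack> %d frame(s) of %d x %d px, %d timepoints each\n",
    length(x$frames), x$config$chip_rows, x$config$chip_cols,
    x$config$n_timepoints
  ))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth: %d tracks, %d images\n",
                dplyr::n_distinct(x$truth$track_id), nrow(x$truth)))
  }
  invisible(x)
}
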