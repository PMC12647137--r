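#' Run the tracking pipeline on ground-truth tracks
#'
#' Convenience wrapper chaining the full analysis on simulated input:
#' [render_frames()] -> [localize_frames()] -> [link_trails()] ->
#' [collapse_trails()]. Frames are rendered and localized one at a time so
#' arbitrarily many tracks can be processed in bounded memory.
#'
#' @param tracks Ground-truth tracks (see [sim_brownian_tracks()]).
#' @param config An [acq_config()].
#' @param link A [link_params()].
#' @param tracks_per_frame Tracks rendered into each readout frame (sets the
#'   single-molecule image density).
#' @param seed Optional integer seed for rendering noise.
#' @param blur_samples Sub-exposure motion-blur samples.
#' @param min_snr Detection threshold passed to [localize_frames()].
#' @param keep_frames Keep the rendered frames in the result (memory-hungry
#'   for large runs).
#' @return A list: `localizations`, `trails`, `trajectories`, `truth`, and
#'   (optionally) `frames`.
#' @examples
#' \donttest{
#' cfg <- acq_preset("protein-pbs")
#' trk <- sim_brownian_tracks(50, 90, cfg$timestep_us, seed = 1)
#' run <- run_tracking_pipeline(trk, cfg,
#'                              link_params(100, cfg$timestep_us), seed = 2)
#' fit_msd(compute_msd(run$trajectories, cfg$timestep_us))
#' }
#' @export
run_tracking_pipeline <- function(tracks, config, link,
                                  tracks_per_frame = 100L, seed = NULL,
                                  blur_samples = 10L, min_snr = 5,
                                  keep_frames = FALSE) {
  stopifnot(inherits(config, "acq_config"), inherits(link, "link_params"))
  tracks <- place_tracks(tracks, config, tracks_per_frame)
  fids <- sort(unique(tracks$frame))
  frames_kept <- if (keep_frames) vector("list", length(fids)) else NULL
  locs <- with_seed_maybe(seed, {
    purrr::map_dfr(seq_along(fids), function(i) {
      f <- fids[i]
      img <- render_one_frame(tracks[tracks$frame == f, ], config,
                              blur_samples, noise = TRUE)
      if (keep_frames) frames_kept[[i]] <<- img
      cand <- detect_spots(img, min_snr = min_snr,
                           smooth_sigma_px = config$psf_sigma_px)
      out <- fit_spots(img, cand, config)
      out$frame <- f
      out
    })
  })
  locs <- dplyr::select(locs, "frame", dplyr::everything())
  trails <- link_trails(locs, link, chip_rows = config$chip_rows)
  traj <- collapse_trails(trails, link)
  out <- list(localizations = locs, trails = trails, trajectories = traj,
              truth = tracks)
  if (keep_frames) out$frames <- frames_kept
  out
}
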