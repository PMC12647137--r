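#' Search radius for trail linking
#'
#' The linking search radius is `2.55 * sqrt(4 * D' * dt)`, where `D'` is the
#' largest diffusion coefficient expected for the sample and `dt` the
#' timestep; at this radius the chance of a Brownian step escaping the search
#' disc is about 0.15%.
#'
#' @param d_max_um2s Largest expected diffusion coefficient (um^2/s).
#' @param timestep_us Timestep (microseconds).
#' @return Search radius in nm.
#' @examples
#' search_radius(100, 307.5)  # ~894 nm
#' @export
search_radius <- function(d_max_um2s, timestep_us) {
  check_number(d_max_um2s, "d_max_um2s")
  check_number(timestep_us, "timestep_us")
  2.55 * sqrt(4 * d_max_um2s * timestep_us * 1e-6) * 1000
}

#' Linking parameters
#'
#' Bundles the knobs of the greedy trail-linking algorithm. The search radius
#' defaults to [search_radius()] from `d_max_um2s`. Trails are terminated when
#' `max_consecutive_skips` skipped timepoints occur in a row: 3 in fixed-shift
#' mode and 6 in variable-shift mode, where up to three gaps per timestep are
#' expected from the shift pattern itself (a multiple of 4 writes "1000").
#'
#' @param d_max_um2s Largest expected diffusion coefficient (um^2/s). May be
#'   omitted when `search_radius_nm` is given directly.
#' @param timestep_us Acquisition timestep (microseconds).
#' @param shift_height Base shift height (rows per slot).
#' @param pixel_nm Pixel size (nm).
#' @param mode `"fixed"` or `"vs"` (variable shift).
#' @param search_radius_nm Override for the search radius.
#' @param max_consecutive_skips Consecutive-skip count that terminates a
#'   trail.
#' @param min_detections Minimum detections for a trail to be kept.
#' @param max_skip_fraction Trails with a larger skipped fraction are
#'   discarded ("dominated by skips"). Defaults to 0.5 in fixed mode; in VS
#'   mode the shift pattern itself makes just over half of all slots
#'   structural gaps (35 of 68 for the reference sequence), so the default
#'   rises to 0.8 to discard only trails with genuine detection dropout.
#' @return A `link_params` list.
#' @export
link_params <- function(d_max_um2s = NULL, timestep_us = NULL,
                        shift_height = 15L, pixel_nm = 159,
                        mode = c("fixed", "vs"),
                        search_radius_nm = NULL,
                        max_consecutive_skips = NULL,
                        min_detections = 4L,
                        max_skip_fraction = NULL) {
  mode <- match.arg(mode)
  if (is.null(search_radius_nm)) {
    if (is.null(d_max_um2s) || is.null(timestep_us)) {
      abort("supply `d_max_um2s` and `timestep_us`, or `search_radius_nm`.")
    }
    search_radius_nm <- search_radius(d_max_um2s, timestep_us)
  }
  check_number(search_radius_nm, "search_radius_nm")
  max_consecutive_skips <- as.integer(
    max_consecutive_skips %||% if (mode == "fixed") 3L else 6L
  )
  max_skip_fraction <- max_skip_fraction %||%
    if (mode == "fixed") 0.5 else 0.8
  if (max_consecutive_skips < 1L) {
    abort("`max_consecutive_skips` must be >= 1.")
  }
  structure(
    list(
      mode = mode,
      d_max_um2s = d_max_um2s,
      timestep_us = timestep_us,
      shift_height = as.integer(shift_height),
      pixel_nm = pixel_nm,
      search_radius_nm = search_radius_nm,
      max_consecutive_skips = max_consecutive_skips,
      min_detections = as.integer(min_detections),
      max_skip_fraction = max_skip_fraction
    ),
    class = "link_params"
  )
}

#' Group localizations into single-molecule trails
#'
#' Greedy reconstruction of streaks, one frame at a time. The seed is the
#' unassigned localization with the smallest row index (the trail's first
#' timepoint); the next timepoint is predicted one shift height below the
#' previous one and searched within the search radius, nearest candidate
#' first (ties broken toward the lowest input index). When nothing is found a
#' skip placeholder is inserted and the search continues from the predicted
#' position; a run of `max_consecutive_skips` skips terminates the trail and
#' trailing skips are stripped. Trails with fewer than `min_detections`
#' detections or dominated by skips are discarded. Used localizations leave
#' the pool either way, so every localization ends up in exactly one trail or
#' in the discard pool.
#'
#' In variable-shift mode the same slot-by-slot search runs with the larger
#' skip allowance; the executed multiples then appear as gap patterns that
#' [align_trails()] decodes.
#'
#' @param localizations Localization table (see [localize_frames()]).
#' @param params A [link_params()].
#' @param chip_rows Chip height; the search stops below the chip.
#' @return A tibble with one row per slot of every kept trail: `trail_id`,
#'   `frame`, `slot` (0-based within the trail), `detected`, `x_px`, `y_px`
#'   (`NA` on skips), `photons`, `sigma_px`, `precision_nm`, `loc_row` (row
#'   index into `localizations`). The discarded localization rows are
#'   attached as attribute `"discarded"`.
#' @export
link_trails <- function(localizations, params, chip_rows = 1024L) {
  stopifnot(inherits(params, "link_params"))
  locs <- localizations
  if (!"frame" %in% names(locs)) locs$frame <- 1L
  need <- c("frame", "x_px", "y_px")
  if (!all(need %in% names(locs))) {
    abort("`localizations` must have columns frame, x_px, y_px.")
  }
  r_px <- params$search_radius_nm / params$pixel_nm
  delta <- params$shift_height
  locs$.row <- seq_len(nrow(locs))

  trails <- list()
  discarded <- integer()
  next_id <- 1L
  for (f in sort(unique(locs$frame))) {
    lf <- locs[locs$frame == f, ]
    ord <- order(lf$y_px, lf$x_px, lf$.row)
    lf <- lf[ord, ]
    avail <- rep(TRUE, nrow(lf))
    for (seed_i in seq_len(nrow(lf))) {
      if (!avail[seed_i]) next
      avail[seed_i] <- FALSE
      used <- seed_i
      slots <- list(list(det = TRUE, i = seed_i))
      pred_x <- lf$x_px[seed_i]
      pred_y <- lf$y_px[seed_i] + delta
      run <- 0L
      while (run < params$max_consecutive_skips &&
             pred_y <= chip_rows - 1 + r_px) {
        cand <- which(avail)
        if (length(cand)) {
          d2 <- (lf$x_px[cand] - pred_x)^2 + (lf$y_px[cand] - pred_y)^2
          hit <- cand[d2 <= r_px^2]
          d2 <- d2[d2 <= r_px^2]
        } else {
          hit <- integer()
        }
        if (length(hit)) {
          j <- hit[order(d2, lf$.row[hit])][1]
          avail[j] <- FALSE
          used <- c(used, j)
          slots[[length(slots) + 1L]] <- list(det = TRUE, i = j)
          pred_x <- lf$x_px[j]
          pred_y <- lf$y_px[j] + delta
          run <- 0L
        } else {
          slots[[length(slots) + 1L]] <- list(det = FALSE, i = NA_integer_)
          pred_y <- pred_y + delta
          run <- run + 1L
        }
      }
      det <- vapply(slots, `[[`, logical(1), "det")
      last_det <- max(which(det))
      slots <- slots[seq_len(last_det)]
      det <- det[seq_len(last_det)]
      n_det <- sum(det)
      if (n_det < params$min_detections ||
          (1 - n_det / length(det)) > params$max_skip_fraction) {
        discarded <- c(discarded, lf$.row[used])
        next
      }
      idx <- vapply(slots, `[[`, integer(1), "i")
      trails[[length(trails) + 1L]] <- tibble::tibble(
        trail_id = next_id,
        frame = f,
        slot = seq_along(slots) - 1L,
        detected = det,
        loc_row = lf$.row[idx]
      )
      next_id <- next_id + 1L
    }
  }
  out <- if (length(trails)) dplyr::bind_rows(trails) else tibble::tibble(
    trail_id = integer(), frame = integer(), slot = integer(),
    detected = logical(), loc_row = integer()
  )
  carry <- intersect(c("x_px", "y_px", "photons", "sigma_px", "precision_nm"),
                     names(localizations))
  for (cl in carry) out[[cl]] <- localizations[[cl]][out$loc_row]
  attr(out, "discarded") <- discarded
  attr(out, "params") <- params
  out
}

#' Collapse trails into spatial trajectories
#'
#' Converts fixed-shift trails from chip coordinates to sample coordinates by
#' subtracting the executed vertical shifts: the slot-k vertical coordinate
#' is reduced by `k * shift_height` rows. Coordinates are reported in nm
#' relative to the trail's first detection (the absolute chip position of a
#' fixed-shift streak carries no spatial meaning); use [recover_absolute()]
#' for variable-shift data. Each slot is one timestep, so `timepoint = slot`.
#'
#' @param trails Output of [link_trails()].
#' @param params The [link_params()] used for linking (defaults to the
#'   attribute stored on `trails`).
#' @param reference `"first"` (relative to the first detection) or `"chip"`
#'   (shift-subtracted chip coordinates).
#' @return A trajectory tibble: `track_id`, `frame`, `timepoint`, `t_us`,
#'   `x_nm`, `y_nm` (`NA` on skips), `skipped`, `photons`, `precision_nm`.
#' @export
collapse_trails <- function(trails, params = attr(trails, "params"),
                            reference = c("first", "chip")) {
  reference <- match.arg(reference)
  if (is.null(params)) abort("supply `params` (link parameters).")
  px <- params$pixel_nm
  delta <- params$shift_height
  out <- trails |>
    dplyr::group_by(.data$trail_id) |>
    dplyr::mutate(
      x_nm = .data$x_px * px,
      y_nm = (.data$y_px - delta * .data$slot) * px
    ) |>
    dplyr::mutate(
      x_nm = .data$x_nm - if (reference == "first")
        .data$x_nm[which(.data$detected)[1]] else 0,
      y_nm = .data$y_nm - if (reference == "first")
        .data$y_nm[which(.data$detected)[1]] else 0
    ) |>
    dplyr::ungroup()
  tibble::tibble(
    track_id = out$trail_id,
    frame = out$frame,
    timepoint = out$slot,
    t_us = if (!is.null(params$timestep_us))
      out$slot * params$timestep_us else NA_real_,
    x_nm = out$x_nm,
    y_nm = out$y_nm,
    skipped = !out$detected,
    photons = out$photons %||% NA_real_,
    precision_nm = out$precision_nm %||% NA_real_
  )
}
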