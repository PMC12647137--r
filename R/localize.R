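gauss_smooth <- function(m, sigma_px) {
  hw <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  k <- k / sum(k)
  sm <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  sm[is.na(sm)] <- median(m)
  sm
}

#' Detect candidate single-molecule images in a frame
#'
#' Matched-filter detection: the frame is smoothed with a Gaussian kernel of
#' the PSF width (`smooth_sigma_px`; set `NULL` to detect on the raw image),
#' then local maxima rising at least `min_snr` noise standard deviations
#' above the background are kept, with non-maximum suppression within
#' `min_separation_px`. Background and noise default to the median and MAD
#' of the (smoothed) frame, which are robust to sparse spots. Smoothing
#' makes dim or motion-blurred images detectable that a raw peak threshold
#' would miss.
#'
#' @param frame Integer/numeric matrix (rows x cols of one readout frame).
#' @param min_snr Detection threshold in units of the background noise sd.
#' @param min_separation_px Minimum distance between retained candidates.
#' @param smooth_sigma_px Matched-filter kernel sd in pixels (`NULL` for no
#'   smoothing).
#' @param background,noise_sd Optional overrides for the background level and
#'   noise sd (counts, on the smoothed image when smoothing is on).
#' @return A tibble of candidates: `row_px`, `col_px` (0-based integer pixel
#'   indices), `value` (counts in the detection image).
#' @export
detect_spots <- function(frame, min_snr = 5, min_separation_px = 3,
                         smooth_sigma_px = 1, background = NULL,
                         noise_sd = NULL) {
  if (!is.matrix(frame) || !all(is.finite(frame))) {
    abort("`frame` must be a finite numeric matrix.")
  }
  if (!is.null(smooth_sigma_px) && smooth_sigma_px > 0) {
    frame <- gauss_smooth(frame, smooth_sigma_px)
  }
  bg <- background %||% median(frame)
  ns <- noise_sd %||% mad(frame)
  thr <- bg + min_snr * ns

  nr <- nrow(frame)
  nc <- ncol(frame)
  # 8-neighbour local maxima via shifted comparisons (ties broken toward the
  # lower index by using >= against later neighbours and > against earlier).
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- frame
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ismax <- ctr > thr
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
      later <- dr > 0L || (dr == 0L && dc > 0L)
      cmp <- if (later) ctr >= nb else ctr > nb
      ismax <- ismax & cmp
    }
  }
  idx <- which(ismax)
  if (!length(idx)) {
    return(tibble::tibble(row_px = integer(), col_px = integer(),
                          value = numeric()))
  }
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  v <- frame[idx]
  ord <- order(-v, r, c)
  r <- r[ord]; c <- c[ord]; v <- v[ord]
  keep <- logical(length(r))
  min2 <- min_separation_px^2
  for (i in seq_along(r)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep[seq_len(i - 1L)])
    keep[i] <- all((r[sel] - r[i])^2 + (c[sel] - c[i])^2 >= min2)
  }
  tibble::tibble(row_px = as.integer(r[keep]), col_px = as.integer(c[keep]),
                 value = v[keep]) |>
    dplyr::arrange(.data$row_px, .data$col_px)
}

#' Fit candidate spots with an integrated 2D Gaussian
#'
#' Least-squares fit of a pixel-integrated Gaussian (centre, width, amplitude,
#' offset) in a square ROI around each candidate, by Levenberg-Marquardt.
#' Candidates whose ROI leaves the chip are dropped; fits that do not
#' converge, land outside their ROI, or return a width outside
#' `sigma_bounds * psf_sigma_px` are discarded and counted in the
#' `rejected` attribute of the result.
#'
#' Counts are converted to photons by dividing by the EM gain, and the
#' theoretical localization precision is attached via [precision_estimate()].
#'
#' @param frame Frame matrix.
#' @param candidates Tibble from [detect_spots()].
#' @param config An [acq_config()] supplying the PSF width, EM gain and pixel
#'   size.
#' @param roi_halfwidth ROI half-width in pixels (default
#'   `ceiling(3 * psf_sigma_px)`).
#' @param sigma_bounds Acceptable fitted width range relative to
#'   `psf_sigma_px`.
#' @return A tibble of localizations: `x_px`, `y_px` (sub-pixel, 0-based),
#'   `photons`, `background` (photons/pixel), `sigma_px`, `precision_nm`.
#' @export
fit_spots <- function(frame, candidates, config,
                      roi_halfwidth = NULL, sigma_bounds = c(0.3, 3)) {
  stopifnot(inherits(config, "acq_config"))
  hw <- as.integer(roi_halfwidth %||% ceiling(3 * config$psf_sigma_px))
  nr <- nrow(frame); nc <- ncol(frame)
  empty <- tibble::tibble(
    x_px = numeric(), y_px = numeric(), photons = numeric(),
    background = numeric(), sigma_px = numeric(), precision_nm = numeric()
  )
  if (!nrow(candidates)) return(structure(empty, rejected = c(edge = 0L, fit = 0L)))
  inside <- candidates$row_px >= hw & candidates$row_px < nr - hw &
    candidates$col_px >= hw & candidates$col_px < nc - hw
  n_edge <- sum(!inside)
  cand <- candidates[inside, , drop = FALSE]
  if (!nrow(cand)) return(structure(empty, rejected = c(edge = n_edge, fit = 0L)))

  f <- fit_gauss2d_cpp(frame, cand$row_px, cand$col_px, hw,
                       config$psf_sigma_px)
  x <- f[, 1]; y <- f[, 2]; sig <- f[, 3]; amp <- f[, 4]; off <- f[, 5]
  ok <- f[, 7] > 0 & amp > 0 &
    sig >= sigma_bounds[1] * config$psf_sigma_px &
    sig <= sigma_bounds[2] * config$psf_sigma_px &
    abs(x - cand$col_px) <= hw & abs(y - cand$row_px) <= hw
  photons <- amp[ok] / config$em_gain
  bg <- pmax(off[ok], 0) / config$em_gain
  out <- tibble::tibble(
    x_px = x[ok], y_px = y[ok],
    photons = photons,
    background = bg,
    sigma_px = sig[ok],
    precision_nm = precision_estimate(photons, sig[ok], bg, config$pixel_nm)
  )
  structure(out, rejected = c(edge = n_edge, fit = sum(!ok)))
}

#' Localize all frames of a stack
#'
#' Runs [detect_spots()] and [fit_spots()] over every frame and binds the
#' results into one localization table, the interchange format consumed by
#' [link_trails()] (third-party localizers can be substituted by providing
#' the same columns).
#'
#' @param x A `frame_stack` from [render_frames()] (or a list of matrices).
#' @param config An [acq_config()]; taken from the stack when omitted.
#' @param min_snr,min_separation_px Passed to [detect_spots()].
#' @param ... Passed to [fit_spots()].
#' @return A tibble: `frame`, `x_px`, `y_px`, `photons`, `background`,
#'   `sigma_px`, `precision_nm`.
#' @export
localize_frames <- function(x, config = NULL, min_snr = 5,
                            min_separation_px = 3, ...) {
  if (inherits(x, "frame_stack")) {
    config <- config %||% x$config
    frames <- x$frames
  } else {
    frames <- x
  }
  if (is.null(config)) abort("supply `config` when `x` is a plain list.")
  purrr::imap_dfr(frames, function(fr, i) {
    cand <- detect_spots(fr, min_snr = min_snr,
                         min_separation_px = min_separation_px,
                         smooth_sigma_px = config$psf_sigma_px)
    locs <- fit_spots(fr, cand, config, ...)
    locs$frame <- as.integer(i)
    locs
  }) |>
    dplyr::select("frame", dplyr::everything())
}

#' Theoretical localization precision
#'
#' Standard least-squares localization-error estimate for a pixel-integrated
#' Gaussian PSF on a uniform background, inflated by the EM-CCD excess noise
#' factor: the variance is
#' `F * (sa2/N) * (16/9 + 8*pi*sa2*b / (N*a^2))`, with
#' `sa2 = (sigma^2 + 1/12) * a^2` the pixelation-corrected PSF variance, `N`
#' the collected photons, `b` the background photons per pixel, `a` the pixel
#' size and `F = 2` the EM multiplicative-noise inflation. Precision falls as
#' `1/sqrt(N)` and grows with background.
#'
#' @param photons Detected signal photons (> 0).
#' @param sigma_px Fitted/true PSF sd in pixels.
#' @param background Background photons per pixel.
#' @param pixel_nm Pixel size (nm).
#' @param em_excess Variance inflation from EM multiplication (2 for an
#'   EM-CCD, 1 for an ideal detector).
#' @return Localization precision in nm (same length as `photons`).
#' @examples
#' precision_estimate(100, 1, 1, 159)   # ~30 nm
#' @export
precision_estimate <- function(photons, sigma_px, background = 0,
                               pixel_nm = 159, em_excess = 2) {
  if (any(!is.finite(photons)) || any(photons <= 0)) {
    abort("`photons` must be > 0.")
  }
  if (any(background < 0)) abort("`background` must be >= 0.")
  sa2 <- (sigma_px^2 + 1 / 12) * pixel_nm^2
  v <- em_excess * (sa2 / photons) *
    (16 / 9 + 8 * pi * sa2 * background / (photons * pixel_nm^2))
  sqrt(v)
}
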