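#' Spatial map of local diffusion coefficient and anomalous exponent
#'
#' Bins single-molecule displacements at lags 1..`max_lag` onto a square grid
#' by their start position. For each bin a local principal diffusion
#' direction is determined from the displacements at `direction_lag`
#' timesteps separation (angle-doubling average), displacements are projected
#' onto it, and the per-lag parallel MSD is fitted twice: a linear
#' one-dimensional model `MSD_par = 2 D t + b` on the first `n_points` lags
#' (local `D`), and the power law `MSD_par = 2 K t^alpha + b` on the first
#' `n_lags_power` lags with the two-step intercept procedure (local `alpha`).
#' Bins with fewer than `min_count` displacements, an undefined orientation,
#' or too few populated lags are flagged invalid rather than fitted.
#'
#' @param trajectories Trajectory tibble in absolute coordinates (from
#'   [recover_absolute()], or any table with `x_nm`/`y_nm`).
#' @param timestep_us Acquisition timestep (microseconds).
#' @param bin_nm Grid spacing (nm).
#' @param max_lag Largest displacement lag pooled into the bins.
#' @param n_points Lags used for the linear fit.
#' @param n_lags_power Lags used for the power-law fit.
#' @param direction_lag Lag (timesteps) used for the principal direction.
#' @param min_count Minimum displacements per bin.
#' @return A `diffusion_map` tibble: `bin_x`, `bin_y`, `x_nm`, `y_nm` (bin
#'   centres), `n_disp`, `theta`, `resultant`, `D_um2s`, `b_lin`, `K`,
#'   `alpha`, `b_pow`, `valid`.
#' @export
map_diffusion <- function(trajectories, timestep_us, bin_nm = 120,
                          max_lag = 10L, n_points = 4L, n_lags_power = 6L,
                          direction_lag = 4L, min_count = 50L) {
  check_number(timestep_us, "timestep_us")
  check_number(bin_nm, "bin_nm")
  disp <- compute_displacements(trajectories, seq_len(max_lag))
  if (!nrow(disp)) abort("no displacements to map.")
  disp$bin_x <- floor(disp$x0_nm / bin_nm)
  disp$bin_y <- floor(disp$y0_nm / bin_nm)

  fit_bin <- function(d) {
    n_disp <- nrow(d)
    base <- tibble::tibble(
      n_disp = n_disp, theta = NA_real_, resultant = NA_real_,
      D_um2s = NA_real_, b_lin = NA_real_, K = NA_real_,
      alpha = NA_real_, b_pow = NA_real_, valid = FALSE
    )
    if (n_disp < min_count) return(base)
    dir <- d[d$lag == direction_lag, ]
    pd <- principal_direction(dir$dx_nm, dir$dy_nm)
    if (!pd$defined) {
      base$theta <- pd$theta
      base$resultant <- pd$resultant
      return(base)
    }
    comp <- decompose_msd(d, pd$theta, timestep_us)
    par <- comp[comp$component == "par", ]
    if (nrow(par) < max(n_points, 2L)) {
      base$theta <- pd$theta
      base$resultant <- pd$resultant
      return(base)
    }
    lin <- fit_msd(par, n_points = n_points, dimensionality = 1L)
    pow <- tryCatch(
      suppressWarnings(
        fit_msd(par, model = "powerlaw", n_lags = n_lags_power,
                dimensionality = 1L)
      ),
      error = function(e) NULL
    )
    tibble::tibble(
      n_disp = n_disp, theta = pd$theta, resultant = pd$resultant,
      D_um2s = lin$D, b_lin = lin$b,
      K = if (is.null(pow)) NA_real_ else pow$K,
      alpha = if (is.null(pow)) NA_real_ else pow$alpha,
      b_pow = if (is.null(pow)) NA_real_ else pow$b,
      valid = TRUE
    )
  }

  out <- disp |>
    dplyr::group_by(.data$bin_x, .data$bin_y) |>
    dplyr::group_modify(~ fit_bin(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      x_nm = (.data$bin_x + 0.5) * bin_nm,
      y_nm = (.data$bin_y + 0.5) * bin_nm
    ) |>
    dplyr::select("bin_x", "bin_y", "x_nm", "y_nm", "n_disp", "theta",
                  "resultant", "D_um2s", "b_lin", "K", "alpha", "b_pow",
                  "valid")
  tibble::new_tibble(out, bin_nm = bin_nm, timestep_us = timestep_us,
                     class = "diffusion_map")
}

#' Render a super-resolution localization image
#'
#' Builds a 2D histogram of localizations on a fine grid, the standard
#' reconstruction of single-molecule localization microscopy. Optionally the
#' histogram is smoothed with a Gaussian kernel of standard deviation
#' `sigma_nm` (e.g. the mean localization precision); without smoothing the
#' image total equals the number of localizations exactly.
#'
#' @param positions Tibble with `x_nm` and `y_nm` (e.g. the detected rows of
#'   a recovered trajectory table).
#' @param pixel_nm Rendering pixel size (nm).
#' @param sigma_nm Optional Gaussian blur sd (nm).
#' @param xlim,ylim Optional ranges (nm); default spans the data.
#' @return An `smlm_image`: list with `image` (matrix, rows = y), `pixel_nm`
#'   and `origin` (nm coordinates of the image corner).
#' @export
render_smlm <- function(positions, pixel_nm = 20, sigma_nm = NULL,
                        xlim = NULL, ylim = NULL) {
  x <- positions$x_nm
  y <- positions$y_nm
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) abort("no finite positions to render.")
  xlim <- xlim %||% range(x)
  ylim <- ylim %||% range(y)
  nx <- max(1L, ceiling((xlim[2] - xlim[1]) / pixel_nm)) + 1L
  ny <- max(1L, ceiling((ylim[2] - ylim[1]) / pixel_nm)) + 1L
  ix <- floor((x - xlim[1]) / pixel_nm) + 1L
  iy <- floor((y - ylim[1]) / pixel_nm) + 1L
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  img <- matrix(0, ny, nx)
  tab <- table((ix[inside] - 1L) * ny + iy[inside])
  img[as.integer(names(tab))] <- as.numeric(tab)
  if (!is.null(sigma_nm) && sigma_nm > 0) {
    s_px <- sigma_nm / pixel_nm
    hw <- ceiling(3 * s_px)
    k <- stats::dnorm(-hw:hw, sd = s_px)
    k <- k / sum(k)
    img <- apply(img, 2, function(col) {
      as.numeric(stats::filter(col, k, sides = 2, circular = FALSE))
    })
    img[is.na(img)] <- 0
    img <- t(apply(img, 1, function(row) {
      as.numeric(stats::filter(row, k, sides = 2, circular = FALSE))
    }))
    img[is.na(img)] <- 0
  }
  structure(
    list(image = img, pixel_nm = pixel_nm,
         origin = c(x = xlim[1], y = ylim[1])),
    class = "smlm_image"
  )
}

#' @export
print.smlm_image <- function(x, ...) {
  cat(sprintf("<smlm_image> %d x %d px at %.0f nm/px, total counts %.1f\n",
              nrow(x$image), ncol(x$image), x$pixel_nm, sum(x$image)))
  invisible(x)
}
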