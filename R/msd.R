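#' Single-molecule displacements at given time lags
#'
#' Extracts all (t, t + lag) displacement pairs from a trajectory table,
#' pooled across tracks. Skipped timepoints contribute no pairs, and a pair
#' spanning skips keeps its true time separation (the lag is a difference of
#' timepoint indices, not of row positions).
#'
#' @param trajectories Trajectory tibble with `track_id`, `timepoint`,
#'   `x_nm`, `y_nm` and optionally `skipped`.
#' @param lags Integer vector of lags (in timesteps).
#' @return A tibble: `track_id`, `lag`, `t0` (start timepoint), `x0_nm`,
#'   `y0_nm`, `dx_nm`, `dy_nm`.
#' @export
compute_displacements <- function(trajectories, lags) {
  det <- trajectories
  if ("skipped" %in% names(det)) det <- det[!det$skipped, ]
  det <- det[is.finite(det$x_nm) & is.finite(det$y_nm), ]
  det <- det[, c("track_id", "timepoint", "x_nm", "y_nm")]
  purrr::map_dfr(as.integer(lags), function(l) {
    later <- dplyr::transmute(
      det,
      track_id = .data$track_id,
      timepoint = .data$timepoint - l,
      x1_nm = .data$x_nm, y1_nm = .data$y_nm
    )
    dplyr::inner_join(det, later, by = c("track_id", "timepoint")) |>
      dplyr::transmute(
        track_id = .data$track_id,
        lag = l,
        t0 = .data$timepoint,
        x0_nm = .data$x_nm, y0_nm = .data$y_nm,
        dx_nm = .data$x1_nm - .data$x_nm,
        dy_nm = .data$y1_nm - .data$y_nm
      )
  })
}

new_msd_result <- function(df, timestep_us) {
  tibble::new_tibble(df, timestep_us = timestep_us, class = "msd_result")
}

#' Mean squared displacement versus time lag
#'
#' Pooled MSD over all tracks using every overlapping (t, t + lag) pair of
#' detected timepoints. The standard error per lag is the standard deviation
#' of the squared displacements divided by `sqrt(n_pairs)`; overlapping pairs
#' are correlated, so this slightly understates the true uncertainty at long
#' lags. Lags with no valid pairs are omitted.
#'
#' @param trajectories Trajectory tibble (see [collapse_trails()]).
#' @param timestep_us Acquisition timestep (microseconds).
#' @param max_lag Largest lag, in timesteps.
#' @return An `msd_result` tibble: `lag`, `t_lag_us`, `msd_um2`, `se_um2`,
#'   `n_pairs`, `component` (`"iso"` for the unprojected 2D MSD).
#' @export
compute_msd <- function(trajectories, timestep_us, max_lag = 10L) {
  check_number(timestep_us, "timestep_us")
  disp <- compute_displacements(trajectories, seq_len(max_lag))
  out <- disp |>
    dplyr::mutate(r2 = (.data$dx_nm^2 + .data$dy_nm^2) * 1e-6) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      msd_um2 = mean(.data$r2),
      se_um2 = stats::sd(.data$r2) / sqrt(dplyr::n()),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(t_lag_us = .data$lag * timestep_us, component = "iso") |>
    dplyr::select("lag", "t_lag_us", "msd_um2", "se_um2", "n_pairs",
                  "component")
  new_msd_result(out, timestep_us)
}

#' Principal diffusion direction from bidirectional displacements
#'
#' Averages displacement directions with the angle-doubling trick (mean of
#' unit vectors at twice the displacement angle, halved), so antiparallel
#' displacements reinforce rather than cancel -- appropriate for diffusion,
#' which has no preferred sign along its axis. The mean resultant length of
#' the doubled angles measures anisotropy; for isotropic motion it tends to
#' zero and the orientation is flagged undefined.
#'
#' @param dx_nm,dy_nm Displacement components.
#' @param min_resultant Resultant length below which the orientation is
#'   declared undefined.
#' @return A list: `theta` (radians in [0, pi), `NA` if undefined),
#'   `resultant` (0-1), `n`, `defined`.
#' @export
principal_direction <- function(dx_nm, dy_nm, min_resultant = 0.1) {
  keep <- is.finite(dx_nm) & is.finite(dy_nm) & (dx_nm != 0 | dy_nm != 0)
  dx <- dx_nm[keep]; dy <- dy_nm[keep]
  n <- length(dx)
  if (!n) {
    return(list(theta = NA_real_, resultant = 0, n = 0L, defined = FALSE))
  }
  phi2 <- 2 * atan2(dy, dx)
  s <- mean(sin(phi2)); cth <- mean(cos(phi2))
  resultant <- sqrt(s^2 + cth^2)
  theta <- (atan2(s, cth) / 2) %% pi
  defined <- resultant >= min_resultant
  list(theta = if (defined) theta else NA_real_,
       resultant = resultant, n = n, defined = defined)
}

#' Decompose displacements into parallel and perpendicular MSD components
#'
#' Projects each displacement onto (and against) a given orientation axis and
#' returns per-lag MSDs of the two components. Their sum equals the total
#' MSD exactly (Pythagoras).
#'
#' @param displacements Tibble from [compute_displacements()].
#' @param theta Axis orientation (radians).
#' @param timestep_us Acquisition timestep.
#' @return An `msd_result` tibble with `component` equal to `"par"` or
#'   `"perp"`, one row per lag and component.
#' @export
decompose_msd <- function(displacements, theta, timestep_us) {
  check_number(timestep_us, "timestep_us")
  if (!is.finite(theta)) abort("`theta` must be a finite orientation.")
  out <- displacements |>
    dplyr::mutate(
      d_par = .data$dx_nm * cos(theta) + .data$dy_nm * sin(theta),
      d_perp = -.data$dx_nm * sin(theta) + .data$dy_nm * cos(theta)
    ) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      par = mean(.data$d_par^2) * 1e-6,
      perp = mean(.data$d_perp^2) * 1e-6,
      se_par = stats::sd(.data$d_par^2) / sqrt(dplyr::n()) * 1e-6,
      se_perp = stats::sd(.data$d_perp^2) / sqrt(dplyr::n()) * 1e-6,
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("par", "perp"), names_to = "component",
                        values_to = "msd_um2") |>
    dplyr::mutate(
      se_um2 = ifelse(.data$component == "par", .data$se_par, .data$se_perp),
      t_lag_us = .data$lag * timestep_us
    ) |>
    dplyr::select("lag", "t_lag_us", "msd_um2", "se_um2", "n_pairs",
                  "component")
  new_msd_result(out, timestep_us)
}

#' Fit a diffusion model to an MSD curve
#'
#' Linear model: ordinary least squares of `MSD = 2 d D t_lag + b` on the
#' first `n_points` lags, where `d` is the dimensionality (2 for the
#' isotropic 2D MSD, giving `MSD = 4 D t + b`; 1 for a projected component,
#' giving `MSD = 2 D t + b`). The intercept `b` absorbs the static error
#' (localization noise, positive contribution `2 d sigma^2`... reported with
#' its sign) and the dynamic error (motion blur, negative contribution).
#'
#' Power law: `MSD = 2 K t_lag^alpha + b` over the first `n_lags` lags. The
#' default `method = "two_step"` follows the mapping procedure: `b` is first
#' fixed by a linear fit through the two initial points, then `alpha` is the
#' slope of `ln(MSD - b)` against `ln(t_lag)` (lags with `MSD <= b` are
#' dropped with a warning). This is exact for normal diffusion (`alpha = 1`)
#' and approximate otherwise; `method = "nls"` fits all three parameters by
#' nonlinear least squares instead.
#'
#' @param msd An `msd_result` (filter to a single component first).
#' @param n_points Number of initial lags for the linear fit.
#' @param dimensionality 2 (isotropic) or 1 (projected component).
#' @param model `"linear"` or `"powerlaw"`.
#' @param n_lags Number of initial lags for the power-law fit.
#' @param method Power-law fitting route, `"two_step"` or `"nls"`.
#' @return An `msd_fit` object; see [tidy.msd_fit()] and
#'   [glance.msd_fit()].
#' @examples
#' msd <- tibble::tibble(lag = 1:4, t_lag_us = (1:4) * 307.5,
#'                       msd_um2 = 4 * 90 * (1:4) * 307.5e-6 + 0.004,
#'                       se_um2 = 0, n_pairs = 100, component = "iso")
#' fit_msd(msd, dimensionality = 2)$D   # 90
#' @export
fit_msd <- function(msd, n_points = 4L, dimensionality = 2L,
                    model = c("linear", "powerlaw"), n_lags = 6L,
                    method = c("two_step", "nls")) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (length(unique(msd$component)) > 1L) {
    abort("`msd` mixes components; filter to one before fitting.")
  }
  msd <- dplyr::arrange(msd, .data$lag)
  t_s <- msd$t_lag_us * 1e-6
  y <- msd$msd_um2

  if (model == "linear") {
    if (nrow(msd) < n_points) {
      abort(sprintf("need >= %d lags for the linear fit.", n_points))
    }
    i <- seq_len(n_points)
    fit <- lm(y[i] ~ t_s[i])
    ci <- suppressMessages(confint(fit))
    slope <- unname(coef(fit)[2])
    out <- list(
      model = "linear",
      dimensionality = dimensionality,
      D = slope / (2 * dimensionality),
      b = unname(coef(fit)[1]),
      ci_D = unname(ci[2, ]) / (2 * dimensionality),
      ci_b = unname(ci[1, ]),
      n_points = n_points,
      r_squared = summary(fit)$r.squared,
      fit = fit
    )
    return(structure(out, class = "msd_fit"))
  }

  # power law
  if (nrow(msd) < max(2L, min(n_lags, 4L))) {
    abort("need at least the first two lags for the power-law fit.")
  }
  i <- seq_len(min(n_lags, nrow(msd)))
  b2 <- {
    sl <- (y[2] - y[1]) / (t_s[2] - t_s[1])
    y[1] - sl * t_s[1]
  }
  if (method == "two_step") {
    use <- i[y[i] > b2]
    if (length(use) < length(i)) {
      warn(sprintf("dropping %d lag(s) with MSD <= fitted intercept.",
                   length(i) - length(use)))
    }
    if (length(use) < 2L) abort("too few lags above the intercept.")
    lf <- lm(log(y[use] - b2) ~ log(t_s[use]))
    alpha <- unname(coef(lf)[2])
    K <- exp(unname(coef(lf)[1])) / 2
    ci_a <- unname(suppressMessages(confint(lf))[2, ])
    fit <- lf
    b_out <- b2
  } else {
    start <- list(K = max((y[2] - y[1]) / (2 * (t_s[2] - t_s[1])), 1e-6),
                  alpha = 1, b = b2)
    fit <- minpack.lm::nlsLM(
      y[i] ~ 2 * K * t_s[i]^alpha + b,
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- coef(fit)
    alpha <- unname(cf["alpha"])
    K <- unname(cf["K"])
    b_out <- unname(cf["b"])
    se_a <- tryCatch(summary(fit)$coefficients["alpha", "Std. Error"],
                     error = function(e) NA_real_)
    ci_a <- alpha + c(-1.96, 1.96) * se_a
  }
  structure(
    list(
      model = "powerlaw", dimensionality = dimensionality,
      K = K, alpha = alpha, b = b_out, ci_alpha = ci_a,
      n_points = length(i), method = method, fit = fit
    ),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf(
      "<msd_fit> MSD = %d D t + b: D = %.4g um^2/s (95%% CI %.4g-%.4g), b = %.3g um^2\n",
      2 * x$dimensionality, x$D, x$ci_D[1], x$ci_D[2], x$b
    ))
  } else {
    cat(sprintf(
      "<msd_fit> MSD = 2 K t^alpha + b: alpha = %.3f, K = %.4g, b = %.3g um^2 (%s)\n",
      x$alpha, x$K, x$b, x$method
    ))
  }
  invisible(x)
}

#' Per-track apparent diffusion coefficients
#'
#' Estimates an apparent `D` for each sufficiently long trajectory from its
#' own MSD over the first `n_points` lags, using the same linear model as
#' [fit_msd()]. Short tracks are excluded, not an error.
#'
#' @param trajectories Trajectory tibble.
#' @param timestep_us Acquisition timestep.
#' @param min_length Minimum track duration in timesteps (last minus first
#'   timepoint).
#' @param n_points Lags used in the per-track fit.
#' @param dimensionality As in [fit_msd()].
#' @return A tibble: `track_id`, `n_detections`, `duration`, `D_um2s`, `b`.
#' @export
apparent_d <- function(trajectories, timestep_us, min_length = 12L,
                       n_points = 4L, dimensionality = 2L) {
  check_number(timestep_us, "timestep_us")
  det <- trajectories
  if ("skipped" %in% names(det)) det <- det[!det$skipped, ]
  det <- det[is.finite(det$x_nm), ]
  keep <- det |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_detections = dplyr::n(),
      duration = max(.data$timepoint) - min(.data$timepoint),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$duration >= min_length)
  purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    id <- keep$track_id[i]
    tr <- det[det$track_id == id, ]
    disp <- compute_displacements(tr, seq_len(n_points))
    pl <- disp |>
      dplyr::group_by(.data$lag) |>
      dplyr::summarise(msd = mean((.data$dx_nm^2 + .data$dy_nm^2) * 1e-6),
                       .groups = "drop")
    if (nrow(pl) < 2L) return(NULL)
    t_s <- pl$lag * timestep_us * 1e-6
    fit <- lm(pl$msd ~ t_s)
    tibble::tibble(
      track_id = id,
      n_detections = keep$n_detections[i],
      duration = keep$duration[i],
      D_um2s = unname(coef(fit)[2]) / (2 * dimensionality),
      b = unname(coef(fit)[1])
    )
  })
}

#' Pooled diffusion coefficient with a track-bootstrap confidence interval
#'
#' Estimates `D` exactly as [fit_msd()] (OLS on the first `n_points` pooled
#' MSD lags) and attaches a percentile confidence interval from a bootstrap
#' over whole tracks. Squared displacements from overlapping pairs of one
#' track are strongly correlated, so resampling tracks -- the independent
#' units -- gives honest uncertainty where the naive per-point OLS interval
#' is too narrow.
#'
#' @param trajectories Trajectory tibble.
#' @param timestep_us Acquisition timestep (microseconds).
#' @param n_points Lags used in the fit.
#' @param dimensionality As in [fit_msd()].
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional seed for the resampling.
#' @return A list: `D` (um^2/s), `b` (um^2), `ci_D`, `ci_b` (percentile
#'   intervals), `n_tracks`, `boot_D` (the replicate estimates).
#' @export
estimate_d <- function(trajectories, timestep_us, n_points = 4L,
                       dimensionality = 2L, n_boot = 200L, conf = 0.95,
                       seed = NULL) {
  check_number(timestep_us, "timestep_us")
  disp <- compute_displacements(trajectories, seq_len(n_points))
  if (!nrow(disp)) abort("no displacements available.")
  cell <- disp |>
    dplyr::group_by(.data$track_id, .data$lag) |>
    dplyr::summarise(
      s = sum((.data$dx_nm^2 + .data$dy_nm^2) * 1e-6),
      n = dplyr::n(), .groups = "drop"
    )
  ids <- unique(cell$track_id)
  s_m <- matrix(0, length(ids), n_points)
  n_m <- matrix(0, length(ids), n_points)
  s_m[cbind(match(cell$track_id, ids), cell$lag)] <- cell$s
  n_m[cbind(match(cell$track_id, ids), cell$lag)] <- cell$n
  t_s <- seq_len(n_points) * timestep_us * 1e-6
  fit_d <- function(rows) {
    msd <- colSums(s_m[rows, , drop = FALSE]) /
      colSums(n_m[rows, , drop = FALSE])
    cf <- coef(lm(msd ~ t_s))
    c(D = unname(cf[2]) / (2 * dimensionality), b = unname(cf[1]))
  }
  est <- fit_d(seq_along(ids))
  boot <- with_seed_maybe(seed, {
    vapply(seq_len(n_boot), function(i) {
      fit_d(sample.int(length(ids), replace = TRUE))
    }, numeric(2))
  })
  a <- (1 - conf) / 2
  list(
    D = est[["D"]], b = est[["b"]],
    ci_D = unname(stats::quantile(boot[1, ], c(a, 1 - a), na.rm = TRUE)),
    ci_b = unname(stats::quantile(boot[2, ], c(a, 1 - a), na.rm = TRUE)),
    n_tracks = length(ids),
    boot_D = boot[1, ]
  )
}
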