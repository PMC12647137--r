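#' Tidy an MSD fit
#'
#' @param x An `msd_fit` from [fit_msd()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.msd_fit <- function(x, ...) {
  if (x$model == "linear") {
    tibble::tibble(
      term = c("D", "b"),
      estimate = c(x$D, x$b),
      conf.low = c(x$ci_D[1], x$ci_b[1]),
      conf.high = c(x$ci_D[2], x$ci_b[2])
    )
  } else {
    tibble::tibble(
      term = c("K", "alpha", "b"),
      estimate = c(x$K, x$alpha, x$b),
      conf.low = c(NA, x$ci_alpha[1], NA),
      conf.high = c(NA, x$ci_alpha[2], NA)
    )
  }
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  if (x$model == "linear") {
    tibble::tibble(
      model = "linear", dimensionality = x$dimensionality,
      D_um2s = x$D, b_um2 = x$b, r.squared = x$r_squared,
      n_points = x$n_points
    )
  } else {
    tibble::tibble(
      model = "powerlaw", dimensionality = x$dimensionality,
      K = x$K, alpha = x$alpha, b_um2 = x$b, n_points = x$n_points,
      method = x$method
    )
  }
}

#' Tidy a FRET kinetics fit
#'
#' @param x A `fret_kinetics` from [fit_fret_kinetics()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` for the opening/closing rates and the derived parameters.
#' @export
tidy.fret_kinetics <- function(x, ...) {
  est <- c(k_open = x$k_open, k_close = x$k_close, k_eff = x$k_eff,
           F_c = x$F_c)
  se <- x$se[names(est)]
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - 1.96 * se),
    conf.high = unname(est + 1.96 * se)
  )
}

#' @rdname tidy.fret_kinetics
#' @export
glance.fret_kinetics <- function(x, ...) {
  tibble::tibble(
    k_open = x$k_open, k_close = x$k_close, k_eff = x$k_eff, F_c = x$F_c,
    flagged = x$flagged, n_lags = nrow(x$pcc)
  )
}
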