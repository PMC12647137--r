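#' FRET efficiency from channel intensities
#'
#' `E = I_A / (I_A + I_D)`, the raw acceptor fraction of the summed
#' two-channel intensity (no gamma or crosstalk correction). Timepoints with
#' non-positive total intensity get `NA` (treated as skipped downstream).
#'
#' @param I_D,I_A Donor and acceptor intensities (photons).
#' @return FRET efficiency vector.
#' @examples
#' fret_efficiency(100, 100)  # 0.5
#' fret_efficiency(0, 80)     # 1
#' @export
fret_efficiency <- function(I_D, I_A) {
  total <- I_D + I_A
  ifelse(is.finite(total) & total > 0, I_A / total, NA_real_)
}

#' Classify FRET observations into states
#'
#' Observations with `E > closed_threshold` are closed (high FRET), those
#' with `E < open_threshold` are open; intermediate efficiencies are excluded
#' from kinetics, and missing values are skips.
#'
#' @param E FRET efficiencies.
#' @param closed_threshold,open_threshold Classification thresholds.
#' @return Character vector: `"closed"`, `"open"`, `"excluded"`, `"skipped"`.
#' @export
classify_fret <- function(E, closed_threshold = 0.65, open_threshold = 0.45) {
  dplyr::case_when(
    !is.finite(E) ~ "skipped",
    E > closed_threshold ~ "closed",
    E < open_threshold ~ "open",
    TRUE ~ "excluded"
  )
}

#' Pair donor- and acceptor-channel localizations
#'
#' Maps acceptor localizations into the donor coordinate system (identity by
#' default, or a user mapping function) and matches the two channels per
#' frame, closest pairs first, within `radius_px`. Matched timepoints carry
#' both intensities; a detection in one channel only keeps the timepoint with
#' the other channel's intensity at zero (background-subtracted non-detection).
#'
#' @param donor_locs,acceptor_locs Localization tables ([localize_frames()]).
#' @param radius_px Pairing radius in pixels.
#' @param mapping Optional function `(x_px, y_px) -> list(x_px, y_px)`
#'   mapping acceptor coordinates into the donor frame.
#' @return A localization-style tibble with `frame`, `x_px`, `y_px`,
#'   `I_D`, `I_A`, `photons` (= `I_D + I_A`, used for linking),
#'   `precision_nm`, `channel` (`"both"`, `"donor"`, `"acceptor"`).
#' @export
pair_channels <- function(donor_locs, acceptor_locs, radius_px = 2,
                          mapping = NULL) {
  acc <- acceptor_locs
  if (!is.null(mapping)) {
    m <- mapping(acc$x_px, acc$y_px)
    acc$x_px <- m[[1]]
    acc$y_px <- m[[2]]
  }
  frames <- sort(unique(c(donor_locs$frame, acc$frame)))
  purrr::map_dfr(frames, function(f) {
    d <- donor_locs[donor_locs$frame == f, ]
    a <- acc[acc$frame == f, ]
    nd <- nrow(d); na <- nrow(a)
    pair_d <- integer(); pair_a <- integer()
    if (nd && na) {
      dist2 <- outer(d$x_px, a$x_px, "-")^2 + outer(d$y_px, a$y_px, "-")^2
      cand <- which(dist2 <= radius_px^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist2[cand])
        cand <- cand[ord, , drop = FALSE]
        used_d <- logical(nd); used_a <- logical(na)
        for (i in seq_len(nrow(cand))) {
          di <- cand[i, 1]; ai <- cand[i, 2]
          if (!used_d[di] && !used_a[ai]) {
            used_d[di] <- TRUE; used_a[ai] <- TRUE
            pair_d <- c(pair_d, di); pair_a <- c(pair_a, ai)
          }
        }
      }
    }
    both <- tibble::tibble(
      frame = f,
      x_px = if (length(pair_d)) d$x_px[pair_d] else numeric(),
      y_px = if (length(pair_d)) d$y_px[pair_d] else numeric(),
      I_D = if (length(pair_d)) d$photons[pair_d] else numeric(),
      I_A = if (length(pair_a)) a$photons[pair_a] else numeric(),
      precision_nm = if (length(pair_d)) d$precision_nm[pair_d] else numeric(),
      channel = rep("both", length(pair_d))
    )
    d_only <- d[setdiff(seq_len(nd), pair_d), ]
    a_only <- a[setdiff(seq_len(na), pair_a), ]
    dplyr::bind_rows(
      both,
      tibble::tibble(frame = f, x_px = d_only$x_px, y_px = d_only$y_px,
                     I_D = d_only$photons, I_A = 0,
                     precision_nm = d_only$precision_nm, channel = "donor"),
      tibble::tibble(frame = f, x_px = a_only$x_px, y_px = a_only$y_px,
                     I_D = 0, I_A = a_only$photons,
                     precision_nm = a_only$precision_nm, channel = "acceptor")
    )
  }) |>
    dplyr::mutate(photons = .data$I_D + .data$I_A)
}

#' Build smFRET time traces from linked trails
#'
#' Attaches the paired channel intensities to each trail timepoint and
#' classifies the FRET state. Skipped slots stay in the trace as state
#' `"skipped"`.
#'
#' @param trails Output of [link_trails()] run on [pair_channels()] output.
#' @param paired The [pair_channels()] table the trails were linked from.
#' @param closed_threshold,open_threshold Passed to [classify_fret()].
#' @return A trace tibble: `track_id`, `timepoint` (slot), `I_D`, `I_A`,
#'   `E`, `state`.
#' @export
fret_traces <- function(trails, paired, closed_threshold = 0.65,
                        open_threshold = 0.45) {
  out <- tibble::tibble(
    track_id = trails$trail_id,
    timepoint = trails$slot,
    I_D = paired$I_D[trails$loc_row],
    I_A = paired$I_A[trails$loc_row]
  )
  out$E <- fret_efficiency(out$I_D, out$I_A)
  out$state <- classify_fret(out$E, closed_threshold, open_threshold)
  out
}

#' Time-correlated conditional probability of staying closed
#'
#' For every observation in the closed state, counts whether the same
#' molecule is closed or open `lag` timesteps later:
#' `P_cc(t_lag) = P(closed at t + t_lag | closed at t)`. Excluded and
#' skipped timepoints enter neither numerator nor denominator. For a
#' two-state chain the expectation is
#' `P_cc = (1 - F_c) exp(-k_eff t_lag) + F_c`, decaying from 1 at lag 0 to
#' the equilibrium closed fraction. Standard errors come from a bootstrap
#' over traces.
#'
#' @param traces Trace tibble with `track_id`, `timepoint`, `state` (see
#'   [fret_traces()]; any table with those columns works).
#' @param timestep_us Acquisition timestep (microseconds).
#' @param max_lag Largest lag in timesteps.
#' @param n_boot Bootstrap replicates (0 disables).
#' @param seed Optional seed for the bootstrap.
#' @return A `pcc_result` tibble: `lag`, `t_lag_us`, `p_cc`, `se`,
#'   `n_pairs`. Lags with no qualifying pairs are omitted.
#' @export
fret_pcc <- function(traces, timestep_us, max_lag = 10L, n_boot = 100L,
                     seed = NULL) {
  check_number(timestep_us, "timestep_us")
  cl <- traces[traces$state %in% c("closed", "open"),
               c("track_id", "timepoint", "state")]
  lags <- 0:max_lag
  # per-track, per-lag pair counts (numerator and denominator)
  counts <- purrr::map_dfr(lags, function(l) {
    start <- cl[cl$state == "closed", ]
    later <- dplyr::transmute(
      cl,
      track_id = .data$track_id,
      timepoint = .data$timepoint - l,
      state1 = .data$state
    )
    dplyr::inner_join(start, later, by = c("track_id", "timepoint")) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(
        num = sum(.data$state1 == "closed"),
        den = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(lag = l)
  })
  pooled <- counts |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(num = sum(.data$num), den = sum(.data$den),
                     .groups = "drop") |>
    dplyr::filter(.data$den > 0) |>
    dplyr::mutate(p_cc = .data$num / .data$den)

  se <- rep(NA_real_, nrow(pooled))
  if (n_boot > 0) {
    ids <- unique(cl$track_id)
    wide <- counts |>
      tidyr::pivot_wider(names_from = "lag",
                         values_from = c("num", "den"), values_fill = 0)
    wide <- wide[match(ids, wide$track_id), ]
    num_m <- as.matrix(wide[, paste0("num_", pooled$lag)])
    den_m <- as.matrix(wide[, paste0("den_", pooled$lag)])
    num_m[is.na(num_m)] <- 0
    den_m[is.na(den_m)] <- 0
    boot <- with_seed_maybe(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample.int(length(ids), replace = TRUE)
        colSums(num_m[take, , drop = FALSE]) /
          pmax(colSums(den_m[take, , drop = FALSE]), 1)
      }, numeric(nrow(pooled)))
    })
    se <- apply(matrix(boot, nrow = nrow(pooled)), 1, stats::sd)
  }
  out <- tibble::tibble(
    lag = pooled$lag,
    t_lag_us = pooled$lag * timestep_us,
    p_cc = pooled$p_cc,
    se = se,
    n_pairs = pooled$den
  )
  tibble::new_tibble(out, timestep_us = timestep_us, class = "pcc_result")
}

#' Fit two-state kinetics to a conditional-probability decay
#'
#' Nonlinear least-squares fit of
#' `P_cc = (1 - F_c) exp(-k_eff t_lag) + F_c`. The fitted effective rate and
#' equilibrium closed fraction convert to the opening and closing rates via
#' `k_open = (1 - F_c) k_eff` and `k_close = F_c k_eff`, so
#' `k_eff = k_open + k_close` and `F_c = k_close / k_eff` hold exactly on
#' the outputs. Confidence intervals are propagated from the fit covariance
#' by the delta method. A curve that does not decay (`F_c` pinned near 1)
#' leaves the rates unidentifiable and is flagged.
#'
#' @param pcc A `pcc_result` from [fret_pcc()] with at least 4 lags.
#' @return A `fret_kinetics` object; see [tidy.fret_kinetics()].
#' @export
fit_fret_kinetics <- function(pcc) {
  if (nrow(pcc) < 4L) abort("need >= 4 lags to fit kinetics.")
  t_s <- pcc$t_lag_us * 1e-6
  p <- pcc$p_cc
  f0 <- max(min(min(p), 0.99), 0.01)
  drop0 <- p - f0
  k0 <- {
    pos <- which(drop0 > 0.05 * (1 - f0) & t_s > 0)
    if (length(pos) > 1) {
      sl <- coef(lm(log(drop0[pos]) ~ t_s[pos]))[2]
      max(-unname(sl), 1 / max(t_s))
    } else {
      1 / max(t_s)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ (1 - Fc) * exp(-keff * t_s) + Fc,
      start = list(Fc = f0, keff = k0),
      lower = c(Fc = 0, keff = 0), upper = c(Fc = 1, keff = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("kinetics poorly identified (non-decaying or noisy P_cc curve).")
    return(structure(
      list(k_open = NA_real_, k_close = NA_real_, k_eff = NA_real_,
           F_c = NA_real_,
           se = c(k_open = NA_real_, k_close = NA_real_, k_eff = NA_real_,
                  F_c = NA_real_),
           ci_k_open = c(NA_real_, NA_real_),
           ci_k_close = c(NA_real_, NA_real_),
           flagged = TRUE, fit = NULL, pcc = pcc),
      class = "fret_kinetics"
    ))
  }
  cf <- coef(fit)
  Fc <- unname(cf["Fc"])
  keff <- unname(cf["keff"])
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  # delta method: k_open = (1-Fc) keff, k_close = Fc keff
  g_open <- c(-keff, 1 - Fc)   # d/dFc, d/dkeff
  g_close <- c(keff, Fc)
  se_open <- sqrt(drop(t(g_open) %*% V %*% g_open))
  se_close <- sqrt(drop(t(g_close) %*% V %*% g_close))
  se_keff <- sqrt(V[2, 2])
  se_fc <- sqrt(V[1, 1])
  flagged <- !is.finite(se_keff) || Fc > 0.99 ||
    (is.finite(se_keff) && se_keff > keff)
  if (flagged) {
    warn("kinetics poorly identified (non-decaying or noisy P_cc curve).")
  }
  structure(
    list(
      k_open = (1 - Fc) * keff,
      k_close = Fc * keff,
      k_eff = keff,
      F_c = Fc,
      se = c(k_open = se_open, k_close = se_close, k_eff = se_keff,
             F_c = se_fc),
      ci_k_open = (1 - Fc) * keff + c(-1.96, 1.96) * se_open,
      ci_k_close = Fc * keff + c(-1.96, 1.96) * se_close,
      flagged = flagged,
      fit = fit,
      pcc = pcc
    ),
    class = "fret_kinetics"
  )
}

#' @export
print.fret_kinetics <- function(x, ...) {
  cat(sprintf(
    "<fret_kinetics> k_open = %.4g /s, k_close = %.4g /s (k_eff = %.4g, F_c = %.3f)%s\n",
    x$k_open, x$k_close, x$k_eff, x$F_c,
    if (x$flagged) " [flagged]" else ""
  ))
  invisible(x)
}

#' Joint FRET-diffusivity distribution of single molecules
#'
#' Pairs each sufficiently long trajectory's mean FRET efficiency (over
#' classifiable timepoints) with its apparent diffusion coefficient,
#' resolving molecular populations that differ in conformation and mobility.
#'
#' @param traces Trace tibble (see [fret_traces()]).
#' @param trajectories Matching trajectory tibble (same `track_id`s).
#' @param timestep_us Acquisition timestep.
#' @param min_length Minimum track duration in timesteps.
#' @return A tibble: `track_id`, `mean_E`, `D_um2s`, `n_detections`.
#' @export
fret_d_distribution <- function(traces, trajectories, timestep_us,
                                min_length = 12L) {
  dd <- apparent_d(trajectories, timestep_us, min_length = min_length)
  me <- traces |>
    dplyr::filter(.data$state %in% c("closed", "open", "excluded"),
                  is.finite(.data$E)) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mean_E = mean(.data$E), .groups = "drop")
  dd |>
    dplyr::inner_join(me, by = "track_id") |>
    dplyr::select("track_id", "mean_E", "D_um2s", "n_detections")
}
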