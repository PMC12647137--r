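# Small-chip configuration for fast rendering tests.
tiny_config <- function(n_timepoints = 10L, background_rate = 0.3, ...) {
  acq_config(exposure_us = 300, n_timepoints = n_timepoints,
             chip_rows = 200L, chip_cols = 64L,
             background_rate = background_rate, ...)
}

# Synthetic localization table for a vertical streak: one detection per TRUE
# slot, at rows y0 + delta * slot, columns x0 (+ optional jitter vectors).
make_streak_locs <- function(y0, x0, slots, delta = 15, frame = 1L,
                             dx = 0, dy = 0, photons = 500) {
  idx <- which(slots) - 1L
  tibble::tibble(
    frame = frame,
    x_px = x0 + rep_len(dx, length(idx)),
    y_px = y0 + delta * idx + rep_len(dy, length(idx)),
    photons = photons,
    background = 0.5,
    sigma_px = 1,
    precision_nm = 20
  )
}

# Trajectory table from ideal per-timepoint positions (no skips).
make_traj <- function(x_nm, y_nm, track_id = 1L) {
  tibble::tibble(
    track_id = track_id,
    timepoint = seq_along(x_nm),
    x_nm = x_nm,
    y_nm = y_nm,
    skipped = FALSE
  )
}

# Brute-force window-uniqueness oracle (independent of validate_multiples).
windows_unique_oracle <- function(m, k) {
  if (k > length(m)) return(TRUE)
  wins <- lapply(seq_len(length(m) - k + 1L), function(i) m[i:(i + k - 1L)])
  for (i in seq_along(wins)) {
    for (j in seq_along(wins)) {
      if (i < j && identical(wins[[i]], wins[[j]])) return(FALSE)
    }
  }
  TRUE
}
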