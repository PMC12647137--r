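#' Reference 33-exposure variable-shift sequence
#'
#' The package's stock shift-multiple sequence for variable-shift
#' acquisitions: 33 exposures with multiples 1-4 summing to 68 base shifts,
#' designed so that every window of 4 consecutive multiples is unique, which
#' makes trail patterns of >= 4 timepoints unambiguous to align.
#'
#' @return Integer vector of 33 shift multiples.
#' @examples
#' m <- vs_master_sequence()
#' sum(m)                      # 68
#' validate_multiples(m, 4)    # TRUE
#' @export
vs_master_sequence <- function() {
  as.integer(strsplit("431232213331411131122233231321211", "")[[1]])
}

#' Translate shift multiples into a detection/gap barcode
#'
#' Each exposure contributes a detection ("1") followed by `m - 1` gaps
#' ("0"): a multiple of 4 writes "1000", 3 writes "100", 2 writes "10" and 1
#' writes "1". The barcode length equals the total number of base shifts and
#' its "1" count equals the number of exposures.
#'
#' @param multiples Integer vector of shift multiples in 1..4.
#' @return A single binary string.
#' @examples
#' translate_multiples(c(2, 1, 3))  # "101100" -> "10" "1" "100"
#' @export
translate_multiples <- function(multiples) {
  multiples <- as.integer(multiples)
  if (!length(multiples) || anyNA(multiples) ||
      any(multiples < 1L | multiples > 4L)) {
    abort("`multiples` must be integers in 1..4.")
  }
  paste(vapply(multiples, function(m) {
    paste0("1", strrep("0", m - 1L))
  }, character(1)), collapse = "")
}

#' Parse a barcode back into shift multiples
#'
#' Exact inverse of [translate_multiples()]: the gaps after each detection
#' (plus any trailing gaps) give the multiples.
#'
#' @param barcode Binary string starting with "1".
#' @return Integer vector of multiples.
#' @export
parse_barcode <- function(barcode) {
  bits <- strsplit(barcode, "")[[1]]
  if (!length(bits) || bits[1] != "1" || !all(bits %in% c("0", "1"))) {
    abort("`barcode` must be a binary string starting with \"1\".")
  }
  ones <- which(bits == "1")
  as.integer(diff(c(ones, length(bits) + 1L)))
}

#' Check window uniqueness of a shift sequence
#'
#' A variable-shift sequence is decodable when every window of `k`
#' consecutive multiples is unique, so that any observed run of `k` or more
#' timepoints pins down its position in the sequence.
#'
#' @param multiples Integer vector of shift multiples.
#' @param k Window length (default 4).
#' @return `TRUE`/`FALSE`, with the duplicated windows (as strings) in
#'   attribute `"duplicates"`. A `k` longer than the sequence is trivially
#'   valid (with a warning).
#' @export
validate_multiples <- function(multiples, k = 4L) {
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  n <- length(multiples)
  if (k > n) {
    warn("`k` exceeds the sequence length; trivially unique.")
    return(structure(TRUE, duplicates = character()))
  }
  wins <- vapply(seq_len(n - k + 1L), function(i) {
    paste(multiples[i:(i + k - 1L)], collapse = ",")
  }, character(1))
  dup <- unique(wins[duplicated(wins)])
  structure(length(dup) == 0L, duplicates = dup)
}

#' Design a decodable shift sequence
#'
#' Randomized depth-first construction with backtracking: multiples are drawn
#' from `m_range` one exposure at a time, rejecting any choice that repeats a
#' length-`k` window or overruns the total-shift budget (e.g. the chip
#' height in units of the shift height). Any sequence passing
#' [validate_multiples()] is acceptable; no optimality is claimed.
#'
#' @param n_exposures Sequence length.
#' @param k Window-uniqueness order.
#' @param m_range Candidate multiples.
#' @param max_total Optional cap on `sum(multiples)`.
#' @param seed Optional integer seed.
#' @param max_restarts Restarts before giving up.
#' @return Integer vector of multiples (passes `validate_multiples(., k)`).
#' @export
design_multiples <- function(n_exposures, k = 4L, m_range = 1:4,
                             max_total = NULL, seed = NULL,
                             max_restarts = 200L) {
  n_exposures <- as.integer(n_exposures)
  k <- as.integer(k)
  m_range <- sort(unique(as.integer(m_range)))
  if (any(m_range < 1L)) abort("`m_range` must be positive.")
  if (!is.null(max_total) &&
      max_total < n_exposures * min(m_range)) {
    abort("`max_total` is infeasible for `n_exposures`.")
  }
  with_seed_maybe(seed, {
    for (restart in seq_len(max_restarts)) {
      seq_m <- integer(0)
      seen <- character(0)
      repeat {
        if (length(seq_m) == n_exposures) {
          return(seq_m)
        }
        left <- n_exposures - length(seq_m) - 1L
        cands <- sample(m_range)
        placed <- FALSE
        for (m in cands) {
          if (!is.null(max_total) &&
              sum(seq_m) + m + left * min(m_range) > max_total) next
          trial <- c(seq_m, m)
          if (length(trial) >= k) {
            w <- paste(tail(trial, k), collapse = ",")
            if (w %in% seen) next
            seen <- c(seen, w)
          }
          seq_m <- trial
          placed <- TRUE
          break
        }
        if (!placed) break  # dead end -> restart
      }
    }
    abort(sprintf(
      "no valid sequence found (n = %d, k = %d, multiples {%s}%s).",
      n_exposures, k, paste(m_range, collapse = ","),
      if (is.null(max_total)) "" else sprintf(", total <= %d", max_total)
    ))
  })
}

#' Align an observed detection/gap pattern to the master barcode
#'
#' Computes the Hamming distance between the observed pattern and the master
#' barcode at every admissible start offset (offsets where the master has a
#' detection, since a trail begins with one). The alignment is accepted when
#' a single offset uniquely achieves the smallest distance and that distance
#' is below 30% of the observed length. Missed (1 -> 0) and spurious
#' (0 -> 1) detections count equally as mismatches.
#'
#' @param observed Binary string (a trail's detection/gap pattern; begins and
#'   ends with "1").
#' @param master Master barcode string (see [translate_multiples()]).
#' @param max_mismatch_frac Acceptance threshold as a fraction of the
#'   observed length.
#' @return One-row tibble: `offset` (0-based slot in the master), `distance`,
#'   `observed_length`, `accepted`. All per-offset distances are attached as
#'   attribute `"scan"`.
#' @export
align_pattern <- function(observed, master, max_mismatch_frac = 0.30) {
  obs <- strsplit(observed, "")[[1]]
  mas <- strsplit(master, "")[[1]]
  if (!all(obs %in% c("0", "1")) || !all(mas %in% c("0", "1"))) {
    abort("patterns must be binary strings.")
  }
  L <- length(obs)
  starts <- which(mas == "1") - 1L
  starts <- starts[starts + L <= length(mas)]
  unaligned <- tibble::tibble(
    offset = NA_integer_, distance = NA_integer_,
    observed_length = L, accepted = FALSE
  )
  if (L > length(mas) || !length(starts)) {
    return(structure(unaligned, scan = tibble::tibble(
      offset = integer(), distance = integer()
    )))
  }
  obs_i <- obs == "1"
  d <- vapply(starts, function(s) {
    sum(obs_i != (mas[(s + 1):(s + L)] == "1"))
  }, integer(1))
  best <- min(d)
  unique_min <- sum(d == best) == 1L
  accepted <- unique_min && best < max_mismatch_frac * L
  out <- tibble::tibble(
    offset = if (unique_min) starts[which.min(d)] else NA_integer_,
    distance = best,
    observed_length = L,
    accepted = accepted
  )
  structure(out, scan = tibble::tibble(offset = starts, distance = d))
}

#' Align linked trails to the master barcode
#'
#' Builds each trail's observed detection/gap pattern (detections are "1",
#' skip placeholders "0"; a trail begins and ends with a detection by
#' construction) and aligns it with [align_pattern()]. Trails with fewer than
#' `min_detections` detections are reported unaligned: short patterns carry
#' too little structure to place reliably.
#'
#' @param trails Output of [link_trails()] (variable-shift mode).
#' @param master Master barcode string.
#' @param min_detections Minimum detections required to attempt alignment.
#' @param max_mismatch_frac Acceptance threshold (fraction of the observed
#'   length).
#' @return A tibble: `trail_id`, `offset`, `distance`, `observed_length`,
#'   `n_detections`, `accepted`.
#' @export
align_trails <- function(trails, master, min_detections = 5L,
                         max_mismatch_frac = 0.30) {
  empty <- tibble::tibble(
    trail_id = integer(), offset = integer(), distance = integer(),
    observed_length = integer(), n_detections = integer(),
    accepted = logical()
  )
  if (!nrow(trails)) return(empty)
  pats <- trails |>
    dplyr::group_by(.data$trail_id) |>
    dplyr::arrange(.data$slot, .by_group = TRUE) |>
    dplyr::summarise(
      pattern = paste(as.integer(.data$detected), collapse = ""),
      n_detections = sum(.data$detected),
      .groups = "drop"
    )
  res <- purrr::map2_dfr(pats$pattern, pats$n_detections, function(p, nd) {
    if (nd >= min_detections) {
      align_pattern(p, master, max_mismatch_frac)
    } else {
      tibble::tibble(offset = NA_integer_, distance = NA_integer_,
                     observed_length = nchar(p), accepted = FALSE)
    }
  })
  dplyr::bind_cols(pats["trail_id"], res,
                   pats["n_detections"]) |>
    dplyr::select("trail_id", "offset", "distance", "observed_length",
                  "n_detections", "accepted")
}

#' Recover absolute positions from aligned trails
#'
#' For every accepted alignment, each detected slot is placed at its global
#' slot `offset + slot` in the master sequence; its absolute vertical
#' coordinate is the chip row minus `shift_height * global_slot` (the
#' patterned shifts executed before that exposure), converted to nm. The
#' slot's exposure index in the master sequence becomes the trajectory
#' timepoint, so timepoints are spaced by the (fixed) VS timestep. Detections
#' at master gap slots (spurious under the alignment) are dropped; master
#' detection slots missed in the trail appear as skipped rows.
#'
#' @param trails Output of [link_trails()].
#' @param alignments Output of [align_trails()].
#' @param multiples The master shift-multiple sequence.
#' @param config The [acq_config()] of the acquisition (pixel size, shift
#'   height, timestep).
#' @return A trajectory tibble in absolute sample coordinates: `track_id`,
#'   `frame`, `timepoint` (exposure index in the master sequence), `t_us`,
#'   `x_nm`, `y_nm`, `skipped`, `photons`, `precision_nm`.
#' @export
recover_absolute <- function(trails, alignments, multiples, config) {
  stopifnot(inherits(config, "acq_config"))
  master <- translate_multiples(multiples)
  mas <- strsplit(master, "")[[1]] == "1"
  exposure_of_slot <- cumsum(mas)          # slot (1-based) -> exposure index
  acc <- alignments[alignments$accepted, c("trail_id", "offset")]
  px <- config$pixel_nm
  delta <- config$shift_height

  trails |>
    dplyr::inner_join(acc, by = "trail_id") |>
    dplyr::mutate(global_slot = .data$offset + .data$slot) |>
    dplyr::filter(.data$global_slot < length(mas)) |>
    dplyr::mutate(
      on_exposure = mas[.data$global_slot + 1L],
      timepoint = exposure_of_slot[.data$global_slot + 1L]
    ) |>
    # keep exposure slots only: spurious detections at gap slots are dropped,
    # undetected exposure slots stay as skips
    dplyr::filter(.data$on_exposure) |>
    dplyr::transmute(
      track_id = .data$trail_id,
      frame = .data$frame,
      timepoint = .data$timepoint,
      t_us = (.data$timepoint - 1) * config$timestep_us,
      x_nm = ifelse(.data$detected, .data$x_px * px, NA_real_),
      y_nm = ifelse(.data$detected,
                    (.data$y_px - delta * .data$global_slot) * px,
                    NA_real_),
      skipped = !.data$detected,
      photons = ifelse(.data$detected, .data$photons, NA_real_),
      precision_nm = ifelse(.data$detected, .data$precision_nm, NA_real_)
    )
}
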