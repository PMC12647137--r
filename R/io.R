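#' Write and read frame stacks as 16-bit multi-page TIFF
#'
#' Frames are stored as one 16-bit page per readout frame. The acquisition
#' configuration is echoed into a YAML sidecar (`<path>.yaml`) so a stack
#' round-trips with its metadata; [read_frames()] restores it when the
#' sidecar is present.
#'
#' @param stack A `frame_stack` (see [render_frames()]).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mats <- lapply(stack$frames, function(m) {
    storage.mode(m) <- "double"
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  if (!is.null(stack$config)) {
    write_config(stack$config, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_frames
#' @param config Optional [acq_config()] overriding the sidecar.
#' @return For `read_frames()`: a `frame_stack` with integer count matrices
#'   (no ground truth).
#' @export
read_frames <- function(path, config = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  mats <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort(sprintf("not a readable TIFF: %s", path))
  )
  if (!is.list(mats)) mats <- list(mats)
  mats <- lapply(mats, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    storage.mode(m) <- "integer"
    m
  })
  side <- paste0(path, ".yaml")
  if (is.null(config) && file.exists(side)) config <- read_config(side)
  structure(list(frames = mats, config = config, truth = NULL),
            class = "frame_stack")
}

#' Write and read acquisition configurations as YAML
#'
#' @param config An [acq_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "acq_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  acq_config(
    n_timepoints = vals$n_timepoints,
    shift_multiples = vals$shift_multiples,
    shift_height = vals$shift_height,
    row_shift_us = vals$row_shift_us,
    timestep_us = vals$timestep_us,
    chip_rows = vals$chip_rows,
    chip_cols = vals$chip_cols,
    pixel_nm = vals$pixel_nm,
    em_gain = vals$em_gain,
    read_noise = vals$read_noise,
    background_rate = vals$background_rate,
    psf_sigma_px = vals$psf_sigma_px
  )
}

meta_header <- function(extra = character()) {
  c(
    sprintf("# streaktrack %s",
            as.character(utils::packageVersion("streaktrack"))),
    extra
  )
}

#' Write a table with a provenance header
#'
#' CSV writer used for all tabular interfaces (localizations, trajectories,
#' traces, alignments): rows are plain CSV preceded by `#` comment lines
#' carrying the package version, a content hash, and any caller-supplied
#' metadata (units, configuration echo). [read_table_csv()] skips the
#' header.
#'
#' @param x Data frame.
#' @param path File path.
#' @param meta Extra header lines (without the leading `#`).
#' @export
write_table_csv <- function(x, path, meta = character()) {
  hdr <- meta_header(c(
    sprintf("# content_hash: %s", rlang::hash(x)),
    if (length(meta)) paste("#", meta)
  ))
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write and read shift sequences as plain digit strings
#'
#' @param multiples Integer shift multiples.
#' @param path File path.
#' @export
write_sequence <- function(multiples, path) {
  writeLines(paste(multiples, collapse = ""), path)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  s <- trimws(readLines(path, n = 1L))
  if (!grepl("^[1-9]+$", s)) abort("sequence file must be a digit string.")
  as.integer(strsplit(s, "")[[1]])
}
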