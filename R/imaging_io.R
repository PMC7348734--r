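#' Construct a frame stack
#'
#' A frame stack holds one imaging session's raw multi-frame grayscale pixel
#' data: several exposures ("frames") of the same lightbox scene, captured to
#' average out frame-to-frame lighting flicker. Pixel values are unsigned
#' integers on a `bit_depth`-bit scale (12-bit by default: 0 = black,
#' 4095 = white).
#'
#' @param frames 3-D integer array, `frame x row x column`, or a single matrix
#'   (treated as one frame). All values must lie in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bits per pixel of the underlying data (default 12).
#' @param session_id Identifier of the imaging session.
#' @param capture_label Free-text label (camera settings, operator notes).
#'
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `bit_depth`, `max_value` (`2^bit_depth - 1`), `session_id`,
#'   `capture_label`.
#' @export
#' @examples
#' st <- frame_stack(array(1000L, c(3, 8, 8)), bit_depth = 12)
#' n_frames(st)
frame_stack <- function(frames, bit_depth = 12L, session_id = NA_character_,
                        capture_label = "") {
  if (is.matrix(frames)) {
    frames <- array(frames, c(1L, nrow(frames), ncol(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_format("`frames` must be a frame x row x column array or a matrix.")
  }
  if (dim(frames)[1] < 1L || any(dim(frames)[2:3] < 1L)) {
    stop_format("Empty frame stack: need at least one frame with pixels.")
  }
  if (anyNA(frames)) stop_format("Frame stack contains missing pixel values.")
  max_value <- bitwShiftL(1L, as.integer(bit_depth)) - 1L
  if (any(frames < 0L)) stop_format("Negative pixel values are not allowed.")
  if (any(frames > max_value)) {
    stop_format(sprintf(
      "Pixel values exceed the %d-bit full scale (%d): bit-depth mismatch.",
      bit_depth, max_value
    ))
  }
  storage.mode(frames) <- "integer"
  structure(
    list(
      frames = frames, bit_depth = as.integer(bit_depth),
      max_value = max_value, session_id = session_id,
      capture_label = capture_label
    ),
    class = "frame_stack"
  )
}

#' @rdname frame_stack
#' @param x A `frame_stack`.
#' @export
n_frames <- function(x) dim(x$frames)[1]

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frame(s) of %d x %d pixels, %d-bit (max %d), session '%s'\n",
    d[1], d[2], d[3], x$bit_depth, x$max_value, x$session_id
  ))
  invisible(x)
}

#' Read a multi-frame grayscale TIFF as a frame stack
#'
#' Reads one imaging session from a multi-directory TIFF file (or an ordered
#' character vector of single-frame TIFF files). Cameras commonly store
#' 12-bit data padded into 16-bit containers; the stored sample depth is
#' therefore ignored and pixel values are validated against
#' `2^expected_bit_depth - 1` instead. Values above that full scale signal a
#' genuine bit-depth mismatch and raise an error rather than being rescaled
#' (silent rescaling would corrupt downstream reflectance changes).
#'
#' @param path Path to a multi-frame TIFF, or a character vector of paths to
#'   single-frame TIFFs making up one session (read in the given order).
#' @param expected_bit_depth Bits per pixel of the underlying data (default 12).
#' @param session_id,capture_label Passed to [frame_stack()]; `session_id`
#'   defaults to the file name.
#'
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, expected_bit_depth = 12L,
                             session_id = NULL, capture_label = "") {
  if (length(path) < 1L) stop_input("No input files given.")
  for (p in path) {
    if (!file.exists(p)) stop_input(sprintf("File not found: '%s'", p))
  }
  frames <- list()
  for (p in path) {
    fr <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(fr)) fr <- list(fr)
    frames <- c(frames, fr)
  }
  if (length(frames) == 0L) stop_format("File decoded to zero frames.")
  for (fr in frames) {
    if (length(dim(fr)) != 2L) {
      stop_format("Input is not single-channel grayscale (multi-channel frame found).")
    }
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("Frames do not share identical row x column dimensions.")
  }
  arr <- array(0L, c(length(frames), dims[1, 1], dims[2, 1]))
  for (j in seq_along(frames)) arr[j, , ] <- frames[[j]]
  if (is.null(session_id)) session_id <- basename(path[[1]])
  frame_stack(arr,
    bit_depth = expected_bit_depth, session_id = session_id,
    capture_label = capture_label
  )
}

#' Write a frame stack to a multi-frame TIFF
#'
#' Pixel integers are stored losslessly in a 16-bit container (the common
#' on-disk representation of 12-bit camera data), uncompressed, one TIFF
#' directory per frame. Reading the file back with [read_frame_stack()]
#' recovers the identical pixel array.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$bit_depth > 16L) stop_format("Only bit depths up to 16 are supported on disk.")
  container_max <- 65535
  mats <- lapply(seq_len(n_frames(stack)), function(j) {
    stack$frames[j, , ] / container_max
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Define the surface layout of a lightbox image
#'
#' A layout maps named surfaces (the passively exposed sample and the
#' unexposed reference imaged beside it) to square regions of interest (ROI)
#' in the camera field of view. ROIs are addressed by 0-based center
#' row/column pixel coordinates and an odd side length (default 49 pixels,
#' roughly 0.4 cm^2 at the nominal imaging geometry), centred on each surface
#' to avoid edge effects such as clamp shadows or handling contamination.
#'
#' @param entries Data frame with columns `surface_name`, `role`
#'   (`"sample"` or `"reference"`), `roi_center_row`, `roi_center_col`
#'   (0-based pixel coordinates), `roi_side_pixels` (positive odd integer).
#' @return A tibble of class `surface_layout`.
#' @export
#' @examples
#' surface_layout(data.frame(
#'   surface_name = c("sample", "reference"),
#'   role = c("sample", "reference"),
#'   roi_center_row = c(127, 127), roi_center_col = c(89, 166),
#'   roi_side_pixels = 49
#' ))
surface_layout <- function(entries) {
  needed <- c(
    "surface_name", "role", "roi_center_row", "roi_center_col",
    "roi_side_pixels"
  )
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols) > 0) {
    stop_layout(sprintf("Layout is missing column(s): %s", toString(missing_cols)))
  }
  entries <- as_tibble(entries)[needed]
  if (!all(entries$role %in% c("sample", "reference"))) {
    stop_layout("Layout roles must be 'sample' or 'reference'.")
  }
  if (sum(entries$role == "reference") != 1L) {
    stop_layout("Layout must contain exactly one reference surface.")
  }
  side <- entries$roi_side_pixels
  if (any(side < 1) || any(side %% 2 != 1)) {
    stop_layout("roi_side_pixels must be a positive odd integer.")
  }
  if (anyDuplicated(entries$surface_name)) {
    stop_layout("Surface names must be unique within a layout.")
  }
  class(entries) <- c("surface_layout", class(entries))
  entries
}

#' @rdname surface_layout
#' @param path Path to a YAML layout file: a list of entries, each with the
#'   fields of `entries`.
#' @export
read_surface_layout <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$surfaces)) raw <- raw$surfaces
  entries <- dplyr::bind_rows(lapply(raw, as_tibble))
  surface_layout(entries)
}

#' @rdname surface_layout
#' @param layout A `surface_layout`.
#' @export
write_surface_layout <- function(layout, path) {
  surfaces <- lapply(seq_len(nrow(layout)), function(i) as.list(layout[i, ]))
  yaml::write_yaml(list(surfaces = surfaces), path)
  invisible(path)
}

## 1-based row/column index ranges of one layout entry's ROI, validated
## against the stack's frame bounds.
roi_indices <- function(stack, entry) {
  half <- (entry$roi_side_pixels - 1L) / 2L
  rows <- (entry$roi_center_row - half):(entry$roi_center_row + half) + 1L
  cols <- (entry$roi_center_col - half):(entry$roi_center_col + half) + 1L
  d <- dim(stack$frames)
  if (min(rows) < 1L || max(rows) > d[2] || min(cols) < 1L || max(cols) > d[3]) {
    stop_layout(sprintf(
      "ROI for surface '%s' (rows %d..%d, cols %d..%d, 0-based) lies outside the %d x %d frame.",
      entry$surface_name, min(rows) - 1L, max(rows) - 1L,
      min(cols) - 1L, max(cols) - 1L, d[2], d[3]
    ))
  }
  list(rows = rows, cols = cols)
}

#' Mean pixel intensity of a surface's region of interest
#'
#' Computes the arithmetic mean of all pixels inside one layout entry's ROI,
#' pooled across every frame of the stack (for a fixed ROI this equals the
#' mean of per-frame ROI means). Pooling across frames averages out minor
#' frame-to-frame lighting fluctuation.
#'
#' @param stack A [frame_stack()].
#' @param layout_entry One row of a [surface_layout()] (or a list with the
#'   same fields).
#' @return Mean pixel intensity (unrounded, in `[0, max_value]`).
#' @export
extract_roi_mean <- function(stack, layout_entry) {
  stopifnot(inherits(stack, "frame_stack"))
  idx <- roi_indices(stack, layout_entry)
  mean(stack$frames[, idx$rows, idx$cols, drop = FALSE])
}

#' Per-frame quality control for an imaging session
#'
#' Report-only checks on a frame stack: the fraction of ROI pixels at the
#' full-scale value per frame (over-saturation from excessive exposure
#' settings), per-frame per-surface ROI means (so flicker outliers are
#' visible), and whether the frame count matches the campaign's expectation.
#'
#' @param stack A [frame_stack()].
#' @param layout A [surface_layout()].
#' @param saturation_fraction_limit A frame is flagged `over_saturated` when
#'   its fraction of ROI pixels at `max_value` exceeds this limit
#'   (default 0.01).
#' @param expected_frames Expected frame count (e.g. 20); `NULL` skips the
#'   count check.
#'
#' @return A list of class `frame_qc_report`: `frames` (tibble with `frame`,
#'   `fraction_at_max`, `over_saturated`), `roi_means` (tibble with `frame`,
#'   `surface_name`, `roi_mean`), and `frame_count_mismatch` (logical).
#' @export
qc_frames <- function(stack, layout, saturation_fraction_limit = 0.01,
                      expected_frames = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  idx <- lapply(seq_len(nrow(layout)), function(i) roi_indices(stack, layout[i, ]))
  frac <- vapply(seq_len(nf), function(j) {
    px <- unlist(lapply(idx, function(ix) stack$frames[j, ix$rows, ix$cols]))
    mean(px == stack$max_value)
  }, numeric(1))
  roi_means <- dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
    ix <- idx[[i]]
    tibble(
      frame = seq_len(nf),
      surface_name = layout$surface_name[i],
      roi_mean = vapply(
        seq_len(nf),
        function(j) mean(stack$frames[j, ix$rows, ix$cols]), numeric(1)
      )
    )
  }))
  structure(
    list(
      frames = tibble(
        frame = seq_len(nf),
        fraction_at_max = frac,
        over_saturated = frac > saturation_fraction_limit
      ),
      roi_means = roi_means,
      frame_count_mismatch =
        !is.null(expected_frames) && nf != as.integer(expected_frames)
    ),
    class = "frame_qc_report"
  )
}
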