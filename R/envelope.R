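#' Calibration of a Doppler trace image
#'
#' Maps image pixels to physical units: columns advance in time, rows encode
#' velocity about a drawn zero-velocity baseline. Rows increase downward, so
#' pixels above `baseline_row` are positive (inflow) velocities. All indices
#' are 1-based.
#'
#' @param dt_ms milliseconds per image column.
#' @param vel_per_px velocity (cm/s) per image row.
#' @param baseline_row 1-based row index of the zero-velocity baseline, or
#'   `NA` to detect it from the image (see [detect_baseline()]).
#' @return A list of class `doppler_calibration`.
#' @export
calibration <- function(dt_ms, vel_per_px, baseline_row = NA_integer_) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  if (vel_per_px <= 0) stop("vel_per_px must be positive")
  if (!is.na(baseline_row) && baseline_row < 1) stop("baseline_row must be >= 1")
  structure(
    list(dt_ms = as.numeric(dt_ms), vel_per_px = as.numeric(vel_per_px),
         baseline_row = as.integer(baseline_row)),
    class = "doppler_calibration"
  )
}

#' Render an envelope signal to a trace image
#'
#' Inverse of [extract_envelope()]: produces a grayscale image (matrix in
#' [0, 1], rows increasing downward) in which each column is filled from the
#' baseline row up (positive velocity) or down (negative velocity) to the row
#' implied by the calibration, and the baseline itself is drawn as a full
#' horizontal line. One signal sample maps to one column, so the calibration's
#' `dt_ms` must equal the signal's.
#'
#' @param signal an [envelope_signal()].
#' @param calib a [calibration()] with a concrete `baseline_row`.
#' @param n_rows image height; defaults to the smallest height that fits the
#'   signal below the baseline.
#' @return numeric matrix (`n_rows` x `length(signal)`), 0 = background,
#'   1 = foreground.
#' @export
render_to_image <- function(signal, calib, n_rows = NULL) {
  stopifnot(inherits(signal, "envelope_signal"), inherits(calib, "doppler_calibration"))
  if (is.na(calib$baseline_row)) stop("rendering needs a concrete baseline_row")
  if (abs(calib$dt_ms - signal$dt_ms) > 1e-9) {
    stop("calibration dt_ms must match the signal's sampling step")
  }
  v <- signal$values
  off <- as.integer(round(v / calib$vel_per_px))
  b <- calib$baseline_row
  if (is.null(n_rows)) n_rows <- b + max(0L, -min(off)) + 1L
  if (b > n_rows) stop("baseline_row outside image")
  if (any(b - off[off > 0L] < 1L) || any(b + abs(off[off < 0L]) > n_rows)) {
    stop("calibration clips signal")
  }
  img <- matrix(0, nrow = n_rows, ncol = length(v))
  img[b, ] <- 1
  for (j in seq_along(v)) {
    if (off[j] > 0L) img[(b - off[j]):(b - 1L), j] <- 1
    else if (off[j] < 0L) img[(b + 1L):(b - off[j]), j] <- 1
  }
  img
}

#' Read a grayscale trace image from PNG or TIFF
#'
#' 8- or 16-bit images are scaled to [0, 1]; RGB(A) images are collapsed to
#' luminance.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @return numeric matrix with intensities in [0, 1], rows increasing downward.
#' @export
read_trace_image <- function(path) {
  if (!file.exists(path)) stop("unreadable input: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img
}

#' Binarize a trace image
#'
#' Separates the bright trace from the dark background. With
#' `threshold = "otsu"` the threshold is chosen by Otsu's method and pixels
#' strictly above it are foreground; with a numeric threshold, pixels at or
#' above it are foreground.
#'
#' @param image numeric matrix of intensities.
#' @param threshold `"otsu"` or a fixed numeric cut.
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(image, threshold = "otsu") {
  if (!is.matrix(image) || nrow(image) < 2L || ncol(image) < 2L) {
    stop("image must be a matrix with at least 2 rows and 2 columns")
  }
  if (!all(is.finite(image))) stop("image intensities must be finite")
  if (is.character(threshold) && threshold == "otsu") {
    rng <- range(image)
    if (rng[1] == rng[2]) stop("degenerate histogram: image has no intensity variance")
    thr <- EBImage::otsu(image, range = rng, levels = 256L)
    image > thr
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    image >= threshold
  } else {
    stop("threshold must be \"otsu\" or a single number")
  }
}

#' Detect the zero-velocity baseline row
#'
#' The drawn baseline is the longest horizontal foreground run in the image.
#' Returns the row maximising the run length (ties broken toward the smaller
#' row index); if no row spans at least half the columns the result is
#' flagged as low confidence.
#'
#' @param mask logical matrix from [binarize()].
#' @return list with `row` (1-based index), `run_length`, and `low_confidence`.
#' @export
detect_baseline <- function(mask) {
  if (!is.matrix(mask) || !any(mask)) stop("empty mask")
  runs <- apply(mask, 1L, function(r) {
    rl <- rle(r)
    m <- rl$lengths[rl$values]
    if (length(m)) max(m) else 0L
  })
  row <- which.max(runs)  # ties -> smallest index
  list(row = as.integer(row), run_length = as.integer(runs[row]),
       low_confidence = runs[row] < ncol(mask) / 2)
}

#' Extract the velocity envelope from a binary trace image
#'
#' Per column, the envelope is the extreme foreground pixel: the topmost
#' foreground row above the baseline (positive velocity) or the bottommost
#' below it (negative velocity); when foreground exists on both sides the
#' side with the larger excursion wins (ties go to the positive side).
#' Baseline pixels themselves are not signal. Columns with no off-baseline
#' foreground map to velocity 0.
#'
#' @param mask logical matrix from [binarize()].
#' @param calib a [calibration()]; if `baseline_row` is `NA` it is detected
#'   with [detect_baseline()].
#' @return an [envelope_signal()] with one sample per column.
#' @export
extract_envelope <- function(mask, calib) {
  stopifnot(is.matrix(mask), inherits(calib, "doppler_calibration"))
  b <- calib$baseline_row
  if (is.na(b)) b <- detect_baseline(mask)$row
  if (b < 1L || b > nrow(mask)) stop("baseline_row outside mask")
  n <- ncol(mask)
  up <- integer(n)
  down <- integer(n)
  if (b > 1L) {
    above <- mask[seq_len(b - 1L), , drop = FALSE]
    has <- colSums(above) > 0L
    # topmost foreground row above baseline
    top <- apply(above[, has, drop = FALSE], 2L, which.max)
    up[has] <- b - top
  }
  if (b < nrow(mask)) {
    below <- mask[(b + 1L):nrow(mask), , drop = FALSE]
    has <- colSums(below) > 0L
    bot <- apply(below[, has, drop = FALSE], 2L, function(col) max(which(col)))
    down[has] <- bot
  }
  v <- ifelse(up >= down, up, -down) * calib$vel_per_px
  envelope_signal(v, calib$dt_ms)
}
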