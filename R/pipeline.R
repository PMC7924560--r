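#' Pipeline configuration
#'
#' Bundles the tunable settings of the end-to-end analysis: the low-pass
#' filter (or `NULL` to skip filtering), the landmark search window, the
#' baseline tolerance, and the binarization threshold used for image input.
#'
#' @param filter a [filter_spec()], or `NULL` to analyse the raw envelope.
#' @param window_frac E-peak search half-window, fraction of the median
#'   A-peak spacing.
#' @param baseline_tol_frac lobe-edge baseline tolerance, fraction of lobe
#'   peak magnitude.
#' @param threshold binarization threshold for image input (`"otsu"` or
#'   numeric), see [binarize()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_spec(), window_frac = 0.45,
                            baseline_tol_frac = 0.05, threshold = "otsu") {
  if (!is.null(filter)) stopifnot(inherits(filter, "filter_spec"))
  structure(
    list(filter = filter, window_frac = window_frac,
         baseline_tol_frac = baseline_tol_frac, threshold = threshold),
    class = "pipeline_config"
  )
}

#' Analyse an envelope signal: intervals and performance indices
#'
#' The core measurement chain: optional zero-phase low-pass filtering, AMPD
#' A-wave detection, landmark search, interval computation, and per-waveform
#' summary of the Tei index and K-index.
#'
#' @param signal an [envelope_signal()].
#' @param config a [pipeline_config()].
#' @return An `analysis_report`: list with `per_cycle` (landmark times in ms
#'   and intervals/indices per cycle), `summary`, `cycles_used`, `a_peaks`
#'   (sample indices), and `settings`.
#' @export
analyze_envelope <- function(signal, config = pipeline_config()) {
  stopifnot(inherits(signal, "envelope_signal"))
  work <- if (is.null(config$filter)) signal else apply_lowpass(signal, config$filter)
  peaks <- detect_a_waves(work)
  if (length(peaks) < 3L) stop("insufficient cycles: found ", length(peaks), " A-wave peak(s)")
  lm <- locate_landmarks(work, peaks, window_frac = config$window_frac,
                         baseline_tol_frac = config$baseline_tol_frac)
  if (nrow(lm) == 0L) stop("zero valid cycles")
  iv <- compute_intervals(lm, signal$dt_ms)
  res <- summarize_waveform(iv)

  lm_ms <- lm
  idx_cols <- setdiff(names(lm), "cycle")
  lm_ms[idx_cols] <- lapply(lm_ms[idx_cols], function(i) {
    signal$origin_time_ms + (i - 1L) * signal$dt_ms
  })
  per_cycle <- cbind(lm_ms, res$per_cycle[setdiff(names(res$per_cycle), "cycle")])

  structure(
    list(per_cycle = per_cycle, summary = res$summary,
         cycles_used = res$cycles_used, sd_defined = res$sd_defined,
         a_peaks = peaks,
         settings = list(
           filter = config$filter, window_frac = config$window_frac,
           baseline_tol_frac = config$baseline_tol_frac, dt_ms = signal$dt_ms
         )),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d A-wave peak(s), %d measured cycle(s)\n",
              length(x$a_peaks), x$cycles_used))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    unit <- if (s$measure[i] %in% c("TI", "KI")) "" else " ms"
    cat(sprintf("  %-12s %8.3f +/- %.3f%s\n", s$measure[i], s$mean[i], s$sd[i], unit))
  }
  invisible(x)
}

#' Run the full measurement pipeline on a file
#'
#' Accepts either a signal CSV (`time_ms,velocity_cm_s`) or a grayscale
#' PNG/TIFF trace image. Image input is binarized, the baseline is taken from
#' the calibration or detected automatically, the envelope is extracted, and
#' the result is passed through [analyze_envelope()].
#'
#' @param input path to a `.csv` signal or `.png`/`.tif`/`.tiff` image.
#' @param config a [pipeline_config()].
#' @param calib a [calibration()]; required for image input.
#' @return An `analysis_report` with a `provenance` element (input path,
#'   MD5 hash, package version, timestamp).
#' @export
run_pipeline <- function(input, config = pipeline_config(), calib = NULL) {
  if (!is.character(input) || length(input) != 1L || !file.exists(input)) {
    stop("unreadable input: ", input)
  }
  ext <- tolower(tools::file_ext(input))
  if (ext == "csv") {
    sig <- read_signal_csv(input)
  } else if (ext %in% c("png", "tif", "tiff")) {
    if (is.null(calib)) stop("calibration missing for image input")
    img <- read_trace_image(input)
    mask <- binarize(img, threshold = config$threshold)
    sig <- extract_envelope(mask, calib)
  } else {
    stop("unsupported input format: ", ext)
  }
  report <- analyze_envelope(sig, config)
  report$provenance <- list(
    input = normalizePath(input),
    md5 = unname(tools::md5sum(input)),
    package_version = as.character(utils::packageVersion("fetalMPI")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report
}

#' Read an envelope signal from CSV
#'
#' Expects columns `time_ms` and `velocity_cm_s` with a header row; samples
#' must be uniformly spaced.
#'
#' @param path CSV file.
#' @return an [envelope_signal()].
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "velocity_cm_s") %in% names(df))) {
    stop("signal CSV must have columns time_ms, velocity_cm_s")
  }
  dts <- diff(df$time_ms)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-6 * max(dts[1], 1))) {
    stop("signal CSV must be uniformly sampled")
  }
  envelope_signal(df$velocity_cm_s, dt_ms = dts[1], origin_time_ms = df$time_ms[1])
}

#' Write an envelope signal to CSV
#'
#' @param signal an [envelope_signal()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "envelope_signal"))
  utils::write.csv(
    data.frame(time_ms = signal_time(signal), velocity_cm_s = signal$values),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Serialise an analysis report (or ground truth) to JSON
#'
#' @param report an `analysis_report` from [run_pipeline()] /
#'   [analyze_envelope()], or any list of plain data.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
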