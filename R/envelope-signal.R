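#' Construct an envelope signal
#'
#' The central 1-D object of the pipeline: a uniformly sampled, signed
#' velocity trace extracted from (or destined for) a pulsed-Doppler display.
#' By acquisition convention left-ventricular inflow is positive and outflow
#' negative.
#'
#' @param values numeric vector of velocities (cm/s), signed.
#' @param dt_ms sampling step in milliseconds (> 0).
#' @param origin_time_ms time of the first sample in milliseconds.
#' @return An object of class `envelope_signal`: a list with elements
#'   `values`, `dt_ms` and `origin_time_ms`.
#' @examples
#' es <- envelope_signal(sin(seq(0, 2 * pi, length.out = 100)), dt_ms = 1)
#' signal_time(es)[1:5]
#' @export
envelope_signal <- function(values, dt_ms, origin_time_ms = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("envelope signal needs at least 2 samples")
  if (!all(is.finite(values))) stop("envelope signal values must be finite")
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || dt_ms <= 0) {
    stop("dt_ms must be a single positive number")
  }
  structure(
    list(values = values, dt_ms = as.numeric(dt_ms),
         origin_time_ms = as.numeric(origin_time_ms)),
    class = "envelope_signal"
  )
}

#' Sample times of an envelope signal
#'
#' @param x an `envelope_signal`.
#' @return numeric vector of sample times in milliseconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "envelope_signal"))
  x$origin_time_ms + (seq_along(x$values) - 1L) * x$dt_ms
}

#' @export
length.envelope_signal <- function(x) length(x$values)

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf(
    "<envelope_signal> %d samples, dt = %g ms (%.3f s), range [%.2f, %.2f] cm/s\n",
    length(x$values), x$dt_ms, length(x$values) * x$dt_ms / 1000,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

# Coerce numeric vectors for internal use; signals pass through.
as_signal_values <- function(x) {
  if (inherits(x, "envelope_signal")) x$values else as.numeric(x)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
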