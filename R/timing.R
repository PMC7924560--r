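#' Locate per-cycle cardiac landmarks around detected A-wave peaks
#'
#' Starting from the AMPD-detected A peaks (one per cardiac cycle), each
#' interior cycle is segmented by windowed extremum search on the signed
#' envelope:
#' \itemize{
#'   \item the E peak is the largest positive local maximum left of the A
#'     peak, within `window_frac` of the median peak spacing;
#'   \item FT start is where the E lobe leaves the baseline: walking left
#'     from the E peak, the flank's local slope is fitted where it falls to
#'     15% of the lobe peak and extrapolated to the zero crossing, which
#'     stays accurate when low-pass filtering has smeared the lobe corner;
#'   \item the end of the previous ejection lobe (previous ET end) is the
#'     right edge of the first negative lobe left of FT start;
#'   \item FT end is the right edge of the A lobe, and ET start / ET end are
#'     the edges of the following negative ejection lobe.
#' }
#' Valve-click spikes, when present at a boundary, snap the boundary to the
#' click sample. The first and last cycles are discarded: IVRT needs the
#' previous cycle's ET end, so only interior cycles yield complete interval
#' sets. A cycle whose landmarks come out mis-ordered is dropped with a
#' warning rather than failing the whole waveform.
#'
#' @param signal an [envelope_signal()] (typically low-pass filtered).
#' @param a_peaks integer indices of A-wave peaks from [detect_peaks()];
#'   at least 3 are needed for one interior cycle.
#' @param window_frac half-window for the E-peak search, as a fraction of the
#'   median A-peak spacing; in (0, 0.5].
#' @param baseline_tol_frac baseline tolerance for lobe-edge detection, as a
#'   fraction of the relevant lobe's peak magnitude.
#' @return data frame with one row per retained cycle: sample indices
#'   `prev_ET_end`, `FT_start`, `E_peak`, `A_peak`, `FT_end`, `ET_start`,
#'   `ET_end`, plus the anchoring `cycle` number.
#' @export
locate_landmarks <- function(signal, a_peaks, window_frac = 0.45,
                             baseline_tol_frac = 0.05) {
  stopifnot(inherits(signal, "envelope_signal"))
  if (window_frac <= 0 || window_frac > 0.5) stop("window_frac must be in (0, 0.5]")
  x <- signal$values
  n <- length(x)
  a_peaks <- sort(as.integer(a_peaks))
  if (length(a_peaks) < 3L) stop("insufficient cycles: need at least 3 A-wave peaks")

  spacing <- stats::median(diff(a_peaks))
  w <- max(3L, as.integer(round(window_frac * spacing)))
  chase <- max(4L, as.integer(round(0.015 * spacing)))
  scan_cap <- as.integer(round(0.6 * spacing))

  rows <- vector("list", length(a_peaks) - 2L)
  dropped <- 0L
  for (j in 2L:(length(a_peaks) - 1L)) {
    p <- a_peaks[j]
    lm <- segment_cycle(x, n, p, a_peaks[j - 1L], a_peaks[j + 1L],
                        w, chase, scan_cap, baseline_tol_frac)
    if (is.null(lm)) {
      dropped <- dropped + 1L
      next
    }
    rows[[j - 1L]] <- data.frame(cycle = j, as.list(lm))
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d cycle(s) with inconsistent landmarks", dropped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cycle = integer(), prev_ET_end = integer(),
                      FT_start = integer(), E_peak = integer(),
                      A_peak = integer(), FT_end = integer(),
                      ET_start = integer(), ET_end = integer())
  }
  out
}

# One interior cycle anchored at A peak p; returns named integer vector or
# NULL when any landmark fails or the ordering invariant is violated.
segment_cycle <- function(x, n, p, p_prev, p_next, w, chase, scan_cap, tol_frac) {
  # E peak: tallest positive strict local maximum left of A that is
  # separated from the A lobe by a genuine valley (the minimum between the
  # candidate and A must dip below half the candidate height) -- this rejects
  # noise wiggles riding on the A lobe itself
  lo <- max(2L, p - w)
  hi <- p - 2L
  if (hi < lo) return(NULL)
  i <- lo:hi
  is_max <- x[i] > x[i - 1L] & x[i] > x[i + 1L] & x[i] > 0
  cand <- i[is_max]
  if (!length(cand)) return(NULL)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  e_pk <- NA_integer_
  for (cnd in cand) {
    if (min(x[cnd:p]) < 0.5 * x[cnd]) { e_pk <- cnd; break }
  }
  if (is.na(e_pk)) return(NULL)

  e_mag <- x[e_pk]
  a_mag <- x[p]
  neg_prev <- max(-x[p_prev:p])
  neg_next <- max(-x[p:p_next])
  if (neg_prev <= 0 || neg_next <= 0) return(NULL)

  ft_start <- walk_edge(x, n, e_pk, dir = -1L, sgn = 1, peak_mag = e_mag, chase = chase)
  ft_start <- snap_click(x, n, ft_start, side = 1L, tol = tol_frac * e_mag)
  if (is.na(ft_start)) return(NULL)
  entry_prev <- find_lobe(x, n, ft_start - 2L, dir = -1L, sgn = -1,
                          tol = tol_frac * neg_prev, cap = scan_cap)
  if (is.na(entry_prev)) return(NULL)
  seg <- max(1L, entry_prev - scan_cap):entry_prev
  prev_min <- seg[which.min(x[seg])]
  prev_et_end <- walk_edge(x, n, prev_min, dir = 1L, sgn = -1,
                           peak_mag = neg_prev, chase = chase)

  ft_end <- walk_edge(x, n, p, dir = 1L, sgn = 1, peak_mag = a_mag, chase = chase)
  ft_end <- snap_click(x, n, ft_end, side = -1L, tol = tol_frac * a_mag)
  if (is.na(ft_end)) return(NULL)
  entry_et <- find_lobe(x, n, ft_end + 2L, dir = 1L, sgn = -1,
                        tol = tol_frac * neg_next, cap = scan_cap)
  if (is.na(entry_et)) return(NULL)
  seg <- entry_et:min(n, entry_et + scan_cap)
  et_min <- seg[which.min(x[seg])]
  et_start <- walk_edge(x, n, et_min, dir = -1L, sgn = -1, peak_mag = neg_next, chase = chase)
  et_end <- walk_edge(x, n, et_min, dir = 1L, sgn = -1, peak_mag = neg_next, chase = chase)

  lm <- c(prev_ET_end = prev_et_end, FT_start = ft_start, E_peak = e_pk,
          A_peak = p, FT_end = ft_end, ET_start = et_start, ET_end = et_end)
  if (anyNA(lm) || any(diff(lm) <= 0)) return(NULL)
  lm
}

# Locate the baseline edge of a lobe. Starting inside a lobe of sign `sgn`
# at `start`, walk in direction `dir` until the rectified signal falls to
# 15% of the lobe peak, fit the flank's local slope there (least squares
# over nearby samples still on the flank), and extrapolate to the zero
# crossing. The 15% crossing sits outside the corner region distorted by
# low-pass smearing, so the extrapolated boundary is unbiased on filtered
# signals and exact on clean half-sine lobes. Falls back to a bounded
# zero-chase when the flank slope cannot be estimated.
walk_edge <- function(x, n, start, dir, sgn, peak_mag, chase) {
  tol_hi <- 0.15 * peak_mag
  i <- start
  while (i >= 1L && i <= n && sgn * x[i] > tol_hi) i <- i + dir
  if (i < 1L || i > n) return(NA_integer_)
  y <- sgn * x
  win <- (i - 3L):(i + 3L)
  win <- win[win >= 1L & win <= n]
  win <- win[y[win] > 0.02 * peak_mag & y[win] < 0.6 * peak_mag]
  slope <- NA_real_
  if (length(win) >= 2L) {
    slope <- stats::cov(win, y[win]) / stats::var(win)
  }
  if (is.finite(slope) && sign(slope) == -dir && abs(slope) > 1e-12) {
    i0 <- i - y[i] / slope
    reach <- max(6, 3 * chase)
    i0 <- min(max(i0, i - reach), i + reach)
    return(as.integer(min(max(round(i0), 1L), n)))
  }
  # fallback: chase the first non-positive (rectified) sample
  steps <- 0L
  while (i >= 1L && i <= n && y[i] > 0 && steps < chase) {
    i <- i + dir
    steps <- steps + 1L
  }
  if (i < 1L || i > n) NA_integer_ else i
}

# Scan in direction dir for the first sample inside a lobe of sign sgn
# (magnitude above tol), giving up after cap samples.
find_lobe <- function(x, n, start, dir, sgn, tol, cap) {
  i <- start
  steps <- 0L
  while (i >= 1L && i <= n && steps <= cap) {
    if (sgn * x[i] > tol) return(i)
    i <- i + dir
    steps <- steps + 1L
  }
  NA_integer_
}

# A valve click stepped over by walk_edge shows as an isolated sample well
# above the baseline tolerance just inside the boundary (on the `side` the
# lobe lies: +1 lobe to the right, -1 lobe to the left). Snap to it.
snap_click <- function(x, n, idx, side, tol) {
  if (is.na(idx)) return(idx)
  win <- idx + side * (0:2)
  win <- win[win >= 1L & win <= n]
  if (!length(win)) return(idx)
  v <- x[win]
  if (max(v) > 4 * tol) win[which.max(v)] else idx
}

#' Cardiac time intervals from cycle landmarks
#'
#' Converts per-cycle landmark sample indices to the four cardiac time
#' intervals (ms): filling time `FT = FT_end - FT_start`, isovolumetric
#' contraction time `IVCT = ET_start - FT_end`, ejection time
#' `ET = ET_end - ET_start`, and isovolumetric relaxation time
#' `IVRT = FT_start - prev_ET_end`. Their sum is one cycle length.
#'
#' @param landmarks data frame from [locate_landmarks()] (or any data frame
#'   with the same landmark columns, in samples).
#' @param dt_ms sampling step (ms per sample).
#' @return data frame with columns `cycle`, `IVCT`, `IVRT`, `ET`, `FT`,
#'   `cycle_length`, all in ms.
#' @examples
#' lm <- data.frame(cycle = 1, prev_ET_end = 0, FT_start = 48, E_peak = 100,
#'                  A_peak = 200, FT_end = 283, ET_start = 326, ET_end = 496)
#' compute_intervals(lm, dt_ms = 1)
#' @export
compute_intervals <- function(landmarks, dt_ms) {
  if (nrow(landmarks) == 0L) stop("no cycles to measure")
  if (dt_ms <= 0) stop("dt_ms must be positive")
  need <- c("prev_ET_end", "FT_start", "E_peak", "A_peak", "FT_end",
            "ET_start", "ET_end")
  ord <- as.matrix(landmarks[, need])
  if (any(t(apply(ord, 1L, diff)) <= 0)) stop("degenerate cycle: landmarks out of order")
  out <- data.frame(
    cycle = if ("cycle" %in% names(landmarks)) landmarks$cycle else seq_len(nrow(landmarks)),
    IVCT = (landmarks$ET_start - landmarks$FT_end) * dt_ms,
    IVRT = (landmarks$FT_start - landmarks$prev_ET_end) * dt_ms,
    ET = (landmarks$ET_end - landmarks$ET_start) * dt_ms,
    FT = (landmarks$FT_end - landmarks$FT_start) * dt_ms
  )
  out$cycle_length <- out$IVCT + out$IVRT + out$ET + out$FT
  if (any(out$IVCT <= 0 | out$IVRT <= 0 | out$ET <= 0 | out$FT <= 0)) {
    stop("degenerate cycle: non-positive interval")
  }
  out
}

#' Tei index (myocardial performance index)
#'
#' `TI = (IVCT + IVRT) / ET`: total isovolumetric time normalised by the
#' ejection time, a dimensionless index of combined systolic and diastolic
#' ventricular performance.
#'
#' @param intervals data frame (or list) with elements `IVCT`, `IVRT`, `ET`
#'   in consistent time units.
#' @return numeric vector of per-cycle Tei indices.
#' @examples
#' tei_index(list(IVCT = 43, IVRT = 48, ET = 170))  # 0.5353
#' @export
tei_index <- function(intervals) {
  if (any(intervals$ET <= 0)) stop("ET must be positive")
  (intervals$IVCT + intervals$IVRT) / intervals$ET
}

#' K-index
#'
#' `KI = (IVCT + IVRT) / FT`: total isovolumetric time normalised by the
#' filling time, weighting the index toward diastolic (relaxation)
#' performance.
#'
#' @inheritParams tei_index
#' @param intervals data frame (or list) with elements `IVCT`, `IVRT`, `FT`.
#' @return numeric vector of per-cycle K-indices.
#' @examples
#' k_index(list(IVCT = 43, IVRT = 48, FT = 235))  # 0.3872
#' @export
k_index <- function(intervals) {
  if (any(intervals$FT <= 0)) stop("FT must be positive")
  (intervals$IVCT + intervals$IVRT) / intervals$FT
}

#' Per-waveform summary of cardiac intervals and performance indices
#'
#' Aggregates per-cycle measurements into a per-waveform result: mean and
#' sample standard deviation of each interval and index over the retained
#' cycles. With a single cycle the standard deviation is reported as 0 and
#' flagged as undefined.
#'
#' @param intervals data frame from [compute_intervals()].
#' @return An object of class `mpi_result`: list with `per_cycle` (intervals
#'   plus `TI`, `KI`), `summary` (data frame of mean/sd per measure),
#'   `cycles_used`, and `sd_defined`.
#' @export
summarize_waveform <- function(intervals) {
  if (nrow(intervals) < 1L) stop("zero valid cycles")
  per_cycle <- intervals
  per_cycle$TI <- tei_index(intervals)
  per_cycle$KI <- k_index(intervals)
  measures <- c("IVCT", "IVRT", "ET", "FT", "TI", "KI", "cycle_length")
  sd_defined <- nrow(per_cycle) > 1L
  summ <- data.frame(
    measure = measures,
    mean = vapply(measures, function(m) mean(per_cycle[[m]]), numeric(1)),
    sd = vapply(measures, function(m) {
      if (sd_defined) stats::sd(per_cycle[[m]]) else 0
    }, numeric(1)),
    row.names = NULL
  )
  structure(
    list(per_cycle = per_cycle, summary = summ,
         cycles_used = nrow(per_cycle), sd_defined = sd_defined),
    class = "mpi_result"
  )
}

#' @export
print.mpi_result <- function(x, ...) {
  cat(sprintf("<mpi_result> %d cycle(s)\n", x$cycles_used))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    unit <- if (s$measure[i] %in% c("TI", "KI")) "" else " ms"
    cat(sprintf("  %-12s %8.3f +/- %.3f%s\n", s$measure[i], s$mean[i], s$sd[i], unit))
  }
  if (!x$sd_defined) cat("  (single cycle: SD undefined, reported as 0)\n")
  invisible(x)
}
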