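#' Local maxima scalogram (LMS) of a signal
#'
#' For scales (sample clearances) k = 1..L with L = ceiling(N/2) - 1, entry
#' m(k, i) is 0 when sample i is a strict local maximum at clearance k, i.e.
#' x(i) > x(i - k) and x(i) > x(i + k) with both neighbours in range;
#' otherwise it is r + 1 with r drawn uniformly from (0, 1). Boundary columns
#' whose k-distant neighbour falls outside the signal are never maxima at that
#' scale. The zero-pattern -- which is all that peak detection uses -- does
#' not depend on the seed; only the arbitrary non-zero fill values do.
#' Plateau samples (equal to a neighbour) are not maxima: the inequality is
#' strict.
#'
#' @param x an [envelope_signal()] or numeric vector, length N >= 4.
#' @param seed seed for the arbitrary non-zero fill values.
#' @return A list of class `lms_matrix` with elements `m` (L x N matrix),
#'   `L` and `N`.
#' @seealso [ampd_summary()], [detect_peaks()]
#' @export
compute_lms <- function(x, seed = 1L) {
  x <- as_signal_values(x)
  n <- length(x)
  if (n < 4L) stop("signal too short: need at least 4 samples")
  L <- as.integer(ceiling(n / 2) - 1)
  m <- matrix(with_seed(as.integer(seed), stats::runif(L * n)) + 1,
              nrow = L, ncol = n)
  for (k in seq_len(L)) {
    i <- (k + 1L):(n - k)
    is_max <- x[i] > x[i - k] & x[i] > x[i + k]
    m[k, i[is_max]] <- 0
  }
  structure(list(m = m, L = L, N = n), class = "lms_matrix")
}

#' Row-wise and column-wise summary of an LMS matrix
#'
#' Computes the row sums gamma of the scalogram, the lambda index (the scale
#' below which all relevant local maxima live), and the column standard
#' deviations sigma of the matrix truncated to rows 1..lambda. A column whose
#' truncated entries are all zero has sigma exactly 0; these columns are the
#' detected peaks.
#'
#' Because the non-zero entries are arbitrary random values, the minimiser of
#' the raw row sums could be flipped between near-tied scales by the random
#' fill. Lambda is therefore taken as the scale minimising the number of
#' non-zero entries per row -- the deterministic statistic the row sums
#' estimate (it equals `which.min(gamma)` with the arbitrary fill set to any
#' constant) -- with ties broken toward the smallest scale, favouring sharper
#' peaks. This makes detection a pure function of the signal.
#'
#' @param lms an `lms_matrix` from [compute_lms()].
#' @return A list of class `ampd_summary`: `gamma` (length L), `lambda`
#'   (scalar scale index), `sigma` (length N), `peaks` (indices with
#'   sigma == 0, ascending).
#' @export
ampd_summary <- function(lms) {
  stopifnot(inherits(lms, "lms_matrix"))
  m <- lms$m
  gamma <- rowSums(m)
  nonzero <- rowSums(m != 0)
  lambda <- which.min(nonzero)
  sub <- m[seq_len(lambda), , drop = FALSE]
  all_zero <- colSums(sub != 0) == 0L
  if (lambda >= 2L) {
    sigma <- apply(sub, 2L, stats::sd)
  } else {
    # single-scale degenerate case: Eq-style sd over one row is undefined;
    # report the entry itself (positive iff not a maximum)
    sigma <- abs(sub[1L, ])
  }
  sigma[all_zero] <- 0
  structure(
    list(gamma = gamma, lambda = as.integer(lambda), sigma = sigma,
         peaks = which(all_zero)),
    class = "ampd_summary"
  )
}

#' Automatic multiscale-based peak detection (AMPD)
#'
#' Detects the dominant positive peaks of a quasi-periodic signal -- for
#' fetal LV Doppler envelopes, one A wave per cardiac cycle -- as the samples
#' that are strict local maxima at every clearance k = 1..lambda, where
#' lambda is the scale at which local maxima are most abundant (see
#' [ampd_summary()]). No tuning parameters are required; the result is
#' invariant to amplitude scaling of the signal and to the random fill of the
#' scalogram.
#'
#' This implementation streams over scales without materialising the random
#' matrix, so it is equivalent to
#' `ampd_summary(compute_lms(x))$peaks` but linear in memory.
#'
#' @param x an [envelope_signal()] or numeric vector, length >= 4.
#' @param max_scale optional cap on the largest clearance considered; by
#'   default all scales up to `ceiling(N/2) - 1` are used. [detect_a_waves()]
#'   uses the cap so that scales probing its baseline padding, which carry no
#'   information about the signal, cannot attract the lambda index.
#' @return integer vector of peak indices (ascending); empty when the signal
#'   has no peaks (e.g. strictly monotone input).
#' @examples
#' detect_peaks(c(0, 1, 0, 2, 0, 1, 0, 3, 0))
#' @export
detect_peaks <- function(x, max_scale = NULL) {
  x <- as_signal_values(x)
  n <- length(x)
  if (n < 4L) stop("signal too short: need at least 4 samples")
  L <- as.integer(ceiling(n / 2) - 1)
  if (!is.null(max_scale)) L <- min(L, max(1L, as.integer(max_scale)))
  # zero_prefix[i] = largest k such that i is a max at all clearances 1..k
  zero_prefix <- integer(n)
  alive <- rep(TRUE, n)
  nonzero_count <- integer(L)
  for (k in seq_len(L)) {
    zero_k <- rep(FALSE, n)
    i <- (k + 1L):(n - k)
    zero_k[i] <- x[i] > x[i - k] & x[i] > x[i + k]
    nonzero_count[k] <- n - sum(zero_k)
    newly_dead <- alive & !zero_k
    zero_prefix[newly_dead] <- k - 1L
    alive <- alive & zero_k
  }
  zero_prefix[alive] <- L
  lambda <- which.min(nonzero_count)
  which(zero_prefix >= lambda)
}

#' Detect A-wave peaks of a baseline-anchored Doppler envelope
#'
#' Envelope-aware front end to [detect_peaks()]. Under the scalogram's
#' boundary convention, a sample closer than lambda to either end of the
#' signal can never be scored as a peak, so when a trace starts or ends at a
#' cardiac cycle boundary the first or last A wave is lost. Because a Doppler
#' envelope is anchored to the zero-velocity baseline, the signal can be
#' extended with baseline (zero) samples on both sides without creating
#' spurious maxima; this wrapper pads by half the signal length per side,
#' runs the detector, and maps the peak indices back. Use [detect_peaks()]
#' directly for signals that are not baseline-anchored.
#'
#' The scalogram scale range is additionally capped at `max_scale_ms`. The
#' lambda index that separates A waves from smaller features sits near half
#' the cardiac cycle, so scales beyond half the longest plausible fetal cycle
#' (600 ms at 100 bpm) carry no information about peak spacing; without the
#' cap, very large clearances -- at which any sample on the upper half of a
#' lobe trivially dominates far-away samples in other phases of the cycle --
#' can attract the lambda index and collapse detection onto the single
#' tallest peak.
#'
#' Detected peaks are finally screened by relative amplitude: successive A
#' waves of one trace have similar height, so a detected "peak" far below
#' the median peak height (a noise bump or filter-ringing ripple on an
#' otherwise flat stretch, which can dominate its surroundings at every
#' scale) is discarded. The threshold is relative, so detection remains
#' invariant to amplitude scaling.
#'
#' @param x an [envelope_signal()], or a numeric vector sampled at 1 ms.
#' @param max_scale_ms largest scalogram clearance considered, in ms.
#' @param min_rel_height minimum peak height as a fraction of the median
#'   detected peak height.
#' @return integer vector of A-wave peak indices (ascending).
#' @export
detect_a_waves <- function(x, max_scale_ms = 350, min_rel_height = 0.25) {
  dt <- if (inherits(x, "envelope_signal")) x$dt_ms else 1
  x <- as_signal_values(x)
  n <- length(x)
  if (n < 4L) stop("signal too short: need at least 4 samples")
  pad <- as.integer(ceiling(n / 2))
  cap <- min(ceiling(n / 2) - 1, max(1L, round(max_scale_ms / dt)))
  peaks <- detect_peaks(c(numeric(pad), x, numeric(pad)), max_scale = cap)
  peaks <- peaks[peaks > pad & peaks <= pad + n] - pad
  if (length(peaks) > 1L) {
    h <- x[peaks]
    peaks <- peaks[h >= min_rel_height * stats::median(h)]
  }
  as.integer(peaks)
}
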