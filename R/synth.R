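#' Specification of a synthetic fetal LV Doppler envelope
#'
#' Parameters for the waveform generator. One cardiac cycle is laid out as
#' filling time (FT, positive inflow lobes: an E wave followed by the dominant
#' A wave), an isovolumetric contraction gap (IVCT), the ejection lobe (ET,
#' negative outflow) and an isovolumetric relaxation gap (IVRT). The four
#' fractions must sum to one. Lobes are half-sines so that every lobe boundary
#' is an exact zero crossing, which makes the implied ground-truth landmark
#' times exact.
#'
#' Defaults describe a physiologically plausible mid-gestation fetus: 140 bpm,
#' A-wave 45 cm/s with E/A = 0.7 (the A wave dominates in fetuses, the reverse
#' of the adult pattern), outflow peak 60 cm/s, and interval fractions
#' IVCT 0.08 / ET 0.35 / IVRT 0.10 / FT 0.47 of the cycle.
#'
#' @param heart_rate_bpm heart rate in beats per minute.
#' @param duration_s trace duration in seconds; must cover at least two full
#'   cardiac cycles.
#' @param dt_ms sampling step in milliseconds.
#' @param frac_ivct,frac_et,frac_ivrt,frac_ft fractions of one cycle occupied
#'   by each interval; must be positive and sum to 1 (within 1e-9).
#' @param e_over_a ratio of E-wave to A-wave peak amplitude, in (0, 1).
#' @param a_amplitude A-wave peak velocity (cm/s).
#' @param et_amplitude magnitude of the negative ejection lobe peak (cm/s).
#' @param click_amplitude amplitude of the valve-click spikes placed at lobe
#'   boundaries (cm/s); 0 disables clicks.
#' @param noise_sd standard deviation of additive white Gaussian noise (cm/s).
#' @param seed integer seed controlling the noise realisation.
#' @return A list of class `synth_spec`.
#' @seealso [generate_envelope()]
#' @export
synth_spec <- function(heart_rate_bpm = 140, duration_s = 3, dt_ms = 1,
                       frac_ivct = 0.08, frac_et = 0.35, frac_ivrt = 0.10,
                       frac_ft = 0.47, e_over_a = 0.7, a_amplitude = 45,
                       et_amplitude = 60, click_amplitude = 0, noise_sd = 0,
                       seed = 1L) {
  spec <- list(
    heart_rate_bpm = heart_rate_bpm, duration_s = duration_s, dt_ms = dt_ms,
    frac_ivct = frac_ivct, frac_et = frac_et, frac_ivrt = frac_ivrt,
    frac_ft = frac_ft, e_over_a = e_over_a, a_amplitude = a_amplitude,
    et_amplitude = et_amplitude, click_amplitude = click_amplitude,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

validate_synth_spec <- function(spec) {
  fr <- c(spec$frac_ivct, spec$frac_et, spec$frac_ivrt, spec$frac_ft)
  if (any(fr <= 0)) stop("all interval fractions must be positive")
  if (abs(sum(fr) - 1) > 1e-9) stop("interval fractions must sum to 1")
  if (spec$e_over_a <= 0 || spec$e_over_a >= 1) stop("e_over_a must be in (0,1)")
  if (spec$dt_ms <= 0) stop("dt_ms must be positive")
  if (spec$heart_rate_bpm <= 0) stop("heart_rate_bpm must be positive")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  if (spec$click_amplitude < 0) stop("click_amplitude must be non-negative")
  invisible(spec)
}

#' Generate a synthetic Doppler envelope with ground-truth landmarks
#'
#' Builds a merged inflow/outflow fetal LV envelope: per cycle, a half-sine
#' E lobe then a half-sine A lobe (both positive, splitting the FT window
#' evenly), a baseline IVCT gap, a negative half-sine ejection lobe over the
#' ET window, and a baseline IVRT gap. Optional single-sample valve-click
#' spikes are added at FT start/end and ET start/end, and white Gaussian
#' noise is added last. The same spec (including seed) always reproduces the
#' identical signal.
#'
#' @param spec a [synth_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{signal}{an [envelope_signal()] of length
#'       `round(duration_s * 1000 / dt_ms)`.}
#'     \item{truth}{a data frame of exact landmark times in ms, one row per
#'       complete cycle: `FT_start`, `E_peak`, `A_peak`, `FT_end`,
#'       `ET_start`, `ET_end`, plus `cycle_length_ms`.}
#'   }
#' @examples
#' ge <- generate_envelope(synth_spec(heart_rate_bpm = 120, duration_s = 2))
#' nrow(ge$truth)  # 4 complete cycles
#' @export
generate_envelope <- function(spec) {
  validate_synth_spec(spec)
  period_ms <- 60000 / spec$heart_rate_bpm
  total_ms <- spec$duration_s * 1000
  n <- round(total_ms / spec$dt_ms)
  n_cycles <- floor(total_ms / period_ms + 1e-9)
  if (n_cycles < 2) stop("insufficient cycles: duration must cover >= 2 full cycles")

  t <- (seq_len(n) - 1L) * spec$dt_ms
  x <- numeric(n)

  ft <- spec$frac_ft * period_ms
  ivct <- spec$frac_ivct * period_ms
  et <- spec$frac_et * period_ms
  half_ft <- ft / 2
  e_amp <- spec$e_over_a * spec$a_amplitude

  truth <- data.frame(
    cycle = seq_len(n_cycles),
    FT_start = NA_real_, E_peak = NA_real_, A_peak = NA_real_,
    FT_end = NA_real_, ET_start = NA_real_, ET_end = NA_real_,
    cycle_length_ms = period_ms
  )

  for (k in seq_len(n_cycles)) {
    s <- (k - 1) * period_ms
    # E lobe on [s, s + ft/2), A lobe on [s + ft/2, s + ft)
    ie <- which(t >= s & t < s + half_ft)
    x[ie] <- e_amp * sin(pi * (t[ie] - s) / half_ft)
    ia <- which(t >= s + half_ft & t < s + ft)
    x[ia] <- spec$a_amplitude * sin(pi * (t[ia] - s - half_ft) / half_ft)
    # ejection lobe on [s + ft + ivct, s + ft + ivct + et)
    es <- s + ft + ivct
    io <- which(t >= es & t < es + et)
    x[io] <- -spec$et_amplitude * sin(pi * (t[io] - es) / et)

    truth$FT_start[k] <- s
    truth$E_peak[k] <- s + ft / 4
    truth$A_peak[k] <- s + 3 * ft / 4
    truth$FT_end[k] <- s + ft
    truth$ET_start[k] <- es
    truth$ET_end[k] <- es + et
  }

  if (spec$click_amplitude > 0) {
    click_t <- c(truth$FT_start, truth$FT_end, truth$ET_start, truth$ET_end)
    idx <- round(click_t / spec$dt_ms) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    x[idx] <- x[idx] + spec$click_amplitude
  }

  if (spec$noise_sd > 0) {
    x <- x + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  }

  list(signal = envelope_signal(x, spec$dt_ms), truth = truth)
}

#' Myocardial performance indices implied by a generator spec
#'
#' The interval fractions fix the Tei index and K-index of every generated
#' cycle independently of heart rate:
#' TI = (IVCT + IVRT) / ET and KI = (IVCT + IVRT) / FT.
#'
#' @param spec a [synth_spec()].
#' @return named numeric vector with elements `TI` and `KI`.
#' @export
implied_mpi <- function(spec) {
  iso <- spec$frac_ivct + spec$frac_ivrt
  c(TI = iso / spec$frac_et, KI = iso / spec$frac_ft)
}
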