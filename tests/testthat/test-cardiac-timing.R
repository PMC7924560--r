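hand_landmarks <- data.frame(
  cycle = 1, prev_ET_end = 0, FT_start = 48, E_peak = 110, A_peak = 210,
  FT_end = 283, ET_start = 326, ET_end = 496
)

test_that("interval computation is plain landmark arithmetic", {
  iv <- compute_intervals(hand_landmarks, dt_ms = 1)
  expect_equal(iv$IVRT, 48)
  expect_equal(iv$FT, 235)
  expect_equal(iv$IVCT, 43)
  expect_equal(iv$ET, 170)
  expect_equal(iv$cycle_length, 496)

  bad <- hand_landmarks
  bad$ET_start <- 280   # before FT_end
  expect_error(compute_intervals(bad, 1), "degenerate cycle")
  expect_error(compute_intervals(hand_landmarks, 0), "dt_ms")
})

test_that("Tei index and K-index reproduce hand-computed values exactly", {
  iv <- compute_intervals(hand_landmarks, dt_ms = 1)
  expect_equal(tei_index(iv), (43 + 48) / 170, tolerance = 1e-15)
  expect_equal(k_index(iv), (43 + 48) / 235, tolerance = 1e-15)
  # symmetry: equal isovolumetric times
  expect_equal(tei_index(list(IVCT = 30, IVRT = 30, ET = 150)), 2 * 30 / 150)
  expect_equal(k_index(list(IVCT = 0, IVRT = 0, FT = 200)), 0)
  expect_error(tei_index(list(IVCT = 1, IVRT = 1, ET = 0)), "ET")
  expect_error(k_index(list(IVCT = 1, IVRT = 1, FT = -5)), "FT")
})

test_that("landmarks are recovered on clean fixtures, with and without clicks", {
  for (click in c(10, 0)) {
    tol <- if (click > 0) 2 else 3
    spec <- synth_spec(click_amplitude = click)
    ge <- generate_envelope(spec)
    pk <- detect_a_waves(ge$signal)
    lm <- locate_landmarks(ge$signal, pk)
    expect_gte(nrow(lm), 4L)
    tr <- ge$truth
    ci <- vapply(lm$A_peak, function(a) {
      which.min(abs(round(tr$A_peak) + 1 - a))
    }, integer(1))
    for (nm in c("FT_start", "E_peak", "A_peak", "FT_end", "ET_start", "ET_end")) {
      expect_true(all(abs(lm[[nm]] - (round(tr[[nm]][ci]) + 1)) <= tol),
                  info = sprintf("%s (click=%g)", nm, click))
    }
    expect_true(all(abs(lm$prev_ET_end - (round(tr$ET_end[ci - 1]) + 1)) <= tol))
    # interval sum identity against the generator cycle length
    iv <- compute_intervals(lm, spec$dt_ms)
    expect_true(all(abs(iv$cycle_length - tr$cycle_length_ms[ci]) <= 2 * spec$dt_ms))
  }
})

test_that("too few A-wave peaks is an error", {
  ge <- generate_envelope(synth_spec())
  expect_error(locate_landmarks(ge$signal, c(500L)), "insufficient cycles")
  expect_error(locate_landmarks(ge$signal, c(500L, 929L)), "insufficient cycles")
  expect_error(locate_landmarks(ge$signal, 1:5, window_frac = 0.8), "window_frac")
})

test_that("prepending baseline shifts landmarks but not intervals", {
  spec <- synth_spec()
  ge <- generate_envelope(spec)
  shift <- 300L
  padded <- envelope_signal(c(numeric(shift), ge$signal$values), spec$dt_ms)
  lm0 <- locate_landmarks(ge$signal, detect_a_waves(ge$signal))
  lm1 <- locate_landmarks(padded, detect_a_waves(padded))
  common <- intersect(lm0$A_peak + shift, lm1$A_peak)
  expect_gte(length(common), 4L)
  i0 <- match(common - shift, lm0$A_peak)
  i1 <- match(common, lm1$A_peak)
  for (nm in c("prev_ET_end", "FT_start", "E_peak", "FT_end", "ET_start", "ET_end")) {
    expect_equal(lm1[[nm]][i1], lm0[[nm]][i0] + shift)
  }
  iv0 <- compute_intervals(lm0[i0, ], spec$dt_ms)
  iv1 <- compute_intervals(lm1[i1, ], spec$dt_ms)
  expect_equal(iv1[c("IVCT", "IVRT", "ET", "FT")], iv0[c("IVCT", "IVRT", "ET", "FT")],
               ignore_attr = TRUE)
})

test_that("TI and KI are heart-rate invariant for fixed interval fractions", {
  tis <- kis <- c()
  for (hr in c(110, 125, 140, 160)) {
    e <- recovery_errors(synth_spec(heart_rate_bpm = hr))
    imp <- implied_mpi(synth_spec())
    tis <- c(tis, imp[["TI"]] + e[["ti_err"]])
    kis <- c(kis, imp[["KI"]] + e[["ki_err"]])
  }
  expect_lt(max(tis) - min(tis), 0.03)
  expect_lt(max(kis) - min(kis), 0.03)
})

test_that("waveform summary aggregates cycles and flags single-cycle SD", {
  iv <- compute_intervals(hand_landmarks, dt_ms = 1)
  one <- summarize_waveform(iv)
  expect_identical(one$cycles_used, 1L)
  expect_false(one$sd_defined)
  expect_true(all(one$summary$sd == 0))
  expect_equal(one$summary$mean[one$summary$measure == "TI"], 91 / 170)

  three <- summarize_waveform(rbind(iv, iv, iv))
  expect_identical(three$cycles_used, 3L)
  expect_true(all(three$summary$sd == 0))  # identical cycles
  expect_error(summarize_waveform(iv[0, ]), "zero valid cycles")
})
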