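test_that("rendering fills columns between baseline and velocity row", {
  cal <- calibration(dt_ms = 1, vel_per_px = 2, baseline_row = 20)
  # constant zero: only the drawn baseline is foreground
  z <- envelope_signal(numeric(50), dt_ms = 1)
  img <- render_to_image(z, cal, n_rows = 40)
  expect_true(all(img[20, ] == 1))
  expect_true(all(img[-20, ] == 0))

  # one sample at +10 cm/s with 2 (cm/s)/px: a 5-px column above the baseline
  v <- numeric(50); v[25] <- 10
  img <- render_to_image(envelope_signal(v, 1), cal, n_rows = 40)
  expect_identical(which(img[, 25] == 1), c(15:19, 20L))
  expect_true(all(img[1:19, -25] == 0))

  # negative velocities fill below the baseline
  v[25] <- -10
  img <- render_to_image(envelope_signal(v, 1), cal, n_rows = 40)
  expect_identical(which(img[, 25] == 1), c(20L, 21:25))

  expect_error(render_to_image(envelope_signal(c(0, 100), 1), cal, n_rows = 40),
               "clips")
  expect_error(render_to_image(envelope_signal(c(0, 1), 1),
                               calibration(2, 2, 20), n_rows = 40),
               "dt_ms")
})

test_that("binarization separates foreground by Otsu or fixed threshold", {
  blank <- matrix(0, 10, 10)
  expect_true(!any(binarize(blank, threshold = 128)))
  expect_error(binarize(blank, threshold = "otsu"), "degenerate histogram")

  two <- matrix(0, 10, 10)
  two[3:6, 2:9] <- 255
  mask <- binarize(two, threshold = "otsu")
  expect_identical(mask, two == 255)

  # fixed threshold is inclusive
  expect_identical(binarize(two, threshold = 255), two == 255)

  # foreground pixel count of a rendered trace equals the renderer's count
  ge <- generate_envelope(synth_spec(duration_s = 2))
  cal <- calibration(1, 1, baseline_row = 60)
  img <- render_to_image(ge$signal, cal)
  mask <- binarize(img * 255, threshold = "otsu")
  expect_identical(sum(mask), sum(img == 1))
})

test_that("baseline detection finds the longest horizontal run", {
  m <- matrix(FALSE, 30, 40)
  m[17, ] <- TRUE
  m[5, 1:10] <- TRUE
  bl <- detect_baseline(m)
  expect_identical(bl$row, 17L)
  expect_false(bl$low_confidence)

  # tie between two full-width rows: smaller index wins
  m[9, ] <- TRUE
  expect_identical(detect_baseline(m)$row, 9L)

  # no row spanning half the columns: flagged low confidence
  m2 <- matrix(FALSE, 10, 40)
  m2[4, 1:10] <- TRUE
  bl2 <- detect_baseline(m2)
  expect_identical(bl2$row, 4L)
  expect_true(bl2$low_confidence)

  expect_error(detect_baseline(matrix(FALSE, 5, 5)), "empty mask")

  # brute-force run-length oracle on a rendered image
  ge <- generate_envelope(synth_spec(duration_s = 2))
  img <- render_to_image(ge$signal, calibration(1, 1, baseline_row = 55))
  mask <- img == 1
  runs <- integer(nrow(mask))
  for (r in seq_len(nrow(mask))) {
    best <- 0L; cur <- 0L
    for (cc in seq_len(ncol(mask))) {
      cur <- if (mask[r, cc]) cur + 1L else 0L
      best <- max(best, cur)
    }
    runs[r] <- best
  }
  expect_identical(detect_baseline(mask)$row, which.max(runs))
  expect_identical(detect_baseline(mask)$row, 55L)
})

test_that("envelope extraction recovers per-column velocities", {
  cal <- calibration(dt_ms = 1, vel_per_px = 2, baseline_row = 20)
  m <- matrix(FALSE, 40, 6)
  m[20, ] <- TRUE                 # baseline line is not signal
  m[10:19, 2] <- TRUE             # 10 px above -> +20
  m[21:25, 3] <- TRUE             # 5 px below -> -10
  m[15:19, 4] <- TRUE; m[21:28, 4] <- TRUE  # both sides: below wins (8 > 5)
  m[12:19, 5] <- TRUE; m[21:28, 5] <- TRUE  # tie: positive side wins
  es <- extract_envelope(m, cal)
  expect_equal(es$values, c(0, 20, -10, -16, 16, 0))
  expect_equal(es$dt_ms, 1)

  # doubling the velocity scale doubles every extracted value exactly
  es2 <- extract_envelope(m, calibration(1, 4, 20))
  expect_identical(es2$values, 2 * es$values)
})

test_that("render then extract round-trips within one velocity pixel", {
  for (vpp in c(0.5, 1)) {
    ge <- generate_envelope(synth_spec(duration_s = 2, click_amplitude = 10))
    cal <- calibration(dt_ms = 1, vel_per_px = vpp,
                       baseline_row = ceiling(60 / vpp))
    img <- render_to_image(ge$signal, cal)
    es <- extract_envelope(binarize(img, threshold = 0.5), cal)
    expect_lte(max(abs(es$values - ge$signal$values)), vpp)
  }
})

test_that("PNG and TIFF images read back as grayscale matrices", {
  ge <- generate_envelope(synth_spec(duration_s = 2))
  cal <- calibration(1, 1, baseline_row = 65)
  img <- render_to_image(ge$signal, cal)

  fp <- tempfile(fileext = ".png")
  png::writePNG(img, fp)
  back <- read_trace_image(fp)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)

  ft <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(img, ft)
  expect_identical(dim(read_trace_image(ft)), dim(img))

  # RGB input collapses to luminance
  rgb <- array(rep(img, 3), dim = c(dim(img), 3))
  fp3 <- tempfile(fileext = ".png")
  png::writePNG(rgb, fp3)
  expect_lt(max(abs(read_trace_image(fp3) - img)), 1 / 255)

  expect_error(read_trace_image(tempfile(fileext = ".png")), "unreadable")
  unlink(c(fp, ft, fp3))
})
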