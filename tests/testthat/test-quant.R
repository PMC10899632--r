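mob <- mobility_model()
scheme <- default_bin_scheme()

test_that("marker peaks are found at band centers within half a pixel", {
  ml <- marker_lane(default_markers(), mob, psf_sigma = 2, gain = 1e4)
  peaks <- detect_marker_peaks(ml)
  truth <- map_length_to_pixel(mob, default_markers())
  ## detected coordinates use the pixel-index convention (bin i covers
  ## [i, i+1)), a constant -0.5 px offset from the continuous band center
  expect_equal(length(peaks), 6)
  expect_true(all(abs(peaks - (truth - 0.5)) < 0.5))

  flat <- marker_lane(numeric(0), mob)
  expect_length(detect_marker_peaks(flat), 0)

  merged <- marker_lane(c(100, 101), mob, psf_sigma = 40)
  expect_error(detect_marker_peaks(merged, n_expected = 2), "expected 2")
})

test_that("size calibration recovers exact and noisy affine mappings", {
  cal <- fit_size_calibration(c(100, 200, 300, 400), c(60, 110, 160, 210))
  expect_equal(cal$residuals, rep(0, 4), tolerance = 1e-10)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$slope, 2)
  expect_equal(calibration_length(cal, calibration_pixel(cal, 80:90)),
               as.numeric(80:90))

  two <- fit_size_calibration(c(10, 20), c(60, 120))
  expect_equal(two$r_squared, 1)

  ml <- marker_lane(default_markers(), mob, psf_sigma = 2, gain = 1e4,
                    noise_sd = 5, seed = 9)
  cal2 <- fit_size_calibration(detect_marker_peaks(ml, n_expected = 6),
                               default_markers())
  expect_lt(abs(cal2$slope - mob$slope) / mob$slope, 0.02)

  expect_error(fit_size_calibration(c(1, 2, 3), c(60, 90)), "3 peaks")
  expect_error(fit_size_calibration(100, 60), "at least 2")
  expect_error(fit_size_calibration(c(10, 30, 20), c(60, 90, 120)),
               "monotonic")
  expect_error(fit_size_calibration(c(10, 20, 30), c(60, 90, 90)),
               "strictly increasing")
})

test_that("tidy/glance expose the calibration fit", {
  cal <- fit_size_calibration(c(100, 200, 305, 400), c(60, 110, 160, 210))
  td <- tidy(cal)
  expect_equal(td$term, c("(Intercept)", "length"))
  gl <- glance(cal)
  expect_equal(gl$n_markers, 4)
  expect_lt(gl$r.squared, 1)
})

test_that("linear calibration of a log-mobility gel surfaces curved residuals", {
  lmob <- mobility_model("log")
  ml <- marker_lane(default_markers(), lmob, psf_sigma = 2)
  cal <- fit_size_calibration(detect_marker_peaks(ml, n_expected = 6),
                              default_markers(), mode = "linear")
  expect_gt(max(abs(cal$residuals)), 1)       # far beyond peak-location error
  ## curvature: end residuals share a sign, middle residuals the opposite
  expect_gt(cal$residuals[1] * cal$residuals[6], 0)
  expect_lt(cal$residuals[1] * cal$residuals[3], 0)
  ## fitting in log mode instead is clean
  call <- fit_size_calibration(detect_marker_peaks(ml, n_expected = 6),
                               default_markers(), mode = "log")
  expect_lt(max(abs(call$residuals)), 0.5)
})

test_that("background subtraction: lane minimum, offsets, sloped baselines", {
  const <- lengths_to_profile(tibble::tibble(length = 100, fraction = 1),
                              mob, psf_sigma = 2, gain = 1e4)
  flat <- const
  flat$intensity <- rep(7, nrow(flat))
  expect_true(all(subtract_background(flat, "min")$intensity == 0))

  cal <- fit_size_calibration(
    detect_marker_peaks(marker_lane(mobility = mob, psf_sigma = 2)),
    default_markers()
  )
  p <- sim_params(n_molecules = 1000, seed = 21)
  d <- simulate_ensemble(p, make_landscape(default_template(), "WT"))
  prof <- lengths_to_profile(d[d$time_s == 60, ], mob, psf_sigma = 2,
                             gain = 1e4)
  f0 <- bin_lane(prof, cal, scheme)

  shifted <- prof
  shifted$intensity <- shifted$intensity + 25
  f_min <- bin_lane(subtract_background(shifted, "min"), cal, scheme)
  expect_equal(as.numeric(f_min), as.numeric(f0), tolerance = 1e-8)

  ramp <- prof
  ramp$intensity <- ramp$intensity + seq(0, 50, length.out = nrow(ramp))
  f_roll <- bin_lane(subtract_background(ramp, "rolling_min"), cal, scheme)
  expect_lt(max(abs(as.numeric(f_roll) - as.numeric(f0))), 0.01)

  expect_error(subtract_background(prof, "rolling_min", width = 0), "width")
})

test_that("bin_lane integrates lanes into a unit-sum seven-bin partition", {
  cal <- fit_size_calibration(
    detect_marker_peaks(marker_lane(mobility = mob, psf_sigma = 2)),
    default_markers()
  )
  stalled <- lengths_to_profile(tibble::tibble(length = 58, fraction = 1),
                                mob, psf_sigma = 2, gain = 1e4)
  f <- bin_lane(stalled, cal, scheme)
  expect_equal(f$bin1, 1, tolerance = 1e-4)
  expect_equal(sum(as.numeric(f)), 1)

  mids <- tibble::tibble(length = scheme$midpoint, fraction = rep(1 / 7, 7))
  fm <- bin_lane(lengths_to_profile(mids, mob, psf_sigma = 2, gain = 1e4),
                 cal, scheme)
  expect_true(all(abs(as.numeric(fm) - 1 / 7) < 0.02))

  ## scale invariance of per-lane normalization
  scaled <- stalled
  scaled$intensity <- scaled$intensity * 37
  expect_equal(as.numeric(bin_lane(scaled, cal, scheme)), as.numeric(f))

  steep <- fit_size_calibration(c(100, 4000), c(60, 65))
  expect_error(bin_lane(stalled, steep, scheme), "domain")
})

test_that("synthesize-then-quantify reproduces direct binning per lane", {
  p <- sim_params(n_molecules = 2000, seed = 13)
  for (variant in c("HTkA-free", "E19K")) {
    d <- simulate_ensemble(p, make_landscape(default_template(), variant))
    direct <- bin_distribution(d, scheme)
    g <- synthesize_gel(d, psf_sigma = 2, gain = 1e4, noise_sd = 0)
    q <- quantify_gel(g, condition = variant, tfs = FALSE, replicate = 1L)
    err <- max(abs(as.matrix(direct[, bin_cols]) -
                     as.matrix(q$bin_table[, bin_cols])))
    expect_lt(err, 0.02)
    expect_equal(q$bin_table$time_s, direct$time_s)
    expect_equal(q$calibration$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("calibration reports serialize coefficients and residuals", {
  cal <- fit_size_calibration(c(100, 200, 305, 400), c(60, 110, 160, 210))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(cal, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$mode, "linear")
  expect_equal(rep$slope, cal$slope)
  expect_length(rep$residuals, 4)
})

test_that("waterfall normalization scales lanes by the SM total", {
  sm <- lengths_to_profile(tibble::tibble(length = 58, fraction = 1),
                           mob, psf_sigma = 2, gain = 1e4)
  self <- waterfall_normalize(list(SM = sm), sm)
  expect_equal(sum(self$rel_intensity), 1, tolerance = 1e-6)

  dbl <- sm
  dbl$intensity <- dbl$intensity * 2
  w <- waterfall_normalize(list(SM = sm, t2 = dbl), sm)
  expect_equal(sum(w$rel_intensity[w$lane == "t2"]), 2, tolerance = 1e-6)

  ## signal conservation across a no-loss simulated time course
  p <- sim_params(n_molecules = 1000, seed = 17)
  d <- simulate_ensemble(p, make_landscape(default_template(), "WT"))
  g <- synthesize_gel(d, psf_sigma = 2, gain = 1e4, noise_sd = 0)
  wf <- waterfall_normalize(g)
  sums <- tapply(wf$rel_intensity, wf$lane, sum)
  expect_true(all(abs(sums - 1) < 0.02))

  zero <- sm
  zero$intensity <- zero$intensity * 0
  expect_error(waterfall_normalize(list(a = sm), zero), "zero")

  cal <- fit_size_calibration(
    detect_marker_peaks(marker_lane(mobility = mob, psf_sigma = 2)),
    default_markers()
  )
  wl <- waterfall_normalize(g, calibration = cal)
  expect_true("length" %in% names(wl))
})
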