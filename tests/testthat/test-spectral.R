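test_that("spectrum_histogram localizes a known tone", {
  t <- (0:1599) / 8          # 200 s at 8 Hz
  x <- sin(2 * pi * 0.25 * t)
  sp <- spectrum_histogram(x, 8)
  pk <- peak_groups(sp)
  expect_equal(pk$primary$freq, 0.25)
  expect_equal(pk$primary$mag, 1, tolerance = 1e-6)
  expect_identical(nrow(pk$secondaries), 0L)
  expect_error(spectrum_histogram(x[1:8], 8), "16 samples")
})

test_that("spectrum satisfies Parseval and is linear in amplitude", {
  set.seed(40)
  x <- rnorm(512)
  sp <- spectrum_histogram(x, 8)
  n <- attr(sp, "n")
  # undo the one-sided amplitude scaling: w = 2 except DC / Nyquist bins
  w <- rep(2, nrow(sp)); w[1] <- 1; w[nrow(sp)] <- 1
  sum_X2 <- sum((sp$mag * n / w)^2 * w)
  expect_equal(sum_X2 / n, sum(x^2), tolerance = 1e-6)
  expect_equal(spectrum_histogram(3.5 * x, 8)$mag, 3.5 * sp$mag)
})

test_that("simulated wall-climbing a_z has its primary peak at 0.25 Hz", {
  tpl <- default_templates()[[3]]
  tpl$noise_sd <- 0
  s <- simulate_exercise(tpl, seed = 2, duration = 120)
  pk <- peak_groups(spectrum_histogram(s$az, 8))
  expect_equal(pk$primary$freq, 0.25, tolerance = 1e-9)
  # the a_y minor component at 0.8 Hz is present in the template
  expect_equal(tpl$minor$axis, "ay")
  expect_equal(tpl$minor$freq, 0.8)
})

test_that("secondary peaks obey the quarter-amplitude threshold", {
  t <- (0:1599) / 8
  two_tone <- function(r) sin(2 * pi * 0.25 * t) + r * sin(2 * pi * 1 * t)
  pk_hi <- peak_groups(spectrum_histogram(two_tone(0.3), 8))
  expect_identical(nrow(pk_hi$secondaries), 1L)     # 0.3 > 1/4
  expect_equal(pk_hi$secondaries$freq, 1)
  pk_lo <- peak_groups(spectrum_histogram(two_tone(0.2), 8))
  expect_identical(nrow(pk_lo$secondaries), 0L)     # 0.2 < 1/4
  # monotone threshold: raising an amplitude never drops the secondary
  pk_up <- peak_groups(spectrum_histogram(two_tone(0.6), 8))
  expect_identical(nrow(pk_up$secondaries), 1L)
  expect_error(peak_groups(raw_spectrum(rep(0, 9))), "no peaks")
})

test_that("lowpass_downsample passes DC, rejects the stopband, keeps length", {
  p <- filter_params(w1 = 0.115, dw = 0.1)
  dc <- rep(1, 400)
  y <- lowpass_downsample(dc, p)
  expect_equal(y, rep(1, length(y)), tolerance = 1e-12)   # unit passband gain
  # documented alignment: drop order/2 transients each end, keep 1 in 5
  expect_length(y, length(seq(1, 400 - p$order, by = p$factor)))
  # tone far above cutoff (0.115 * 4 Hz = 0.46 Hz) is attenuated
  t <- (0:1999) / 8
  tone <- sin(2 * pi * 2.5 * t)
  out <- lowpass_downsample(tone, p)
  expect_lt(sqrt(mean(out^2)), 0.05 * sqrt(mean(tone^2)))
  expect_error(lowpass_downsample(rep(1, 50), p), "too short")
})

test_that("envelope matches the pencil-and-paper 8-bin construction", {
  sp <- raw_spectrum(c(0, 1, 4, 1, 2, 3, 1, 0.5), rate = 8, n = 16)
  env <- envelope_spectrum(sp, w1 = 0.25, dw = 0.25)
  # knots at the per-interval peaks (1@0.125, 4@0.25, 3@0.625, 1@0.75 of
  # Nyquist-normalized frequency); chords interpolate, pmax restores peaks
  expect_equal(env$mag, c(0, 1, 4, 11 / 3, 10 / 3, 3, 1, 0.5))
  expect_true(all(env$mag >= sp$mag))
  expect_equal(magnitude_difference(env, sp), 176 / 9)
  expect_error(envelope_spectrum(sp, w1 = 0.25, dw = 0.01), "resolution")
})

test_that("magnitude_difference follows its definition", {
  a <- raw_spectrum(c(1, 2, 1))
  b <- raw_spectrum(c(1, 2, 2))
  expect_equal(magnitude_difference(b, a), 3)   # (1+4+4) - (1+4+1)
  expect_equal(magnitude_difference(a, a), 0)
  expect_error(magnitude_difference(a, raw_spectrum(c(1, 2))), "grid")
  # dE >= 0 whenever the envelope dominates pointwise (definitional)
  set.seed(41)
  x <- rnorm(256)
  sp <- spectrum_histogram(x, 8)
  env <- envelope_spectrum(sp, 0.115, 0.1)
  expect_true(all(env$mag >= sp$mag - 1e-12))
  expect_gte(magnitude_difference(env, sp), 0)
})

test_that("envelope equals the original on a monotone peak chain", {
  # decreasing staircase: every chord stays below the step levels
  sp <- staircase_spectrum(440)
  env <- envelope_spectrum(sp, w1 = 0.115, dw = 0.1)
  expect_equal(env$mag, sp$mag)
  expect_equal(magnitude_difference(env, sp), 0)
})

test_that("select_filter_params picks (0.115, 0.1) on the engineered set", {
  spectra <- lapply(c(400, 440, 500, 560), staircase_spectrum)
  sel <- select_filter_params(spectra, w1_grid = c(0.065, 0.115, 0.165),
                              dw_grid = c(0.1, 0.15, 0.2))
  expect_equal(sel$w1, 0.115)
  expect_equal(sel$dw, 0.1)
  # a collection of identical spectra returns the single-spectrum argmin
  one <- spectrum_histogram(sin(2 * pi * 0.3 * (0:799) / 8) +
                              0.4 * sin(2 * pi * 1.1 * (0:799) / 8), 8)
  tab1 <- attr(select_filter_params(list(one), c(0.1, 0.2), c(0.05, 0.1)),
               "table")
  best <- tab1[order(tab1$dE, tab1$dw, tab1$w1), ][1, ]
  sel1 <- select_filter_params(list(one, one, one), c(0.1, 0.2), c(0.05, 0.1))
  expect_equal(sel1$w1, best$w1)
  expect_equal(sel1$dw, best$dw)
  # exhaustive brute force reproduces the dE table
  brute <- sapply(seq_len(nrow(tab1)), function(i)
    magnitude_difference(envelope_spectrum(one, tab1$w1[i], tab1$dw[i]), one))
  expect_equal(tab1$dE, brute)
})

test_that("the envelope pipeline is deterministic", {
  x <- sin(2 * pi * 0.4 * (0:999) / 8)
  s1 <- select_filter_params(list(spectrum_histogram(x, 8)),
                             c(0.1, 0.115), c(0.1, 0.2))
  s2 <- select_filter_params(list(spectrum_histogram(x, 8)),
                             c(0.1, 0.115), c(0.1, 0.2))
  expect_identical(unclass(s1)[c("w1", "dw", "dE")],
                   unclass(s2)[c("w1", "dw", "dE")])
})
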