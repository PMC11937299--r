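test_that("detect_extrema follows the alternating-extrema hand trace", {
  ex <- detect_extrema(c(0, 12, 1, 15, 2), positions = 0:4, delta = 10)
  expect_equal(ex$maxima$position, c(1, 3))
  expect_equal(ex$maxima$value, c(12, 15))
  expect_equal(ex$minima$position, 2)
  expect_equal(ex$minima$value, 1)
})

test_that("monotone series yield no extrema and scaling is equivariant", {
  expect_equal(nrow(detect_extrema(1:50, delta = 5)$maxima), 0)
  v <- c(0, 30, 4, 22, 1, 40, 2)
  a <- detect_extrema(v, delta = 10)
  b <- detect_extrema(v * 7, delta = 70)
  expect_equal(a$maxima$index, b$maxima$index)
  expect_equal(a$minima$index, b$minima$index)
})

test_that("detect_extrema matches the independent reference on random series", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:50, 1)
    v <- round(runif(n, 0, 60), 1)
    delta <- sample(c(1, 10, 25), 1)
    got <- detect_extrema(v, delta = delta)
    ref <- ref_extrema(v, delta)
    expect_equal(got$maxima$index, ref$max_idx)
    expect_equal(got$minima$index, ref$min_idx)
    # every maximum exceeds its neighbouring reported minima by >= delta
    mx <- got$maxima$index; mn <- got$minima$index
    for (i in seq_along(mx)) {
      prev <- mn[mn < mx[i]]
      nxt <- mn[mn > mx[i]]
      if (length(prev)) expect_gte(v[mx[i]] - v[max(prev)], delta)
      if (length(nxt)) expect_gte(v[mx[i]] - v[min(nxt)], delta)
    }
  }
})

test_that("the preceding-minimum delta variant fires on any reversal", {
  # rise of 12 from the start, then a 1-unit dip: classic semantics with
  # delta 10 see no 10-unit drop, the variant emits the maximum at the dip
  v <- c(0, 12, 11, 12.5, 11.5)
  expect_equal(nrow(detect_extrema(v, delta = 10)$maxima), 0)
  ex <- detect_extrema(v, delta = 10, delta_mode = "preceding_min")
  expect_equal(ex$maxima$index, 2)
})

test_that("estimate_noise is a robust scale of clean intensities", {
  mk <- function(v) msi_spectrum(seq_along(v), v)
  expect_equal(estimate_noise(list(mk(rep(3, 50)))), 3)
  spiky <- c(rep(3, 49), 5000)
  expect_equal(estimate_noise(list(mk(spiky))), 3)
  set.seed(5)
  b <- 2.5
  clean <- matrix(abs(rnorm(200 * 400, sd = b)), nrow = 200)
  est <- estimate_noise(clean)
  # |N(0, b)| has median ~0.674 b
  expect_lt(abs(est - 0.674 * b) / (0.674 * b), 0.15)
  expect_error(estimate_noise(list()), "no clean spectra")
})

test_that("pick_pixel_peaks thresholds inclusively and keeps top-k", {
  mz <- seq(100, 100 + 27, by = 1)
  v <- rep(0, length(mz))
  v[seq(2, 26, by = 4)] <- c(100, 90, 80, 70, 60, 50, 40)  # 7 clear maxima
  sp <- msi_spectrum(mz, v)
  pk <- pick_pixel_peaks(sp, detection_params(), noise = 1)
  expect_equal(nrow(pk), 5)
  expect_equal(pk$intensity, c(100, 90, 80, 70, 60))  # intensity-descending

  # all maxima below 10x noise -> empty, and the pixel fails the filter
  pk2 <- pick_pixel_peaks(sp, detection_params(), noise = 50)
  expect_equal(nrow(pk2), 0)
  expect_false(pixel_passes_signal_filter(pk2))

  # boundary: a peak at exactly noise_factor x noise is kept
  v3 <- c(0, 50, 0, 30, 0)
  pk3 <- pick_pixel_peaks(msi_spectrum(1:5, v3), detection_params(), noise = 5)
  expect_true(50 %in% pk3$intensity)

  # appending pure baseline below threshold does not change the result
  v4 <- c(v, rep(0.5, 30))
  pk4 <- pick_pixel_peaks(msi_spectrum(seq_along(v4), v4),
                          detection_params(), noise = 1)
  expect_equal(pk4$intensity, pk$intensity)
})

test_that("background ions do not count as pixel signal", {
  pk <- data.frame(mz = c(301.0, 413.5), intensity = c(40, 30))
  expect_true(pixel_passes_signal_filter(pk))
  expect_false(pixel_passes_signal_filter(pk, background_mz = c(301, 413.5)))
  expect_true(pixel_passes_signal_filter(rbind(pk, data.frame(
    mz = 1088, intensity = 200)), background_mz = c(301, 413.5)))
})

test_that("collect_background_ions keeps only prevalent consolidated ions", {
  mk <- function(pixel, mz) data.frame(pixel = pixel, mz = mz, intensity = 50)
  pk <- rbind(mk(1:100, 301.02), mk(1, 999))
  bg <- collect_background_ions(pk, n_pixels = 100, min_fraction = 0.25)
  expect_equal(length(bg), 1)
  expect_lt(abs(bg - 301.02), 0.1)
  # an ion in 1 of 100 pixels is excluded
  expect_false(any(abs(bg - 999) < 0.5))
  # per-pixel list input
  lst <- c(lapply(1:4, function(i) data.frame(mz = 500.0, intensity = 20)),
           list(data.frame(mz = numeric(), intensity = numeric())))
  expect_equal(collect_background_ions(lst), 500)
})
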