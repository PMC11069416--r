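test_that("optical density conversion matches the closed-form definition", {
  # constant intensity: OD identically zero
  raw <- raw_intensity(array(1000, c(2, 100, 3)), fs = 8.33)
  expect_equal(intensity_to_od(raw)$values, array(0, c(2, 100, 3)))

  # I = mean * exp(-1) at one sample gives OD = 1 there: build a series
  # whose temporal mean is exactly 600 with one sample at 600 * exp(-1)
  n <- 200
  x <- rep((n * 600 - 600 * exp(-1)) / (n - 1), n)
  x[50] <- 600 * exp(-1)
  raw <- raw_one_channel(x)
  od <- intensity_to_od(raw)$values[1, , 1]
  expect_equal(od[50], 1, tolerance = 1e-12)

  # random positive series: per-sample formula to 1e-12
  set.seed(11)
  v <- array(exp(rnorm(3 * 150 * 3, sd = 0.2)) * 800, c(3, 150, 3))
  raw <- raw_intensity(v, fs = 8.33)
  od <- intensity_to_od(raw)$values
  for (ch in 1:3) for (w in 1:3)
    expect_equal(od[ch, , w], -log(v[ch, , w] / mean(v[ch, , w])),
                 tolerance = 1e-12)
})

test_that("non-positive intensities are rejected with channel and sample", {
  v <- array(100, c(2, 50, 3))
  v[2, 10, 1] <- 0
  expect_error(raw_intensity(v, fs = 8.33), "channel 2, sample 10")
})

test_that("MBLL inverts its own forward model and is linear", {
  # zero OD gives zero concentrations
  od0 <- intensity_to_od(raw_intensity(array(1000, c(1, 80, 3)), fs = 8.33))
  conc0 <- od_to_concentration(od0)
  expect_equal(max(abs(conc0$hbo)), 0)
  expect_equal(max(abs(conc0$hbr)), 0)

  # forward-generate OD from known (1, -0.3) uM and invert: 1e-9 relative
  set.seed(12)
  nt <- 300
  hbo <- 1 * sin(seq(0, 6 * pi, length.out = nt))
  hbr <- -0.3 * hbo
  ext <- extinction_coefficients()
  od <- array(0, c(1, nt, 3))
  for (w in 1:3)
    od[1, , w] <- (ext$eps_hbo[w] * hbo / 1000 + ext$eps_hbr[w] * hbr / 1000) * 3 * 6
  odobj <- structure(list(values = od, fs = 8.33, wavelengths = c(780, 805, 830),
                          channels = NULL), class = "ib_od")
  conc <- od_to_concentration(odobj)
  expect_equal(conc$hbo[1, ], hbo, tolerance = 1e-9)
  expect_equal(conc$hbr[1, ], hbr, tolerance = 1e-9)

  # doubling OD doubles both concentrations
  od2 <- odobj; od2$values <- 2 * od2$values
  conc2 <- od_to_concentration(od2)
  expect_equal(conc2$hbo, 2 * conc$hbo, tolerance = 1e-12)
  expect_equal(conc2$hbr, 2 * conc$hbr, tolerance = 1e-12)
})

test_that("CBSI matches its closed forms and is HbR-scale invariant", {
  set.seed(13)
  h <- cumsum(rnorm(200))
  mk <- function(hbo, hbr) structure(
    list(hbo = matrix(hbo, 1), hbr = matrix(hbr, 1), fs = 8.33,
         dpf = c(6, 6, 6), channels = NULL), class = "ib_conc")

  # HbR = -HbO: alpha = 1, x = HbO
  a <- cbsi(mk(h, -h))
  expect_equal(a$alpha[1], 1)
  expect_equal(a$values[1, ], h, tolerance = 1e-12)

  # HbR = +HbO: alpha = 1, x = 0
  b <- cbsi(mk(h, h))
  expect_equal(b$values[1, ], rep(0, length(h)), tolerance = 1e-12)

  # random pair: direct formula to 1e-12
  hbo <- rnorm(150); hbr <- rnorm(150)
  cc <- cbsi(mk(hbo, hbr))
  alpha <- sd(hbo) / sd(hbr)
  expect_equal(cc$values[1, ], (hbo - alpha * hbr) / 2, tolerance = 1e-12)

  # scaling HbR by k > 0 leaves x unchanged (alpha absorbs k)
  for (k in c(0.25, 3, 17)) {
    ck <- cbsi(mk(hbo, k * hbr))
    expect_equal(ck$values[1, ], cc$values[1, ], tolerance = 1e-12)
  }

  # zero-variance HbR flags the channel degenerate
  dg <- cbsi(mk(hbo, rep(0, 150)))
  expect_true(dg$degenerate[1])
  expect_true(all(is.na(dg$values[1, ])))
})

test_that("band-pass filter meets its frequency-response contract", {
  fs <- 8.33
  n <- round(600 * fs)
  t <- (seq_len(n) - 1) / fs
  gain_at <- function(f) {
    od <- structure(list(values = array(sin(2 * pi * f * t), c(1, n, 3)),
                         fs = fs, wavelengths = c(780, 805, 830),
                         channels = NULL), class = "ib_od")
    y <- bandpass_filter(od)$values[1, , 1]
    mid <- (n %/% 4):(3 * n %/% 4)
    # FFT amplitude ratio at the probe frequency
    probe <- function(v) Mod(sum(v[mid] * exp(-2i * pi * f * t[mid])))
    probe(y) / probe(sin(2 * pi * f * t))
  }
  # DC rejection
  dc <- structure(list(values = array(7, c(1, n, 3)), fs = fs,
                       wavelengths = c(780, 805, 830), channels = NULL),
                  class = "ib_od")
  expect_lt(max(abs(bandpass_filter(dc)$values)), 1e-6 * 7)
  expect_gt(gain_at(0.05), 0.95)
  expect_lt(gain_at(1.1), 0.01)
  # out-of-range corner is rejected
  expect_error(bandpass_filter(dc, lo = 0.01, hi = 5), "Nyquist")
})

test_that("band-pass output has negligible power outside 0.005-0.5 Hz", {
  set.seed(14)
  fs <- 8.33; n <- 4096
  od <- structure(list(values = array(rnorm(n), c(1, n, 3)), fs = fs,
                       wavelengths = c(780, 805, 830), channels = NULL),
                  class = "ib_od")
  y <- bandpass_filter(od)$values[1, , 1]
  sp <- Mod(fft(y))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  out_band <- f < 0.005 | f > 0.5
  expect_lt(sum(sp[out_band]) / sum(sp), 0.01)
})

test_that("wavelet motion correction removes transients and keeps smooth signal", {
  fs <- 8.33; n <- 1000
  t <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * 0.05 * t)
  od_of <- function(x) structure(
    list(values = array(x, c(1, length(x), 3)), fs = fs,
         wavelengths = c(780, 805, 830), channels = NULL), class = "ib_od")

  # smooth low-frequency sinusoid passes nearly untouched
  y <- motion_correct_wavelet(od_of(s))$values[1, , 1]
  expect_lt(sqrt(mean((y - s)^2)) / sqrt(mean(s^2)), 0.05)

  # injected 10-SD spike is suppressed below 10% of its amplitude
  k <- 500; A <- 10 * sd(s)
  sp <- s; sp[k] <- sp[k] + A
  yc <- motion_correct_wavelet(od_of(sp))$values[1, , 1]
  expect_lt(abs(yc[k] - s[k]) / A, 0.10)

  # all-zero input stays exactly zero
  z <- motion_correct_wavelet(od_of(rep(0, 512)))$values[1, , 1]
  expect_equal(z, rep(0, 512))

  # too-short series passes through with a warning
  short <- od_of(rnorm(12))
  expect_warning(out <- motion_correct_wavelet(short), "too short")
  expect_equal(out$values, short$values)
})

test_that("the underlying wavelet transform reconstructs exactly", {
  set.seed(15)
  x <- cumsum(rnorm(1024))
  dec <- interbrain:::dwt_full(x)
  expect_equal(interbrain:::idwt_full(dec), x, tolerance = 1e-12)
  # orthonormality: energy preserved across the decomposition
  energy <- sum(interbrain:::dwt_full(x)$approx^2) +
    sum(unlist(lapply(dec$details, function(d) sum(d^2))))
  expect_equal(energy, sum(x^2), tolerance = 1e-10)
})

test_that("channel quality gates heartbeat, saturation and jumps", {
  cfg <- test_config(seed = 21)
  s <- simulate_session(cfg, 1)
  raw <- s$participants$A

  # simulated channels carry a cardiac oscillation and pass
  q <- channel_quality(raw)
  expect_true(all(q$included))

  # flat-lined channel at a rail value is excluded for saturation
  sat <- raw$values
  sat[1, , ] <- 4000
  qs <- channel_quality(raw_intensity(sat, raw$fs), rail = 4000)
  expect_true(qs$saturation_flag[1])
  expect_false(qs$included[1])

  # removing the cardiac oscillation excludes the channel for heartbeat
  nohb <- simulate_session(test_config(seed = 21, heartbeat_amp = 0), 1)
  qh <- channel_quality(nohb$participants$A)
  expect_true(all(!qh$included))
  expect_true(all(qh$heartbeat_snr_db < 18))
})

test_that("preprocessing preserves shape and records the fixed stage order", {
  cfg <- test_config(seed = 22)
  s <- simulate_session(cfg, 1)
  raw <- sub_raw(s$participants$A, 1:3)
  d <- dim(raw$values)

  od <- intensity_to_od(raw)
  expect_equal(dim(od$values), d)
  odm <- motion_correct_wavelet(od)
  expect_equal(dim(odm$values), d)
  odb <- bandpass_filter(odm)
  expect_equal(dim(odb$values), d)
  conc <- od_to_concentration(odb)
  expect_equal(dim(conc$hbo), d[1:2])
  act <- cbsi(conc)
  expect_equal(dim(act$values), d[1:2])

  full <- preprocess_session(raw)
  prov <- attr(full, "provenance")
  expect_identical(prov$stages,
                   c("intensity_to_od", "motion_correct_wavelet",
                     "bandpass_filter", "od_to_concentration", "cbsi"))
  expect_equal(dim(full$values), d[1:2])
})
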