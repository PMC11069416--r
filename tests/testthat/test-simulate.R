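test_that("identical config and seed give bit-identical sessions", {
  cfg <- test_config(seed = 61)
  s1 <- simulate_session(cfg, 2)
  s2 <- simulate_session(cfg, 2)
  expect_identical(s1$participants$A$values, s2$participants$A$values)
  expect_identical(s1$participants$B$values, s2$participants$B$values)
  expect_identical(s1$geometry, s2$geometry)
  expect_identical(s1$truth$coupling, s2$truth$coupling)
  # a different seed changes the data
  s3 <- simulate_session(test_config(seed = 62), 2)
  expect_false(identical(s1$participants$A$values, s3$participants$A$values))
})

test_that("counterbalancing alternates episode order across dyads", {
  tiny <- function(n) sim_config(n_dyads = n, phase_durations = c(10, 5, 10),
                                 n_channels_per_hemisphere = 13, seed = 63,
                                 artifact_rate = 0)
  co4 <- simulate_cohort(tiny(4))
  expect_equal(unname(table(co4$meta$video_order)), c(2L, 2L), ignore_attr = TRUE)

  co27 <- simulate_cohort(tiny(27))
  expect_equal(nrow(co27$meta), 27)
  expect_equal(sort(unname(table(co27$meta$video_order))), c(13L, 14L),
               ignore_attr = TRUE)

  # identical config + seed: identical metadata
  co27b <- simulate_cohort(tiny(27))
  expect_identical(co27$meta, co27b$meta)
})

test_that("coupling maps are validated", {
  expect_error(sim_config(coupling = tibble::tibble(
    phase = "video1", band = "gamma", roi = "TPJ_R", coupling = 0.5)),
    "unknown frequency band")
  expect_error(sim_config(coupling = tibble::tibble(
    phase = "video4", band = "high", roi = "TPJ_R", coupling = 0.5)),
    "unknown phase")
  expect_error(sim_config(coupling = tibble::tibble(
    phase = "video1", band = "high", roi = "TPJ_X", coupling = 0.5)),
    "unknown ROI")
  expect_error(sim_config(coupling = tibble::tibble(
    phase = "video1", band = "high", roi = "TPJ_R", coupling = 1.5)),
    "\\[0, 1\\]")
  # "all" expands to the eight ROIs
  cs <- coupling_spec(phase = "video1", band = "high", roi = "all", coupling = 0.3)
  expect_equal(nrow(cs), 8)
})

test_that("motion artifact injection is Poisson with faithful bookkeeping", {
  set.seed(64)
  x <- rnorm(1000)

  # rate 0: output equals input exactly
  out0 <- inject_motion_artifacts(x, fs = 8.33, rate_per_min = 0)
  expect_identical(out0$values, x)
  expect_equal(nrow(out0$events), 0)

  # rate 6/min on 120 s: mean count over 200 seeds within 3 SE of 12
  n120 <- round(120 * 8.33)
  counts <- vapply(1:200, function(s)
    nrow(inject_motion_artifacts(rnorm(n120), 8.33, 6, seed = s)$events),
    numeric(1))
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 200))

  # every recorded event modified the series at its sample; spikes are
  # at least 5 SD, widths under 2 s
  inj <- inject_motion_artifacts(x, 8.33, rate_per_min = 20, seed = 9)
  expect_gt(nrow(inj$events), 0)
  for (i in seq_len(nrow(inj$events))) {
    k <- inj$events$sample[i]
    expect_false(isTRUE(all.equal(inj$values[k], x[k])))
  }
  sp <- inj$events[inj$events$type == "spike", ]
  if (nrow(sp) > 0) {
    expect_true(all(abs(sp$amplitude) >= 5 * sd(x)))
    expect_true(all(sp$width_s < 2))
  }
  # determinism
  inj2 <- inject_motion_artifacts(x, 8.33, rate_per_min = 20, seed = 9)
  expect_identical(inj$values, inj2$values)
})

test_that("simulated intensities carry a cardiac spectral peak", {
  cfg <- test_config(seed = 65)
  s <- simulate_session(cfg, 1)
  raw <- s$participants$B
  nt <- dim(raw$values)[2]
  f <- (seq_len(nt) - 1) * cfg$fs / nt
  sel <- f >= 0.5 & f <= 2
  for (ch in seq_len(dim(raw$values)[1])) {
    x <- raw$values[ch, , 1]
    sp <- Mod(stats::fft(x - mean(x)))^2
    peak <- f[sel][which.max(sp[sel])]
    expect_lt(abs(peak - cfg$heartbeat_freq), 0.2)
  }
})

test_that("the forward model is inverted exactly by the MBLL stage", {
  cfg <- test_config(seed = 66, artifact_rate = 0, noise_sd = 0, drift_sd = 0,
                     heartbeat_amp = 0)
  s <- simulate_session(cfg, 1)
  conc <- od_to_concentration(intensity_to_od(s$participants$A))
  truth <- s$truth$latents$A
  centre <- function(m) m - rowMeans(m)
  scale_ref <- sd(truth$hbo)
  expect_lt(max(abs(centre(conc$hbo) - centre(truth$hbo))) / scale_ref, 1e-6)
  expect_lt(max(abs(centre(conc$hbr) - centre(truth$hbr))) / scale_ref, 1e-6)
})

test_that("zero-coupling dyads look like unrelated participants", {
  # band coherence of real (c = 0) pairs vs cross-dyad pairs drawn from the
  # same cohort: indistinguishable means
  cfg <- sim_config(n_dyads = 2, phase_durations = c(120, 10, 10),
                    n_channels_per_hemisphere = 13, seed = 67,
                    artifact_rate = 0)
  ch <- designated_channel(cfg, "TPJ_R")
  real <- c(); crossed <- c()
  for (k in 1:12) {
    cfgk <- sim_config(n_dyads = 2, phase_durations = c(120, 10, 10),
                       n_channels_per_hemisphere = 13, seed = 670 + k,
                       artifact_rate = 0)
    s1 <- simulate_session(cfgk, 1); s2 <- simulate_session(cfgk, 2)
    act <- lapply(list(s1$participants$A, s1$participants$B,
                       s2$participants$A, s2$participants$B),
                  function(r) preprocess_session(sub_raw(r, ch))$values[1, 1:1000])
    bv <- function(x, y) band_average(wtc(x, y, cfgk$fs), "medium")$value
    real <- c(real, bv(act[[1]], act[[2]]))
    crossed <- c(crossed, bv(act[[1]], act[[4]]))
  }
  # same distribution: difference of means within Monte-Carlo error
  tt <- stats::t.test(real, crossed)
  expect_gt(tt$p.value, 0.01)
})

test_that("band coherence increases with the configured coupling", {
  # full-pipeline Monte Carlo over coupling levels; the mean must not
  # decrease beyond Monte-Carlo error and the strongest level must clearly
  # exceed the null
  levels <- c(0, 0.3, 0.6, 0.9)
  nseed <- 30
  res <- sapply(levels, function(cpl) {
    vapply(seq_len(nseed), function(k) {
      cfg <- sim_config(
        n_dyads = 2, phase_durations = c(120, 10, 10),
        n_channels_per_hemisphere = 13, seed = 6800 + k,
        coupling = if (cpl > 0)
          coupling_spec(phase = "video1", band = "medium", roi = "TPJ_R",
                        coupling = cpl) else NULL)
      s <- simulate_session(cfg, 1)
      ch <- designated_channel(cfg, "TPJ_R")
      a <- preprocess_session(sub_raw(s$participants$A, ch))
      b <- preprocess_session(sub_raw(s$participants$B, ch))
      v1a <- extract_trial(a, s$events, "video1")$values[1, ]
      v1b <- extract_trial(b, s$events, "video1")$values[1, ]
      band_average(wtc(v1a, v1b, cfg$fs), "medium")$value
    }, numeric(1))
  })
  mu <- colMeans(res)
  se <- apply(res, 2, sd) / sqrt(nseed)
  # non-decreasing within Monte-Carlo tolerance
  for (i in seq_len(length(levels) - 1))
    expect_gt(mu[i + 1] - mu[i], -2 * sqrt(se[i]^2 + se[i + 1]^2))
  # strong coupling clearly separates from the null
  expect_gt(mu[4] - mu[1], 3 * sqrt(se[1]^2 + se[4]^2))
})

test_that("sessions round-trip through the plain-text serialisation", {
  cfg <- sim_config(n_dyads = 2, phase_durations = c(30, 10, 30),
                    n_channels_per_hemisphere = 13, seed = 69)
  s <- simulate_session(cfg, 1)
  dir <- withr::local_tempdir()
  write_session_tsv(s, dir)
  raw <- read_intensity_tsv(file.path(dir, "d01A_intensity.tsv"), fs = cfg$fs)
  expect_equal(dim(raw$values), dim(s$participants$A$values))
  expect_equal(raw$values, s$participants$A$values, tolerance = 1e-8,
               ignore_attr = TRUE)
  ev <- read_events_tsv(file.path(dir, "events.tsv"))
  expect_equal(as.data.frame(ev), as.data.frame(s$events), tolerance = 1e-12)
  g <- read_geometry_tsv(file.path(dir, "d01A_geometry.tsv"))
  expect_equal(g$mni_x, s$geometry$A$mni_x, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$video_order, s$truth$video_order)
})
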