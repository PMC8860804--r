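test_that("bandpass is zero-phase in the passband and rejects DC", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * 8.5 * t)
  y <- bandpass(x, c(7, 10), fs)$samples[, 1]
  interior <- seq(2 * fs, length(x) - 2 * fs)
  # peak cross-correlation at lag 0 (no net phase shift)
  lags <- -10:10
  cc <- vapply(lags, function(L)
    stats::cor(x[interior], y[interior + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  gain <- sqrt(mean(y[interior]^2) / mean(x[interior]^2))
  expect_gt(gain, 0.9)
  expect_lte(gain, 1.0)
  # constant input is annihilated (away from the edge transients)
  dc <- bandpass(rep(3, 5000), c(7, 10), fs)$samples[, 1]
  expect_lt(max(abs(dc[2000:3000])), 1e-8)
  expect_error(bandpass(x, c(7, 130), fs), "Nyquist")
})

test_that("out-of-band attenuation matches the squared Butterworth response", {
  fs <- 250
  t <- seq(0, 16, by = 1 / fs)
  bf <- signal::butter(4, c(7, 10) / (fs / 2), type = "pass")
  interior <- seq(4 * fs, 12 * fs)
  # near the stopband edge the steady-state response dominates: the
  # measured RMS must match the analytic squared-magnitude prediction
  y13 <- bandpass(sin(2 * pi * 13 * t), c(7, 10), fs)$samples[, 1]
  bound13 <- oracle_filtfilt_gain(bf, 13, fs) / sqrt(2)  # RMS of unit sine
  expect_lt(sqrt(mean(y13[interior]^2)), bound13 * 1.01)
  expect_gt(sqrt(mean(y13[interior]^2)), bound13 * 0.9)
  # far outside the band (40 Hz) the tone is suppressed to numerical noise
  y40 <- bandpass(sin(2 * pi * 40 * t), c(7, 10), fs)$samples[, 1]
  expect_lt(sqrt(mean(y40[interior]^2)), 1e-6)
})

test_that("resampling preserves in-band content and suppresses aliases", {
  fs <- 5000
  x <- rnorm(fs * 10)
  y <- resample_signal(x, fs, 500)
  expect_equal(nrow(y), 5000)           # 10 s at 500 Hz
  expect_equal(attr(y, "fs"), 500)
  # a pure 8 Hz tone keeps its spectral peak at 8 Hz
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 8 * t)
  z <- resample_signal(tone, fs, 500)[, 1]
  spec <- Mod(stats::fft(z))[1:2500]
  expect_equal(which.max(spec[-1]), 8 * 10)  # bin index at 0.1 Hz resolution
  # a 300 Hz tone (would alias to 200 Hz) is attenuated by the anti-alias
  # filter at least as strongly as the order-8 Butterworth response allows
  alias <- resample_signal(sin(2 * pi * 300 * t), fs, 500)[, 1]
  expect_lt(sqrt(mean(alias[500:4500]^2)), 0.01)
  expect_error(resample_signal(x, 500, 5000), "downsampling")
})

test_that("common average reference removes the per-sample mean", {
  expect_equal(rereference_common_average(matrix(c(1, 3), 1)),
               matrix(c(-1, 1), 1))
  set.seed(3)
  x <- matrix(rnorm(400), 100, 4)
  y <- rereference_common_average(x)
  expect_equal(rowMeans(y), rep(0, 100))
  expect_equal(rereference_common_average(y), y)  # idempotent
  expect_error(rereference_common_average(matrix(1:5)), "2 channels")
})

test_that("analytic signal recovers amplitude, phase and envelopes", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  x <- cos(2 * pi * 8 * t)
  a <- analytic(band_signal(x, fs, c(7, 10)))
  expect_lt(max(abs(a$amplitude - 1)), 0.01)
  dphi <- wrap_phase(diff(a$phase[, 1]))
  expect_lt(max(abs(dphi - 2 * pi * 8 / fs)), 0.01)
  # amplitude-modulated carrier: envelope recovered in the interior
  env <- 1 + 0.5 * sin(2 * pi * 0.7 * t)
  am <- env * cos(2 * pi * 40 * t)
  b <- analytic(band_signal(am, fs, c(30, 60)))
  keep <- ceiling(fs / 30)
  expect_lt(max(abs(b$amplitude[, 1] -
                      env[(keep + 1):(length(t) - keep)])), 0.05)
  expect_error(analytic(band_signal(x[1:50], fs, c(7, 10))), "3 cycles")
})

test_that("analytic phase matches an independent FFT Hilbert oracle and scales", {
  set.seed(11)
  fs <- 250
  x <- bandpass(rnorm(2000), c(7, 10), fs)
  a <- analytic(x, trim_samples = 0)
  z <- oracle_analytic_fft(x$samples[, 1])
  expect_equal(a$phase[, 1], atan2(Im(z), Re(z)), tolerance = 1e-10)
  # positive scaling: amplitude scales, phase unchanged
  x3 <- band_signal(3 * x$samples, fs, c(7, 10))
  a3 <- analytic(x3, trim_samples = 0)
  expect_equal(a3$amplitude, 3 * a$amplitude)
  expect_equal(a3$phase, a$phase)
})

test_that("artifact excision and concatenation pool exactly the clean samples", {
  fs <- 100
  x <- matrix(rnorm(1000 * 2), 1000, 2)
  segs <- clean_segments(x, data.frame(start = 3, stop = 5), fs)
  expect_length(segs, 2)
  expect_equal(nrow(segs[[1]]) + nrow(segs[[2]]), 1000 - length(301:500))
  # fully artifactual trial contributes nothing
  expect_length(clean_segments(x, data.frame(start = 0, stop = 10), fs), 0)

  mk <- function(n) {
    s <- bandpass(matrix(rnorm(n * 2), n, 2), c(7, 10), 100)
    analytic(s, trim_samples = 0)
  }
  s1 <- mk(100)
  s2 <- mk(200)
  cc <- concatenate_clean(list(s1, s2))
  expect_equal(cc$n, 300)
  # dPLI on the concatenation equals the Heaviside oracle on pooled phases
  expect_equal(dpli(cc$phase[, 1], cc$phase[, 2]),
               oracle_dpli(c(s1$phase[, 1], s2$phase[, 1]),
                           c(s1$phase[, 2], s2$phase[, 2])))
  expect_equal(concatenate_clean(list(s1, s2), drop = c(FALSE, TRUE))$n, 100)
  expect_error(concatenate_clean(list(s1, s2), drop = c(TRUE, TRUE)),
               "no segments")
})

test_that("BrainVision triplet roundtrips through the reader", {
  dir <- withr::local_tempdir()
  x <- matrix(round(rnorm(500 * 3), 3), 500, 3)
  writeBin(as.vector(t(x)), file.path(dir, "rec.eeg"), size = 4,
           endian = "little")
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=rec.eeg", "MarkerFile=rec.vmrk",
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               "NumberOfChannels=3", "SamplingInterval=2000",
               "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "[Channel Infos]", "Ch1=Fz,,1,µV", "Ch2=Cz,,1,µV",
               "Ch3=Pz,,1,µV"),
             file.path(dir, "rec.vhdr"))
  writeLines(c("[Marker Infos]", "Mk1=New Segment,,1,1,0",
               "Mk2=Stimulus,S 1,101,1,0"),
             file.path(dir, "rec.vmrk"))
  rec <- read_brainvision(file.path(dir, "rec.vhdr"))
  expect_equal(rec$fs, 500)
  expect_equal(colnames(rec$samples), c("Fz", "Cz", "Pz"))
  expect_equal(rec$samples[, 2], x[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rec$markers$position, c(1L, 101L))
})
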