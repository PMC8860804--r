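test_that("phase-lagged pair generator controls the dPLI ground truth", {
  # full strength: every wrapped difference equals the planted positive lag,
  # so dPLI is exactly 1 even after re-extracting phases from the signals
  p <- gen_phase_lagged_pair(8.5, 0.3, 1, 4000, 250, seed = 1)
  a <- analytic(bandpass(cbind(p$x, p$y), c(7, 10), 250))
  expect_identical(dpli(a$phase[, 1], a$phase[, 2]), 1)
  # zero strength: chance level within binomial error (jitter is iid here)
  p0 <- gen_phase_lagged_pair(8.5, 0.3, 0, 5000, 250, seed = 2)
  expect_lt(abs(dpli(p0$phase_x, p0$phase_y) - 0.5), 3 * sqrt(0.25 / 5000))
  # intermediate strength: pipeline dPLI equals the loop oracle
  p8 <- gen_phase_lagged_pair(8.5, 0.3, 0.8, 5000, 250, seed = 1)
  expect_equal(dpli(p8$phase_x, p8$phase_y),
               oracle_dpli(p8$phase_x, p8$phase_y))
  expect_error(gen_phase_lagged_pair(200, 0.3, 1, 100, 250), "f_center")
  expect_error(gen_phase_lagged_pair(8, 4, 1, 100, 250), "lag")
  expect_error(gen_phase_lagged_pair(8, 0.3, 1.2, 100, 250), "strength")
})

test_that("PAC generator: no coupling at depth 0, monotone in depth, oracle match", {
  n <- 15000
  fs <- 500
  # depth 0: nMI measured from the generated signals is not extreme under a
  # 200-surrogate null built by circularly shifting the amplitude series
  q0 <- gen_pac_series(8.5, 55, 0, 0, n, fs, seed = 3)
  trim <- ceiling(fs / 7)
  ph <- analytic(bandpass(q0$x, c(7, 10), fs),
                 trim_samples = trim)$phase[, 1]
  am <- analytic(bandpass(q0$y, c(30, 80), fs),
                 trim_samples = trim)$amplitude[, 1]
  obs <- nmi(ph, am)
  set.seed(4)
  nn <- length(am)
  null <- vapply(1:200, function(i) {
    k <- sample(nn - 2, 1)
    nmi(ph, c(am[-(1:k)], am[1:k]))
  }, numeric(1))
  expect_lt(mean(null <= obs), 0.95)
  # monotone: deeper modulation, larger nMI at the same seed and length
  vals <- vapply(c(0, 0.3, 0.6, 1), function(d) {
    q <- gen_pac_series(8.5, 55, d, 0, n, fs, seed = 7)
    nmi(q$phase_theta, q$amp_gamma)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # direct formula oracle on the same arrays
  q6 <- gen_pac_series(8.5, 55, 0.6, 0, n, fs, seed = 7)
  expect_equal(nmi(q6$phase_theta, q6$amp_gamma),
               oracle_nmi(q6$phase_theta, q6$amp_gamma))
  expect_error(gen_pac_series(8.5, 55, 1.3, 0, n, fs), "depth")
  expect_error(gen_pac_series(55, 8.5, 0.5, 0, n, fs), "f_theta")
})

test_that("modulated gamma envelope follows the planted von-Mises bump", {
  q <- gen_pac_series(8.5, 55, 0.8, 1.1, 8000, 500, seed = 5)
  # ground-truth envelope attains its max near the preferred phase
  near <- abs(wrap_phase(q$phase_theta - 1.1)) < 0.2
  far <- abs(wrap_phase(q$phase_theta - 1.1 - pi)) < 0.2
  expect_gt(mean(q$amp_gamma[near]), mean(q$amp_gamma[far]))
  expect_equal(max(q$amp_gamma), 1, tolerance = 1e-6)
})

test_that("dataset generation is deterministic and validates its config", {
  cfg <- sim_config(n_subjects = 2, n_rois = 4, n_trials = 2,
                    trial_duration = 2, sampling_rate = 250,
                    artifact_fraction = 0.1, seed = 42)
  d1 <- gen_dataset(cfg)
  d2 <- gen_dataset(cfg)
  expect_identical(d1, d2)
  ann <- d1$subjects$sub01$memory$annotations
  expect_true(all(ann$stop <= 2 * 2 + 1e-9))
  expect_true(all(ann$start >= 0))
  expect_equal(nrow(d1$subjects$sub01$control$samples), 2 * 2 * 250)
  expect_error(sim_config(sampling_rate = 100), "twice the upper gamma")
  expect_error(sim_config(n_rois = 4,
                          planted_pac_links = data.frame(
                            phase_src = 1, amp_dst = 9, depth = 0.5,
                            pref_phase = 0)),
               "outside")
  expect_error(sim_config(n_rois = 4, mixing_matrix = matrix(1, 3, 3)),
               "mixing matrix")
})

test_that("planted links appear only in the memory condition", {
  cfg <- sim_config(n_subjects = 1, n_rois = 4, n_trials = 2,
                    trial_duration = 4, sampling_rate = 250,
                    planted_dpli_links = data.frame(src = 1, dst = 2,
                                                    lag = 0.5,
                                                    strength = 0.95),
                    noise_snr = 2, artifact_fraction = 0, seed = 7)
  ds <- gen_dataset(cfg)
  conn <- lapply(ds$subjects$sub01, function(e)
    subject_connectivity(e$samples, e$annotations, 250))
  expect_gt(conn$memory$dpli_theta[1, 2], 0.8)
  expect_lt(abs(conn$control$dpli_theta[1, 2] - 0.5), 0.25)
  expect_equal(ds$ground_truth,
               data.frame(src = 1, dst = 2, type = "dpli",
                          parameter = 0.95))
})

test_that("datasets roundtrip through the plain-text writer", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 1, n_rois = 3, n_trials = 1,
                    trial_duration = 2, sampling_rate = 250, seed = 9)
  ds <- gen_dataset(cfg)
  write_dataset(ds, dir)
  x <- read_num_matrix(file.path(dir, "sub01_memory.tsv"))
  expect_equal(unname(x), unname(ds$subjects$sub01$memory$samples),
               tolerance = 1e-12)
  ann <- read_annotations(file.path(dir, "sub01_memory_annotations.tsv"))
  expect_true(all(c("trial", "artifact") %in% ann$kind))
})

test_that("zero-lag mixing in the generator leaves dPLI at chance", {
  mix <- matrix(c(1, 0.5, 0.3, 1, 0.2, 0.7), 3, 2)
  cfg <- sim_config(n_subjects = 1, n_rois = 2, n_trials = 1,
                    trial_duration = 40, sampling_rate = 250,
                    mixing_matrix = mix, artifact_fraction = 0, seed = 13)
  ds <- gen_dataset(cfg)
  x <- ds$subjects$sub01$control$samples
  expect_equal(ncol(x), 3)
  a <- analytic(bandpass(x[, 1:2], c(7, 10), 250))
  spacing <- ceiling(3 * 250 / 3)
  idx <- seq(1, a$n, by = spacing)
  expect_lt(abs(dpli(a$phase[idx, 1], a$phase[idx, 2]) - 0.5),
            3 * sqrt(0.25 / length(idx)))
})
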