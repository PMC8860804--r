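#' Pink (1/f) noise
#'
#' Spectrally shaped Gaussian noise whose amplitude spectrum falls off as
#' 1/sqrt(f), matching the broadband background of EEG. Generated in the
#' frequency domain with random phases and normalized to unit standard
#' deviation. Uses the current RNG state (seed management belongs to the
#' caller).
#'
#' @param n Number of samples.
#' @return Numeric vector of length `n`, SD 1, mean ~0.
#' @export
pink_noise <- function(n) {
  stopifnot(n >= 4)
  nf <- (n - 1) %/% 2                      # strictly positive, non-Nyquist bins
  amp <- 1 / sqrt(seq_len(nf))
  ph <- stats::runif(nf, 0, 2 * pi)
  full <- complex(real = rep(0, n))
  full[2:(nf + 1)] <- complex(modulus = amp, argument = ph)
  if (n %% 2 == 0)                         # Nyquist bin must be real
    full[n / 2 + 1] <- complex(real = stats::rnorm(1) / sqrt(n / 2))
  full[n:(n - nf + 1)] <- Conj(full[2:(nf + 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Narrowband analytic carrier: white noise bandpassed around f_center, unit
# RMS, returned as a complex analytic series (positive-frequency support).
narrowband_carrier <- function(f_center, n, fs, bw = f_center / 4) {
  lo <- max(f_center - bw / 2, 0.01 * fs)
  hi <- min(f_center + bw / 2, 0.49 * fs)
  x <- stats::rnorm(n)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y <- y / stats::sd(y)
  hilbert_analytic(y)
}

#' Generate a phase-lagged pair of narrowband signals
#'
#' Ground-truth generator for the directed phase lag index. A narrowband
#' carrier (filtered noise around `f_center`) provides the leading signal
#' `x`; the partner `y` is produced by rotating the carrier's analytic
#' signal backwards by `lag` radians, so `x` leads `y`. On a random
#' fraction `1 - strength` of samples the rotation is replaced by uniform
#' phase noise, so the expected dPLI of `x` over `y` is
#' `(1 + strength) / 2`: 1 at full coupling, 0.5 at none.
#'
#' @param f_center Carrier center frequency (Hz), inside (0, fs/2).
#' @param lag Phase lag of `y` behind `x`, radians in (-pi, pi].
#' @param strength Fraction of samples carrying the planted lag, in
#'   \[0, 1\].
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param bw Carrier bandwidth (Hz).
#' @return List with real signals `x`, `y` and the ground-truth phase
#'   arrays `phase_x`, `phase_y` used to build them.
#' @export
gen_phase_lagged_pair <- function(f_center, lag, strength, n, fs,
                                  seed = NULL, bw = f_center / 4) {
  if (f_center <= 0 || f_center >= fs / 2)
    stop("f_center must lie strictly inside (0, fs/2)")
  if (lag <= -pi || lag > pi) stop("lag must be in (-pi, pi]")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  z <- narrowband_carrier(f_center, n, fs, bw)
  coupled <- stats::runif(n) < strength
  jitter <- ifelse(coupled, 0, stats::runif(n, -pi, pi))
  phase_x <- wrap_phase(Arg(z))
  phase_y <- wrap_phase(phase_x - lag + jitter)
  y <- Mod(z) * cos(phase_y)
  list(x = Re(z), y = y, phase_x = phase_x, phase_y = phase_y)
}

#' Generate a theta-phase modulated gamma series
#'
#' Ground-truth generator for phase-amplitude coupling. The gamma carrier's
#' amplitude envelope follows
#' `1 - depth + depth * g(phi_theta - pref_phase)` with
#' `g(x) = exp(kappa * (cos(x) - 1))`, a smooth von-Mises-style bump
#' peaking at 1 when the theta phase passes `pref_phase`. `depth = 0`
#' yields a constant envelope (no coupling); `depth = 1` silences gamma at
#' the anti-preferred phase.
#'
#' @param f_theta Low (phase-providing) frequency, Hz.
#' @param f_gamma High (amplitude-providing) frequency, Hz; must satisfy
#'   `f_theta < f_gamma < fs/2`.
#' @param depth Modulation depth in \[0, 1\].
#' @param pref_phase Theta phase (radians) at which gamma amplitude peaks.
#' @param n,fs Samples and sampling rate.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param kappa Concentration of the modulation bump.
#' @return List with `x` (theta signal, carries the phase), `y` (modulated
#'   gamma signal), and ground truth `phase_theta`, `amp_gamma`.
#' @export
gen_pac_series <- function(f_theta, f_gamma, depth, pref_phase = 0, n, fs,
                           seed = NULL, kappa = 2.5) {
  if (!(f_theta < f_gamma && f_gamma < fs / 2))
    stop("need f_theta < f_gamma < fs/2")
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  zt <- narrowband_carrier(f_theta, n, fs, bw = f_theta / 3)
  zg <- narrowband_carrier(f_gamma, n, fs, bw = f_gamma / 3)
  phase_theta <- wrap_phase(Arg(zt))
  g <- exp(kappa * (cos(phase_theta - pref_phase) - 1))
  env <- 1 - depth + depth * g
  y <- env * cos(Arg(zg))
  list(x = Re(zt), y = y, phase_theta = phase_theta, amp_gamma = env)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: two conditions
#' (a memory-like task with planted connectivity and a control task
#' without) recorded from `n_subjects` participants over `n_trials` trials
#' of `trial_duration` seconds at `sampling_rate` Hz, on `n_rois` regions.
#' Defaults mirror a 15-subject, 40-trial, 30-s, 500-Hz acquisition with
#' high-theta (7-10 Hz) and gamma (30-80 Hz) bands of interest.
#'
#' @param n_subjects,n_rois,n_trials Counts.
#' @param trial_duration Seconds per trial.
#' @param sampling_rate Hz; must exceed twice the upper gamma edge.
#' @param theta_band,gamma_band Length-2 Hz pairs.
#' @param planted_dpli_links Data frame `src`, `dst`, `lag` (radians),
#'   `strength` (0-1): directed phase-lag links planted in the memory
#'   condition (theta band).
#' @param planted_pac_links Data frame `phase_src`, `amp_dst`, `depth`
#'   (0-1), `pref_phase` (radians): theta-phase to gamma-amplitude links.
#' @param noise_snr RMS ratio of each planted component to the pink-noise
#'   background.
#' @param mixing_matrix `"identity"` (ROI-level data returned as-is) or an
#'   `n_channels x n_rois` numeric matrix applied instantaneously
#'   (zero-lag leakage).
#' @param artifact_fraction Fraction of each trial marked artifactual
#'   (one contiguous segment per trial at a random position), in \[0, 1).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 15, n_rois = 84, n_trials = 40,
                       trial_duration = 30, sampling_rate = 500,
                       theta_band = c(7, 10), gamma_band = c(30, 80),
                       planted_dpli_links = NULL, planted_pac_links = NULL,
                       noise_snr = 1, mixing_matrix = "identity",
                       artifact_fraction = 0.05, seed = 1) {
  stopifnot(n_subjects >= 1, n_rois >= 2, n_trials >= 1,
            trial_duration > 0, length(theta_band) == 2,
            length(gamma_band) == 2, noise_snr > 0,
            artifact_fraction >= 0, artifact_fraction < 1)
  if (sampling_rate <= 2 * gamma_band[2])
    stop("sampling_rate must exceed twice the upper gamma edge")
  chk_links <- function(df, cols, roi_cols) {
    if (is.null(df)) return(df)
    df <- as.data.frame(df)
    stopifnot(all(cols %in% names(df)))
    for (rc in roi_cols)
      if (any(df[[rc]] < 1 | df[[rc]] > n_rois))
        stop("planted link references ROI outside 1..", n_rois)
    df
  }
  planted_dpli_links <- chk_links(planted_dpli_links,
                                  c("src", "dst", "lag", "strength"),
                                  c("src", "dst"))
  if (!is.null(planted_dpli_links) &&
      any(planted_dpli_links$strength < 0 | planted_dpli_links$strength > 1))
    stop("coupling strength must be in [0, 1]")
  planted_pac_links <- chk_links(planted_pac_links,
                                 c("phase_src", "amp_dst", "depth",
                                   "pref_phase"),
                                 c("phase_src", "amp_dst"))
  if (!is.null(planted_pac_links) &&
      any(planted_pac_links$depth < 0 | planted_pac_links$depth > 1))
    stop("modulation depth must be in [0, 1]")
  if (!identical(mixing_matrix, "identity")) {
    mixing_matrix <- as.matrix(mixing_matrix)
    if (ncol(mixing_matrix) != n_rois)
      stop("mixing matrix must have n_rois = ", n_rois, " columns")
  }
  structure(list(n_subjects = n_subjects, n_rois = n_rois,
                 n_trials = n_trials, trial_duration = trial_duration,
                 sampling_rate = sampling_rate, theta_band = theta_band,
                 gamma_band = gamma_band,
                 planted_dpli_links = planted_dpli_links,
                 planted_pac_links = planted_pac_links,
                 noise_snr = noise_snr, mixing_matrix = mixing_matrix,
                 artifact_fraction = artifact_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic multi-subject dataset
#'
#' Produces per-subject, per-condition multichannel recordings with pink
#' 1/f background noise. The memory condition additionally embeds the
#' planted directed phase-lag pairs (theta band) and theta-to-gamma
#' phase-amplitude coupling links of the configuration; the control
#' condition carries background only, so any structure recovered there is
#' a false positive. Optional zero-lag mixing emulates source leakage.
#' One contiguous artifact segment per trial is annotated (and filled with
#' large-amplitude noise) when `artifact_fraction > 0`.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_dataset`: list with `config`,
#'   `roi_table`, `ground_truth` (data frame src, dst, type, parameter),
#'   and `subjects` — per subject a list of conditions (`memory`,
#'   `control`), each holding `samples` (time x channel matrix, trials
#'   concatenated) and `annotations` (trial and artifact intervals in
#'   seconds).
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  nt <- round(config$trial_duration * fs)
  f_theta <- mean(config$theta_band)
  f_gamma <- mean(config$gamma_band)
  roi_table <- utils::head(read_roi_table(), config$n_rois)
  if (nrow(roi_table) < config$n_rois)
    stop("bundled ROI table supports at most ", nrow(roi_table), " ROIs")
  gt <- data.frame(src = integer(0), dst = integer(0),
                   type = character(0), parameter = numeric(0))
  if (!is.null(config$planted_dpli_links))
    gt <- rbind(gt, data.frame(src = config$planted_dpli_links$src,
                               dst = config$planted_dpli_links$dst,
                               type = "dpli",
                               parameter = config$planted_dpli_links$strength))
  if (!is.null(config$planted_pac_links))
    gt <- rbind(gt, data.frame(src = config$planted_pac_links$phase_src,
                               dst = config$planted_pac_links$amp_dst,
                               type = "pac",
                               parameter = config$planted_pac_links$depth))

  gen_trial <- function(planted) {
    x <- vapply(seq_len(config$n_rois), function(r) pink_noise(nt),
                numeric(nt))
    if (planted) {
      snr <- config$noise_snr
      dl <- config$planted_dpli_links
      if (!is.null(dl)) for (k in seq_len(nrow(dl))) {
        p <- gen_phase_lagged_pair(f_theta, dl$lag[k], dl$strength[k],
                                   nt, fs)
        x[, dl$src[k]] <- x[, dl$src[k]] + snr * p$x / stats::sd(p$x)
        x[, dl$dst[k]] <- x[, dl$dst[k]] + snr * p$y / stats::sd(p$y)
      }
      pl <- config$planted_pac_links
      if (!is.null(pl)) for (k in seq_len(nrow(pl))) {
        p <- gen_pac_series(f_theta, f_gamma, pl$depth[k],
                            pl$pref_phase[k], nt, fs)
        x[, pl$phase_src[k]] <- x[, pl$phase_src[k]] +
          snr * p$x / stats::sd(p$x)
        x[, pl$amp_dst[k]] <- x[, pl$amp_dst[k]] + snr * p$y / stats::sd(p$y)
      }
    }
    x
  }

  gen_condition <- function(label, planted) {
    mats <- vector("list", config$n_trials)
    ann <- NULL
    for (tr in seq_len(config$n_trials)) {
      m <- gen_trial(planted)
      t0 <- (tr - 1) * config$trial_duration
      ann <- rbind(ann, data.frame(kind = "trial", start = t0,
                                   stop = t0 + config$trial_duration,
                                   label = label))
      if (config$artifact_fraction > 0) {
        len <- config$artifact_fraction * config$trial_duration
        a0 <- stats::runif(1, 0, config$trial_duration - len)
        i0 <- max(1L, floor(a0 * fs) + 1L)
        i1 <- min(nt, ceiling((a0 + len) * fs))
        m[i0:i1, ] <- m[i0:i1, ] + 20 * stats::rnorm(length(i0:i1))
        ann <- rbind(ann, data.frame(kind = "artifact", start = t0 + a0,
                                     stop = t0 + a0 + len,
                                     label = "simulated"))
      }
      mats[[tr]] <- m
    }
    samples <- do.call(rbind, mats)
    if (!identical(config$mixing_matrix, "identity")) {
      samples <- samples %*% t(config$mixing_matrix)
      colnames(samples) <- paste0("CH", seq_len(ncol(samples)))
    } else {
      colnames(samples) <- roi_table$abbrev
    }
    list(samples = samples, annotations = ann)
  }

  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    list(memory = gen_condition("memory", planted = TRUE),
         control = gen_condition("control", planted = FALSE))
  })
  names(subjects) <- sprintf("sub%02d", seq_len(config$n_subjects))
  structure(list(config = config, roi_table = roi_table,
                 ground_truth = gt, subjects = subjects),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d subjects x 2 conditions, ",
                     "%d ROIs, %d trials x %g s @ %g Hz, %d planted links\n"),
              x$config$n_subjects, x$config$n_rois, x$config$n_trials,
              x$config$trial_duration, x$config$sampling_rate,
              nrow(x$ground_truth)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' One delimited matrix per subject and condition
#' (`<subject>_<condition>.tsv`, rows = samples, columns = channels/ROIs),
#' one annotation file each (`..._annotations.tsv`), a ground-truth edge
#' list `ground_truth.tsv` (src, dst, type, parameter) and the ROI table.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(ds$subjects)) {
    for (cond in names(ds$subjects[[s]])) {
      e <- ds$subjects[[s]][[cond]]
      write_num_matrix(e$samples,
                       file.path(dir, sprintf("%s_%s.tsv", s, cond)))
      write_annotations(e$annotations,
                        file.path(dir,
                                  sprintf("%s_%s_annotations.tsv", s, cond)))
    }
  }
  utils::write.table(ds$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$roi_table, file.path(dir, "roi_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
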