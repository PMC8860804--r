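#' Band-limited multichannel signal
#'
#' Lightweight container for a band-filtered time series: a samples-by-channel
#' numeric matrix plus its sampling rate and passband. Produced by
#' [bandpass()]; consumed by [analytic()].
#'
#' @param samples Numeric matrix, rows = samples, columns = channels (a
#'   vector is treated as one channel).
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric, passband edges in Hz.
#' @param labels Optional channel labels.
#' @return An object of class `band_signal`.
#' @export
band_signal <- function(samples, fs, band, labels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), fs > 0, length(band) == 2)
  if (!all(is.finite(samples))) stop("non-finite sample values")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high < fs/2")
  if (is.null(labels)) labels <- colnames(samples)
  structure(list(samples = samples, fs = fs, band = as.numeric(band),
                 labels = labels),
            class = "band_signal")
}

#' @export
print.band_signal <- function(x, ...) {
  cat(sprintf("<band_signal> %d samples x %d channels, fs = %g Hz, band = %g-%g Hz\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$band[1], x$band[2]))
  invisible(x)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth bandpass of the given order and applies it
#' forward-backward (`signal::filtfilt`), so the net phase shift is zero and
#' the effective magnitude response is the squared Butterworth response.
#' The default order 4 applied both ways gives an effective order-8
#' attenuation profile.
#'
#' @param x Numeric vector or samples-by-channel matrix, or a `band_signal`.
#' @param band Length-2 numeric, passband edges in Hz (strictly inside
#'   Nyquist).
#' @param fs Sampling rate in Hz (taken from `x` if it is a `band_signal`).
#' @param order Design order of the Butterworth prototype.
#' @return A [band_signal()] carrying the filtered samples.
#' @export
#' @examples
#' fs <- 250
#' t <- seq(0, 2, by = 1 / fs)
#' bs <- bandpass(sin(2 * pi * 8.5 * t), c(7, 10), fs)
bandpass <- function(x, band, fs = NULL, order = 4) {
  if (inherits(x, "band_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- as.matrix(x)
  stopifnot(!is.null(fs), length(band) == 2, order >= 1)
  if (band[1] <= 0 || band[1] >= band[2])
    stop("band edges must satisfy 0 < low < high")
  if (band[2] >= fs / 2) stop("upper band edge must be below Nyquist (fs/2)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  y <- matrix(y, nrow = nrow(x), dimnames = dimnames(x))
  band_signal(y, fs, band)
}

#' Anti-alias filtered downsampling
#'
#' Lowpass filters below the new Nyquist frequency (zero-phase Butterworth)
#' and decimates. Integer decimation factors keep every k-th sample;
#' rational factors fall back to `signal::resample`. Upsampling is rejected.
#'
#' @param x Numeric vector or samples-by-channel matrix.
#' @param fs Current sampling rate in Hz.
#' @param target_fs Desired sampling rate in Hz, strictly below `fs`.
#' @param order Order of the anti-alias Butterworth lowpass.
#' @return Matrix of resampled data (vector input returns a one-column
#'   matrix) with attribute `fs` set to `target_fs`.
#' @export
resample_signal <- function(x, fs, target_fs, order = 8) {
  x <- as.matrix(x)
  if (target_fs >= fs) stop("target_fs must be below fs (downsampling only)")
  k <- fs / target_fs
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    # cutoff at 80% of the new Nyquist leaves a guard band for the roll-off
    lp <- signal::butter(order, 0.8 * target_fs / fs, type = "low")
    y <- apply(x, 2, function(col) signal::filtfilt(lp, col))
    y <- matrix(y, nrow = nrow(x))
    out <- y[seq(1, nrow(y), by = k), , drop = FALSE]
  } else {
    fr <- as.integer(c(round(target_fs * 1000), round(fs * 1000)))
    g <- gcd_int(fr[1], fr[2])
    out <- apply(x, 2, function(col)
      signal::resample(col, fr[1] / g, fr[2] / g))
    out <- matrix(out, ncol = ncol(x))
  }
  colnames(out) <- colnames(x)
  attr(out, "fs") <- target_fs
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each sample (row) has zero mean. Idempotent.
#'
#' @param x Samples-by-channel numeric matrix with at least two channels.
#' @return Re-referenced matrix of the same shape.
#' @export
rereference_common_average <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("common average reference needs >= 2 channels")
  x - rowMeans(x)
}

# FFT-based analytic signal of a real vector: positive frequencies doubled,
# negative frequencies zeroed (Marple's construction).
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Analytic signal: instantaneous phase and amplitude
#'
#' Computes the analytic signal of each channel of a band-limited input via
#' the Hilbert transform (FFT construction) and returns instantaneous phase
#' (wrapped to (-pi, pi]) and amplitude. Because both the zero-phase filter
#' and the Hilbert transform are unreliable near segment edges, one cycle of
#' the band's lower edge is trimmed from each end before returning; segments
#' shorter than three such cycles are rejected.
#'
#' @param x A [band_signal()].
#' @param trim_cycles Cycles of the band's lower edge to trim from each end.
#' @param trim_samples Optional explicit per-end trim in samples, overriding
#'   `trim_cycles` — useful to align two bands (e.g. theta phase and gamma
#'   amplitude for cross-frequency coupling) onto identical sample sets.
#' @return An object of class `analytic_series`: list with `phase` and
#'   `amplitude` (samples x channels), `fs`, `band` and `n` (retained
#'   samples).
#' @export
analytic <- function(x, trim_cycles = 1, trim_samples = NULL) {
  stopifnot(inherits(x, "band_signal"))
  n <- nrow(x$samples)
  cyc <- ceiling(x$fs / x$band[1])
  if (n < 3 * cyc)
    stop("segment shorter than 3 cycles of the band's lower edge (",
         3 * cyc, " samples at ", x$band[1], " Hz)")
  trim <- if (is.null(trim_samples)) trim_cycles * cyc else trim_samples
  if (n <= 2 * trim) stop("segment too short for the requested edge trim")
  z <- apply(x$samples, 2, hilbert_analytic)
  z <- matrix(z, nrow = n, dimnames = dimnames(x$samples))
  keep <- seq(trim + 1, n - trim)
  structure(list(phase = wrap_phase(Arg(z[keep, , drop = FALSE])),
                 amplitude = Mod(z[keep, , drop = FALSE]),
                 fs = x$fs, band = x$band, n = length(keep)),
            class = "analytic_series")
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf("<analytic_series> %d samples x %d channels, band = %g-%g Hz\n",
              x$n, ncol(x$phase), x$band[1], x$band[2]))
  invisible(x)
}

#' Cut a trial into artifact-free segments
#'
#' Removes artifact intervals from a continuous trial and returns the clean
#' stretches as separate matrices, so the analytic transform can be applied
#' per continuous segment (splicing raw signals first would create phase
#' discontinuities).
#'
#' @param x Samples-by-channel matrix for one trial.
#' @param artifacts Data frame with `start` / `stop` columns in seconds,
#'   relative to trial onset; `NULL` or zero rows means the whole trial is
#'   clean. Intervals may overlap and are clipped to the trial.
#' @param fs Sampling rate in Hz.
#' @param min_samples Segments shorter than this are dropped.
#' @return List of samples-by-channel matrices (possibly empty).
#' @export
clean_segments <- function(x, artifacts, fs, min_samples = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  bad <- rep(FALSE, n)
  if (!is.null(artifacts) && nrow(artifacts)) {
    for (i in seq_len(nrow(artifacts))) {
      a <- max(1L, floor(artifacts$start[i] * fs) + 1L)
      b <- min(n, ceiling(artifacts$stop[i] * fs))
      if (b >= a) bad[a:b] <- TRUE
    }
  }
  r <- rle(!bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_samples)
      out[[length(out) + 1L]] <- x[starts[i]:ends[i], , drop = FALSE]
  }
  out
}

#' Concatenate clean analytic segments
#'
#' Appends the phase and amplitude arrays of the retained segments, pooling
#' all artifact-free samples of a recording into one `analytic_series` per
#' band, as required before connectivity estimation. A fully artifactual
#' trial simply contributes no segments.
#'
#' @param series List of `analytic_series` objects sharing band and fs.
#' @param drop Optional logical vector marking elements to exclude (e.g.
#'   trials annotated as artifactual in their entirety).
#' @return A single `analytic_series` with `n` equal to the total number of
#'   retained samples.
#' @export
concatenate_clean <- function(series, drop = NULL) {
  if (!is.null(drop)) series <- series[!drop]
  if (!length(series)) stop("no segments retained")
  stopifnot(all(vapply(series, inherits, logical(1), "analytic_series")))
  b0 <- series[[1]]$band
  fs0 <- series[[1]]$fs
  for (s in series)
    if (!isTRUE(all.equal(s$band, b0)) || s$fs != fs0)
      stop("all segments must share band and sampling rate")
  ph <- do.call(rbind, lapply(series, `[[`, "phase"))
  am <- do.call(rbind, lapply(series, `[[`, "amplitude"))
  if (!nrow(ph)) stop("no samples retained")
  structure(list(phase = ph, amplitude = am, fs = fs0, band = b0,
                 n = nrow(ph)),
            class = "analytic_series")
}

#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision triplet: parses the `.vhdr` header,
#' loads the binary `.eeg` data (IEEE_FLOAT_32 or INT_16, multiplexed or
#' vectorized orientation, per-channel resolution scaling) and the `.vmrk`
#' markers.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return List with `samples` (samples x channels, labelled), `fs` (Hz) and
#'   `markers` (data frame: type, description, position, points, channel).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  getval <- function(key) {
    m <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^", key, "="), "", m[1])
  }
  datafile <- file.path(dirname(vhdr), getval("DataFile"))
  mrkfile <- getval("MarkerFile")
  nchan <- as.integer(getval("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getval("SamplingInterval"))
  fmt <- getval("BinaryFormat") %||% "IEEE_FLOAT_32"
  orient <- getval("DataOrientation") %||% "MULTIPLEXED"
  chlines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  chinfo <- strsplit(sub("^Ch[0-9]+=", "", chlines), ",")
  labels <- vapply(chinfo, `[`, character(1), 1)
  res <- vapply(chinfo, function(v) {
    r <- suppressWarnings(as.numeric(v[3]))
    if (is.na(r) || r == 0) 1 else r
  }, numeric(1))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(datafile, "numeric", n = file.size(datafile) / 4,
                   size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(datafile, "integer", n = file.size(datafile) / 2,
                   size = 2, signed = TRUE, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  nsamp <- length(raw) %/% nchan
  if (identical(orient, "VECTORIZED")) {
    x <- matrix(raw[seq_len(nsamp * nchan)], nrow = nsamp, ncol = nchan)
  } else {
    x <- t(matrix(raw[seq_len(nsamp * nchan)], nrow = nchan, ncol = nsamp))
  }
  x <- sweep(x, 2, res, `*`)
  colnames(x) <- labels
  markers <- data.frame(type = character(0), description = character(0),
                        position = integer(0), points = integer(0),
                        channel = integer(0))
  if (!is.null(mrkfile) && file.exists(file.path(dirname(vhdr), mrkfile))) {
    ml <- readLines(file.path(dirname(vhdr), mrkfile), warn = FALSE)
    mk <- grep("^Mk[0-9]+=", ml, value = TRUE)
    if (length(mk)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
      markers <- data.frame(
        type = vapply(parts, `[`, character(1), 1),
        description = vapply(parts, `[`, character(1), 2),
        position = as.integer(vapply(parts, `[`, character(1), 3)),
        points = as.integer(vapply(parts, `[`, character(1), 4)),
        channel = as.integer(vapply(parts, `[`, character(1), 5)))
    }
  }
  list(samples = x, fs = fs, markers = markers)
}

#' Read an annotation file
#'
#' Plain-text annotations: tab-separated with columns `kind` (`trial` or
#' `artifact`), `start`, `stop` (seconds from recording onset) and `label`
#' (condition name for trials; free text for artifacts).
#'
#' @param path Path to the annotation file.
#' @return Data frame with those four columns.
#' @export
read_annotations <- function(path) {
  a <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "start", "stop", "label") %in% names(a)))
  if (any(a$stop < a$start)) stop("annotation with stop < start")
  a
}

write_annotations <- function(a, path) {
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
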