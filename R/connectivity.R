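#' Directed phase lag index
#'
#' Fraction of samples at which the first signal's instantaneous phase leads
#' the second's:
#' `dPLI_xy = (1/N) * sum_t H(wrap(phi_x(t) - phi_y(t)))`,
#' with `H` the Heaviside step function. Phase differences are wrapped to
#' (-pi, pi] before the sign test; `H(0) = 0.5` so that the complement
#' identity `dPLI_xy + dPLI_yx = 1` holds exactly even when exact-zero
#' differences occur in finite precision. Values are in \[0, 1\]; `x` leads
#' `y` when the value exceeds 0.5, and a value of 0.5 indicates no
#' consistent lead, which is the null value by construction, not a tuned
#' threshold.
#'
#' @param phase_x,phase_y Equal-length numeric vectors of instantaneous
#'   phase in radians.
#' @return Scalar dPLI in \[0, 1\].
#' @export
#' @examples
#' dpli(c(0.1, 0.2, 0.3), c(0, 0, 0))  # x always leads: 1
#' dpli(rep(0, 4), c(0.1, -0.1, 0.1, -0.1))  # balanced: 0.5
dpli <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y))
    stop("phase arrays must have equal length")
  if (!length(phase_x)) stop("empty phase arrays")
  d <- wrap_phase(phase_x - phase_y)
  mean((d > 0) + 0.5 * (d == 0))
}

#' Normalized modulation index
#'
#' Phase-amplitude coupling between a low-frequency phase and a
#' high-frequency amplitude envelope:
#' `nMI = (1/sqrt(N)) * |sum_t a(t) exp(i phi(t))| / sqrt(sum_t a(t)^2)`.
#' Bounded in \[0, 1\] by the Cauchy-Schwarz inequality and invariant to
#' positive rescaling of the amplitude. Directionality is phase -> amplitude
#' and carries no causal meaning.
#'
#' @param phase_lo Numeric vector of low-frequency instantaneous phase
#'   (radians).
#' @param amp_hi Nonnegative numeric vector of high-frequency amplitude,
#'   same length, not all zero.
#' @return Scalar nMI in \[0, 1\].
#' @export
#' @examples
#' nmi(rep(1.2, 100), rep(3, 100))  # perfectly concentrated: 1
#' nmi(seq(0, 2 * pi, length.out = 101)[-101], rep(1, 100))  # uniform: ~0
nmi <- function(phase_lo, amp_hi) {
  if (length(phase_lo) != length(amp_hi))
    stop("phase and amplitude arrays must have equal length")
  n <- length(amp_hi)
  if (!n) stop("empty arrays")
  if (any(amp_hi < 0)) stop("amplitude must be nonnegative")
  den <- sqrt(sum(amp_hi^2))
  if (den == 0) stop("all-zero amplitude")
  Mod(sum(amp_hi * exp(1i * phase_lo))) / (sqrt(n) * den)
}

#' dPLI matrix over all region pairs
#'
#' Computes the directed phase lag index for every ordered pair of columns
#' of a phase matrix. The diagonal is undefined (a region does not lead
#' itself) and returned as `NA`; off-diagonal entries satisfy
#' `M[i, j] + M[j, i] = 1`.
#'
#' @param phase Samples-by-region matrix of instantaneous phase, or an
#'   `analytic_series`.
#' @return n_region x n_region matrix with attribute `n_samples`.
#' @export
dpli_matrix <- function(phase) {
  if (inherits(phase, "analytic_series")) phase <- phase$phase
  phase <- as.matrix(phase)
  r <- ncol(phase)
  n <- nrow(phase)
  if (!n) stop("empty phase matrix")
  m <- matrix(NA_real_, r, r, dimnames = list(colnames(phase),
                                              colnames(phase)))
  for (i in seq_len(r)) {
    if (i < r) {
      d <- wrap_phase(phase[, i] - phase[, (i + 1):r, drop = FALSE])
      v <- colMeans((d > 0) + 0.5 * (d == 0))
      m[i, (i + 1):r] <- v
      m[(i + 1):r, i] <- 1 - v
    }
  }
  structure(m, n_samples = n, measure = "dpli")
}

#' nMI matrix over all ordered region pairs
#'
#' `M[i, j]` couples the low-frequency phase of region `i` (rows,
#' phase-providing) to the high-frequency amplitude of region `j` (columns,
#' amplitude-providing). The diagonal is local phase-amplitude coupling
#' within a region and is computed, not masked.
#'
#' @param phase_lo Samples-by-region phase matrix (or `analytic_series`) in
#'   the low band.
#' @param amp_hi Samples-by-region amplitude matrix (or `analytic_series`)
#'   in the high band; same sample count and region order.
#' @return n_region x n_region matrix with attribute `n_samples`.
#' @export
nmi_matrix <- function(phase_lo, amp_hi) {
  if (inherits(phase_lo, "analytic_series")) phase_lo <- phase_lo$phase
  if (inherits(amp_hi, "analytic_series")) amp_hi <- amp_hi$amplitude
  phase_lo <- as.matrix(phase_lo)
  amp_hi <- as.matrix(amp_hi)
  if (nrow(phase_lo) != nrow(amp_hi))
    stop("phase and amplitude matrices must have equal sample counts")
  n <- nrow(amp_hi)
  if (!n) stop("empty input")
  den <- sqrt(colSums(amp_hi^2))
  if (any(den == 0)) stop("all-zero amplitude in region(s): ",
                          paste(which(den == 0), collapse = ", "))
  num <- Mod(t(exp(1i * phase_lo)) %*% amp_hi)   # rows: phase, cols: amp
  m <- num / (sqrt(n) * rep(den, each = ncol(phase_lo)))
  dimnames(m) <- list(colnames(phase_lo), colnames(amp_hi))
  structure(m, n_samples = n, measure = "nmi")
}

#' Per-subject connectivity matrices for one condition
#'
#' Given the pooled artifact-free analytic series of every ROI in the high
#' theta and gamma bands, computes the three matrices used downstream: dPLI
#' in theta, dPLI in gamma, and the theta-phase to gamma-amplitude nMI
#' (rows = phase ROI, columns = amplitude ROI, diagonal = local coupling).
#'
#' @param theta `analytic_series` of all ROIs in the low (theta) band.
#' @param gamma `analytic_series` of all ROIs in the high (gamma) band,
#'   same ROI order and sample count.
#' @return Named list `dpli_theta`, `dpli_gamma`, `nmi`, each an
#'   n_roi x n_roi matrix with `n_samples` attribute.
#' @export
connectivity_matrices <- function(theta, gamma) {
  stopifnot(inherits(theta, "analytic_series"),
            inherits(gamma, "analytic_series"))
  if (ncol(theta$phase) != ncol(gamma$phase))
    stop("theta and gamma series must cover the same ROIs")
  if (theta$n != gamma$n)
    stop("theta and gamma series must have equal sample counts")
  list(dpli_theta = dpli_matrix(theta),
       dpli_gamma = dpli_matrix(gamma),
       nmi = nmi_matrix(theta, gamma))
}

#' Logit transform of a connectivity matrix
#'
#' Maps values from (0, 1) to the real line before group-level t-tests, so
#' the critical value for "no consistent lead" becomes 0 instead of 0.5 and
#' the dPLI matrix becomes anti-symmetric (`logit(p) = -logit(1 - p)`).
#' Entries saturated at exactly 0 or 1 — possible for a finite-sample
#' proportion — are clipped to `1/(2N)` using the matrix's `n_samples`
#' attribute, keeping the transform finite without reordering values.
#'
#' @param m Connectivity matrix as returned by [dpli_matrix()] or
#'   [nmi_matrix()] (any numeric matrix with values in \[0, 1\] works; the
#'   `n_samples` attribute, if present, sets the clipping bound).
#' @return Matrix of the same shape on the logit scale, attribute
#'   `scale = "logit"`.
#' @export
logit_connectivity <- function(m) {
  n <- attr(m, "n_samples")
  eps <- if (!is.null(n)) 1 / (2 * n) else NULL
  out <- m
  ok <- !is.na(m)
  out[ok] <- logit(m[ok], eps = eps)
  attr(out, "scale") <- "logit"
  out
}
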