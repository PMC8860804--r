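#' Read a linear inverse operator
#'
#' The operator maps `n_channels` sensor signals to `n_sources` point
#' sources with three dipole components each. It is consumed as data, never
#' computed here: head modelling and the inverse solution belong to the
#' source-imaging software that produced the matrix.
#'
#' @param matrix_path Delimited numeric matrix, `3 * n_sources` rows (three
#'   consecutive rows per source: x, y, z dipole components) by
#'   `n_channels` columns, no header.
#' @param coords_path TSV of source MNI coordinates in mm, columns
#'   `x`, `y`, `z`, one row per source.
#' @return List of class `inverse_operator` with `K` (the matrix) and
#'   `coords`.
#' @export
read_inverse_operator <- function(matrix_path, coords_path) {
  K <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "\t"))
  dimnames(K) <- NULL
  coords <- utils::read.table(coords_path, header = TRUE, sep = "\t")
  stopifnot(all(c("x", "y", "z") %in% names(coords)))
  inverse_operator(K, as.matrix(coords[, c("x", "y", "z")]))
}

#' Construct an inverse operator object
#'
#' @param K Numeric matrix, `3 * n_sources` x `n_channels`.
#' @param coords Numeric matrix `n_sources` x 3 of MNI coordinates (mm).
#' @return Object of class `inverse_operator`.
#' @export
inverse_operator <- function(K, coords) {
  K <- as.matrix(K)
  coords <- as.matrix(coords)
  if (nrow(K) %% 3 != 0)
    stop("inverse matrix must have 3 rows per source")
  if (nrow(K) / 3 != nrow(coords))
    stop("coordinate count (", nrow(coords), ") does not match source count (",
         nrow(K) / 3, ")")
  if (!all(is.finite(coords))) stop("non-finite source coordinates")
  structure(list(K = K, coords = coords, n_sources = nrow(K) / 3,
                 n_channels = ncol(K)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d channels -> %d sources x 3 components\n",
              x$n_channels, x$n_sources))
  invisible(x)
}

#' Project sensor signals into source space
#'
#' Applies the linear inverse operator independently to the real and
#' imaginary parts of the sensor analytic signals (linearity makes the two
#' projections equivalent to projecting the complex series). Each source
#' then carries a 3-component complex dipole time course; its power is the
#' squared norm of that vector, a single real nonnegative time course per
#' source.
#'
#' @param x Samples-by-channel matrix, real or complex (e.g. the analytic
#'   signal of band-filtered sensor data).
#' @param inv An [inverse_operator()] whose channel count matches `ncol(x)`.
#' @param keep_components Keep the full `n_samples x 3 n_sources` complex
#'   component matrix (memory-heavy for dense source grids)?
#' @return Object of class `source_activity`: list with `power`
#'   (samples x sources) and, optionally, `components`.
#' @export
apply_inverse <- function(x, inv, keep_components = FALSE) {
  stopifnot(inherits(inv, "inverse_operator"))
  x <- as.matrix(x)
  if (ncol(x) != inv$n_channels)
    stop("input has ", ncol(x), " channels but operator expects ",
         inv$n_channels)
  s <- x %*% t(inv$K)                       # samples x (3 * n_sources)
  sq <- Mod(s)^2
  idx <- seq(1, ncol(s), by = 3)
  power <- sq[, idx, drop = FALSE] + sq[, idx + 1, drop = FALSE] +
    sq[, idx + 2, drop = FALSE]
  out <- list(power = power, n_sources = inv$n_sources)
  if (keep_components) out$components <- s
  structure(out, class = "source_activity")
}

#' Standardize source power across time
#'
#' Z-scores each source's power time course (mean 0, SD 1 across the pooled
#' time axis), removing per-source activation biases so conditions can be
#' compared on a common scale. Pool all trials and conditions of a subject
#' before standardizing, then average within condition: z-scoring within a
#' single averaging window would force every mean to zero.
#'
#' Zero-variance sources cannot be standardized; they are set to `NA` and
#' listed in the `excluded` attribute so downstream statistics can drop
#' them.
#'
#' @param x Samples-by-source power matrix (pooled trials), or a
#'   `source_activity`.
#' @param index Optional factor of length `nrow(x)` (e.g. condition label
#'   per sample). If given, the return value is the per-level mean of the
#'   standardized power: one value per source per level.
#' @return Standardized matrix (or per-level means), with attribute
#'   `excluded` holding indices of zero-variance sources.
#' @export
standardize_power <- function(x, index = NULL) {
  if (inherits(x, "source_activity")) x <- x$power
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(sdv) | sdv == 0)
  sdv[bad] <- NA_real_
  z <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  if (length(bad))
    warning("zero-variance source(s) excluded: ",
            paste(bad, collapse = ", "))
  if (!is.null(index)) {
    index <- as.factor(index)
    stopifnot(length(index) == nrow(x))
    z <- do.call(rbind, lapply(split(seq_len(nrow(x)), index),
                               function(i) colMeans(z[i, , drop = FALSE])))
  }
  structure(z, excluded = bad)
}

#' Read an ROI atlas table
#'
#' TSV with columns `id`, `abbrev`, `x`, `y`, `z` (centroid, MNI mm) and
#' optionally `sources` (comma-separated member source indices). The
#' package ships `roi84_synthetic.tsv` in `inst/extdata`, a synthetic
#' 84-region stand-in table with atlas-style abbreviations and plausible
#' centroid coordinates, for simulations and examples.
#'
#' @param path Path to the table; defaults to the bundled synthetic table.
#' @return Data frame of class `roi_table`.
#' @export
read_roi_table <- function(path = system.file("extdata",
                                              "roi84_synthetic.tsv",
                                              package = "dirconn")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "abbrev", "x", "y", "z") %in% names(tab)))
  if (!all(is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("non-finite ROI centroids")
  class(tab) <- c("roi_table", "data.frame")
  tab
}

#' Assign point sources to ROIs by nearest centroid
#'
#' @param coords `n_sources` x 3 matrix of source MNI coordinates (mm).
#' @param roi_table An ROI table (see [read_roi_table()]).
#' @param max_dist Sources farther than this (mm) from every centroid stay
#'   unassigned (`NA`); `Inf` assigns everything.
#' @return Integer vector of ROI row indices, one per source (each source
#'   belongs to at most one ROI).
#' @export
assign_sources_to_rois <- function(coords, roi_table, max_dist = Inf) {
  coords <- as.matrix(coords)
  cent <- as.matrix(roi_table[, c("x", "y", "z")])
  out <- integer(nrow(coords))
  for (s in seq_len(nrow(coords))) {
    d2 <- colSums((t(cent) - coords[s, ])^2)
    j <- which.min(d2)
    out[s] <- if (sqrt(d2[j]) <= max_dist) j else NA_integer_
  }
  out
}

# First singular component of a time x k block with majority-rule sign
# correction: the component is flipped so that more than half of the member
# series load on it with positive weight; ties leave the sign untouched.
svd_first_component <- function(block) {
  sv <- svd(block, nu = 1, nv = 1)
  u <- sv$u[, 1] * sv$d[1]
  v <- sv$v[, 1]
  if (sum(v > 0) < sum(v < 0)) {
    u <- -u
    v <- -v
  }
  list(series = u, weights = v)
}

#' Reduce source clouds to one time course per ROI
#'
#' For each ROI, stacks the band-filtered time series of all member sources
#' — every dipole orientation as its own column — and takes the first
#' component of the singular value decomposition as the representative ROI
#' time course. The SVD sign ambiguity is resolved by a majority rule: the
#' component is oriented so that most member series correlate positively
#' with it (flipping the sign of a majority of members therefore flips the
#' output).
#'
#' @param x Samples-by-series real matrix of band-filtered source signals.
#'   With `components_per_source = 3` (dipole data), columns
#'   `3s-2 .. 3s` belong to source `s`; set it to 1 when each column is
#'   already one source.
#' @param membership Integer vector, ROI index per source (`NA` =
#'   unassigned). Every ROI referenced must have at least one member.
#' @param roi_ids ROI indices to extract, default all present in
#'   `membership`.
#' @param components_per_source Number of consecutive columns per source.
#' @return Samples-by-ROI matrix (class `roi_series` via attribute
#'   `measure`), columns named by ROI index, attribute `weights` holding
#'   the per-ROI member loadings.
#' @export
roi_reduce <- function(x, membership, roi_ids = NULL,
                       components_per_source = 3) {
  x <- as.matrix(x)
  n_src <- length(membership)
  if (ncol(x) != n_src * components_per_source)
    stop("expected ", n_src * components_per_source, " columns (",
         components_per_source, " per source), got ", ncol(x))
  if (is.null(roi_ids)) roi_ids <- sort(unique(membership[!is.na(membership)]))
  out <- matrix(NA_real_, nrow(x), length(roi_ids),
                dimnames = list(NULL, as.character(roi_ids)))
  wts <- vector("list", length(roi_ids))
  for (k in seq_along(roi_ids)) {
    src <- which(!is.na(membership) & membership == roi_ids[k])
    if (!length(src)) stop("ROI ", roi_ids[k], " has no member sources")
    cols <- as.vector(outer(seq_len(components_per_source),
                            (src - 1) * components_per_source, `+`))
    comp <- svd_first_component(x[, sort(cols), drop = FALSE])
    out[, k] <- comp$series
    wts[[k]] <- comp$weights
  }
  attr(out, "weights") <- wts
  out
}
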