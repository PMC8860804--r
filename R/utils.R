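#' Wrap phase angles to (-pi, pi]
#'
#' Maps arbitrary phase values onto the principal interval. The interval is
#' half-open at the lower end so that a phase difference of exactly pi counts
#' as a positive lead, keeping the complement identity of the directed phase
#' lag index exact.
#'
#' @param x Numeric vector, matrix or array of phase values in radians.
#' @return Object of the same shape with all values in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Logit transform with finite-sample clipping
#'
#' `log(p / (1 - p))`, mapping (0, 1) to the real line with `logit(0.5) = 0`.
#' Values exactly at 0 or 1 (which finite-sample dPLI can reach) are clipped
#' to `eps` / `1 - eps` before the transform so the result stays finite
#' without reordering values; clipped entries trigger a warning.
#'
#' @param p Numeric vector or matrix of probabilities in \[0, 1\].
#' @param eps Clipping bound for saturated entries. The natural choice for a
#'   proportion estimated from `N` samples is `1 / (2 * N)`.
#' @return Transformed object of the same shape.
#' @export
#' @examples
#' logit(0.5)  # exactly 0
#' logit(c(0.25, 0.75))  # anti-symmetric about 0.5
logit <- function(p, eps = NULL) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  sat <- !is.na(p) & (p == 0 | p == 1)
  if (any(sat)) {
    if (is.null(eps)) eps <- .Machine$double.eps
    warning(sum(sat), " entries at 0 or 1 clipped to [", format(eps), ", 1-",
            format(eps), "] before logit")
    p[!is.na(p) & p == 0] <- eps
    p[!is.na(p) & p == 1] <- 1 - eps
  }
  log(p / (1 - p))
}

# Union-find over integer node ids 1..n. Used in the permutation loops of the
# cluster and network statistics, where building a graph object per
# permutation would dominate run time.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Returns component labels (root id per node) for an undirected edge list.
# edges: 2-column integer matrix; n: number of nodes.
uf_components <- function(edges, n) {
  parent <- seq_len(n)
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- uf_find(parent, edges[k, 1L])
      rb <- uf_find(parent, edges[k, 2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

#' Weakly connected components of a directed edge set
#'
#' Partitions nodes into weakly connected components, i.e. components of the
#' undirected projection of the directed graph: `A -> B -> C` is one weak
#' component even though no directed path leads back to `A`. This is the
#' component notion used by the directed network-based statistic, where the
#' component-level measure is its number of links.
#'
#' @param edges Two-column matrix (or data frame) of directed links,
#'   `from` / `to`, as integer node indices in `1..n_nodes`.
#' @param n_nodes Total number of nodes (isolated nodes form singleton
#'   components).
#' @return A list with `membership` (integer component label per node,
#'   labels `1..n_components`), `n_components`, and `n_links` (number of
#'   edges, including self-loops, inside each component).
#' @export
#' @examples
#' weak_components(rbind(c(1, 2), c(2, 3)), n_nodes = 4)
weak_components <- function(edges, n_nodes) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2)
    stop("edges must have two columns (from, to)")
  if (length(edges)) {
    storage.mode(edges) <- "integer"
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints must reference nodes in 1..n_nodes")
  }
  lab <- uf_components(edges[, 1:2, drop = FALSE], n_nodes)
  lab <- match(lab, unique(lab))
  nc <- max(lab, 0L)
  nl <- integer(nc)
  if (length(edges)) {
    tab <- table(factor(lab[edges[, 1L]], levels = seq_len(nc)))
    nl <- as.integer(tab)
  }
  list(membership = lab, n_components = nc, n_links = nl)
}

#' Read / write a delimited numeric matrix
#'
#' Plain tab-separated numeric matrices are the package's interchange
#' format for time series (rows = samples, columns = channels/ROIs) and
#' connectivity matrices; the header row carries channel or ROI labels.
#'
#' @param path File path.
#' @param header Does the file carry a header row?
#' @return `read_num_matrix`: a numeric matrix.
#' @export
read_num_matrix <- function(path, header = TRUE) {
  x <- utils::read.table(path, header = header, sep = "\t",
                         check.names = FALSE)
  as.matrix(x)
}

#' @rdname read_num_matrix
#' @param x Numeric matrix to write.
#' @param col_names Column labels for the header row, or `NULL` for no
#'   header.
#' @export
write_num_matrix <- function(x, path, col_names = colnames(x)) {
  df <- as.data.frame(x)
  if (!is.null(col_names)) names(df) <- col_names
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(col_names))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
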