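# Paired/one-sample t statistics under sign-flip permutations share a trick:
# with q_j = sum_i d_ij^2 fixed under sign flips, the column t-values for a
# sign vector s are a function of m_j = (s' D)_j / n alone, so a whole block
# of permutations is one matrix product.
t_from_means <- function(M, q, n) {
  v <- (rep(q, each = nrow(M)) - n * M^2) / (n - 1)
  tt <- M / sqrt(v / n)
  tt[!is.finite(tt)] <- 0
  matrix(tt, nrow = nrow(M))
}

# Largest link count over weak components of a directed edge subset.
# Cheap path for the permutation loop; 0 or 1 edge needs no search.
max_comp_links <- function(edges) {
  ne <- nrow(edges)
  if (ne <= 1L) return(ne)
  nodes <- unique(as.vector(edges))
  e2 <- matrix(match(edges, nodes), ncol = 2)
  lab <- uf_components(e2, length(nodes))
  max(tabulate(lab[e2[, 1L]], nbins = length(nodes)))
}

# Decompose a suprathreshold directed edge set into weak components and
# return one record per component.
component_records <- function(edges, tvals) {
  if (!nrow(edges)) return(list())
  nodes <- unique(as.vector(edges))
  e2 <- matrix(match(edges, nodes), ncol = 2)
  lab <- uf_components(e2, length(nodes))
  lab <- match(lab, unique(lab))
  lapply(seq_len(max(lab)), function(k) {
    in_k <- lab[e2[, 1L]] == k
    list(links = data.frame(src = edges[in_k, 1L], dst = edges[in_k, 2L],
                            t = tvals[in_k]),
         n_links = sum(in_k))
  })
}

#' Classify the nodes of a directed network
#'
#' Labels each node by its role in the link set: a *source* has only
#' outgoing links, a *sink* only incoming links, and an *intermediate* node
#' has both. Degree is the total number of links touching the node.
#'
#' @param links Data frame with `src` and `dst` columns (node ids or
#'   labels).
#' @return Data frame `node`, `type`, `n_out`, `n_in`, `degree`, sorted by
#'   decreasing degree.
#' @export
#' @examples
#' classify_nodes(data.frame(src = c("A", "B"), dst = c("B", "C")))
classify_nodes <- function(links) {
  if (!nrow(links)) stop("empty link set")
  nodes <- unique(c(links$src, links$dst))
  n_out <- vapply(nodes, function(v) sum(links$src == v), integer(1))
  n_in <- vapply(nodes, function(v) sum(links$dst == v), integer(1))
  type <- ifelse(n_out > 0 & n_in == 0, "source",
                 ifelse(n_in > 0 & n_out == 0, "sink", "intermediate"))
  out <- data.frame(node = nodes, type = type, n_out = n_out, n_in = n_in,
                    degree = n_out + n_in, row.names = NULL)
  out[order(-out$degree), ]
}

new_directed_network <- function(links, p, measure, sign = "positive",
                                 labels = NULL) {
  if (!is.null(labels)) {
    links$src_label <- labels[links$src]
    links$dst_label <- labels[links$dst]
  }
  structure(list(links = links, nodes = classify_nodes(links), p = p,
                 measure = measure, sign = sign),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %s (%s): %d links, %d nodes, p = %.4g\n",
              x$measure, x$sign, nrow(x$links), nrow(x$nodes), x$p))
  invisible(x)
}

#' @export
summary.directed_network <- function(object, ...) {
  print(object)
  cat("node roles:\n")
  print(object$nodes, row.names = FALSE)
  invisible(object)
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s: %d candidate component(s), %d significant at alpha = %g\n",
              x$measure, nrow(x$components), length(x$networks),
              x$alpha_comp))
  if (nrow(x$components)) print(x$components, row.names = FALSE)
  invisible(x)
}

# Core of the directed network-based statistic. D is subjects x links on the
# logit scale (condition differences for the paired variant; the
# anti-symmetric logit dPLI values for the one-sample variant — transposing a
# subject's matrix negates its row, so both permutation schemes are row sign
# flips). mode "two_sided" keeps both tails and forms components separately
# per sign; mode "positive" keeps only leading (t > 0) link directions.
nbs_core <- function(D, pairs, measure, alpha_init, alpha_comp, n_perm,
                     seed, mode, labels = NULL, block = 500L) {
  n <- nrow(D)
  if (n < 3) stop("at least 3 subjects are required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  sdv <- apply(D, 2, stats::sd)
  drop <- which(sdv == 0 | !is.finite(sdv))
  if (length(drop)) {
    warning(length(drop), " zero-variance link(s) excluded")
    D <- D[, -drop, drop = FALSE]
    pairs <- pairs[-drop, , drop = FALSE]
  }
  if (!ncol(D)) {
    # e.g. identical conditions: nothing to test, nothing significant
    return(structure(list(networks = list(),
                          components = data.frame(component = integer(0),
                                                  sign = character(0),
                                                  n_links = integer(0),
                                                  p = numeric(0)),
                          t = numeric(0), pairs = pairs,
                          null_max = rep(0, n_perm), measure = measure,
                          alpha_init = alpha_init, alpha_comp = alpha_comp,
                          n_perm = n_perm),
                     class = "nbs_result"))
  }
  df <- n - 1
  tcrit <- stats::qt(1 - alpha_init / 2, df)
  q <- colSums(D^2)
  t_obs <- as.vector(t_from_means(matrix(colMeans(D), 1), q, n))

  supra_sets <- function(tv) {
    if (mode == "positive") list(positive = which(tv > tcrit))
    else list(positive = which(tv > tcrit), negative = which(tv < -tcrit))
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    Tm <- t_from_means(S %*% D / n, q, n)
    for (r in seq_len(nb)) {
      mx <- 0L
      for (idx in supra_sets(Tm[r, ])) {
        if (length(idx))
          mx <- max(mx, max_comp_links(pairs[idx, , drop = FALSE]))
      }
      null_max[done + r] <- mx
    }
    done <- done + nb
  }

  comps <- list()
  for (sgn in names(supra_sets(t_obs))) {
    idx <- supra_sets(t_obs)[[sgn]]
    if (!length(idx)) next
    for (rec in component_records(pairs[idx, , drop = FALSE], t_obs[idx])) {
      p <- (1 + sum(null_max >= rec$n_links)) / (1 + n_perm)
      comps[[length(comps) + 1L]] <-
        list(net = new_directed_network(rec$links, p, measure, sgn, labels),
             n_links = rec$n_links, sign = sgn, p = p)
    }
  }
  summary_df <- if (length(comps)) {
    data.frame(component = seq_along(comps),
               sign = vapply(comps, `[[`, character(1), "sign"),
               n_links = vapply(comps, `[[`, integer(1), "n_links"),
               p = vapply(comps, `[[`, numeric(1), "p"))
  } else data.frame(component = integer(0), sign = character(0),
                    n_links = integer(0), p = numeric(0))
  structure(list(networks = lapply(Filter(function(cc) cc$p < alpha_comp,
                                          comps), `[[`, "net"),
                 components = summary_df, t = t_obs, pairs = pairs,
                 null_max = null_max, measure = measure,
                 alpha_init = alpha_init, alpha_comp = alpha_comp,
                 n_perm = n_perm),
            class = "nbs_result")
}

# Stack a list (or 3-d array) of n_roi x n_roi matrices into subjects x links
# over the given ordered pairs.
stack_links <- function(mats, pairs) {
  t(vapply(mats, function(m) m[pairs], numeric(nrow(pairs))))
}

ordered_pairs <- function(n_roi, diagonal) {
  g <- expand.grid(src = seq_len(n_roi), dst = seq_len(n_roi))
  g <- g[diagonal | g$src != g$dst, ]
  cbind(g$src, g$dst)
}

as_mat_list <- function(x) {
  if (is.list(x)) x else lapply(seq_len(dim(x)[3]), function(i) x[, , i])
}

#' Directed NBS: paired contrast of two conditions
#'
#' Network-based statistic for directed (non-symmetric) connectivity
#' matrices, contrasting two conditions within subjects. Each ordered link
#' gets a paired t-test across subjects; links crossing the initial
#' threshold (two-sided `p < alpha_init`) are grouped — separately for
#' positive and negative contrasts — into weakly connected components
#' (directions ignored for connectedness). Family-wise error over
#' components is controlled by permutation: conditions are swapped within
#' random subsets of subjects (equivalently the per-subject differences are
#' sign-flipped), and the null distribution records the largest component
#' link count over both signs. Component
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' Use logit-scale matrices so the t-test operates on an unbounded scale.
#' For nMI matrices the diagonal (local coupling) participates as
#' self-loop links.
#'
#' @param a,b Lists (or `n_roi x n_roi x n_subj` arrays) of connectivity
#'   matrices, one per subject, same subject order in both conditions.
#' @param alpha_init Two-sided per-link threshold for component definition.
#' @param alpha_comp Component-level significance threshold.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draw.
#' @param measure Tag stored on the result (e.g. `"nMI"`).
#' @param diagonal Include diagonal (self-loop) links? Default `TRUE`;
#'   diagonals that are `NA` in any subject are dropped automatically.
#' @param labels Optional ROI labels for reporting.
#' @return An `nbs_result`: significant `networks` (class
#'   `directed_network`), a `components` summary table, per-link `t`, and
#'   the permutation null.
#' @export
nbs_paired <- function(a, b, alpha_init = 0.005, alpha_comp = 0.05,
                       n_perm = 5000, seed = 1, measure = "nMI",
                       diagonal = TRUE, labels = NULL) {
  a <- as_mat_list(a)
  b <- as_mat_list(b)
  if (length(a) != length(b))
    stop("conditions must have the same subjects")
  n_roi <- nrow(a[[1]])
  pairs <- ordered_pairs(n_roi, diagonal)
  Da <- stack_links(a, pairs)
  Db <- stack_links(b, pairs)
  D <- Da - Db
  ok <- colSums(is.na(D)) == 0
  nbs_core(D[, ok, drop = FALSE], pairs[ok, , drop = FALSE], measure,
           alpha_init, alpha_comp, n_perm, seed, mode = "two_sided",
           labels = labels %||% colnames(a[[1]]))
}

#' Directed NBS: consistent lead directions within one condition
#'
#' For anti-symmetric logit dPLI matrices a paired contrast between
#' conditions is not meaningful; instead, each ordered link is tested for a
#' lead direction consistent across subjects with a one-sample t-test
#' against 0. Only the leading direction of each pair (positive t, two-sided
#' `p < alpha_init`) enters the component search. The permutation null
#' transposes each subject's matrix independently — reversing all its link
#' directions, which on the anti-symmetric logit scale is a per-subject
#' sign flip — and records the largest weak-component link count.
#'
#' @param mats List (or array) of per-subject logit-scale dPLI matrices for
#'   one condition (anti-symmetric, `NA` diagonal).
#' @inheritParams nbs_paired
#' @return An `nbs_result` (see [nbs_paired()]).
#' @export
nbs_onesample_dpli <- function(mats, alpha_init = 0.005, alpha_comp = 0.05,
                               n_perm = 5000, seed = 1, measure = "dPLI",
                               labels = NULL) {
  mats <- as_mat_list(mats)
  n_roi <- nrow(mats[[1]])
  for (m in mats) {
    od <- !is.na(m) & !is.na(t(m))
    if (max(abs(m[od] + t(m)[od])) > 1e-8)
      stop("matrices must be anti-symmetric (logit scale)")
  }
  pairs <- ordered_pairs(n_roi, diagonal = FALSE)
  D <- stack_links(mats, pairs)
  ok <- colSums(is.na(D)) == 0
  nbs_core(D[, ok, drop = FALSE], pairs[ok, , drop = FALSE], measure,
           alpha_init, alpha_comp, n_perm, seed, mode = "positive",
           labels = labels %||% colnames(mats[[1]]))
}

#' Neighborhood edges from source coordinates
#'
#' Declares two point sources neighbors when their Euclidean distance is
#' below `radius`; the default radius is 1.5 times the median
#' nearest-neighbor spacing of the grid, a conventional choice when the
#' source geometry does not come with an explicit neighborhood structure.
#'
#' @param coords `n_sources` x 3 coordinate matrix (mm).
#' @param radius Neighbor radius in mm, or `NULL` for the default.
#' @return Two-column integer matrix of neighbor pairs (i < j).
#' @export
adjacency_from_coords <- function(coords, radius = NULL) {
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  if (is.null(radius)) {
    diag(d) <- Inf
    radius <- 1.5 * stats::median(apply(d, 1, min))
    diag(d) <- 0
  }
  idx <- which(upper.tri(d) & d <= radius & d > 0, arr.ind = TRUE)
  unname(as.matrix(idx))
}

#' Cluster-based permutation test on source power
#'
#' Compares standardized source power between two conditions with a
#' two-sided paired t-test per point source, controls multiple comparisons
#' by cluster-based permutation: suprathreshold sources (two-sided
#' `p < alpha_init`) are grouped into spatially connected clusters —
#' positive and negative t separately — and each cluster's mass (sum of
#' t-values) is referred to the permutation distribution of the maximum
#' absolute cluster mass under random within-subject condition swaps
#' (sign flips of the per-subject differences).
#'
#' @param power_a,power_b `n_subjects x n_sources` matrices of per-source
#'   average standardized power under each condition (paired rows).
#' @param adjacency Two-column matrix of neighbor pairs
#'   (see [adjacency_from_coords()]).
#' @param alpha_init Two-sided per-source threshold for cluster definition.
#' @param alpha_cluster Cluster-level significance threshold.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @param coords Optional source coordinates; adds each cluster's peak
#'   location to the report.
#' @param block Permutations evaluated per vectorized block (memory/speed
#'   trade-off; results do not depend on it).
#' @return Object of class `cluster_result_set`: list with `clusters` (each
#'   with members, mass, peak t, peak coordinate, p), a summary data frame,
#'   per-source `t`, and the permutation null.
#' @export
cluster_perm_power <- function(power_a, power_b, adjacency,
                               alpha_init = 5e-4, alpha_cluster = 0.05,
                               n_perm = 5000, seed = 1, coords = NULL,
                               block = 500L) {
  power_a <- as.matrix(power_a)
  power_b <- as.matrix(power_b)
  stopifnot(identical(dim(power_a), dim(power_b)))
  n <- nrow(power_a)
  if (n < 2) stop("at least 2 subjects are required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  D <- power_a - power_b
  ns <- ncol(D)
  if (length(adjacency) && max(adjacency) > ns)
    stop("adjacency references unknown sources")
  df <- n - 1
  tcrit <- stats::qt(1 - alpha_init / 2, df)
  q <- colSums(D^2)
  t_obs <- as.vector(t_from_means(matrix(colMeans(D), 1), q, n))

  clusters_of <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      supra <- which(sgn * tv > tcrit)
      if (!length(supra)) next
      keep <- adjacency[adjacency[, 1] %in% supra &
                          adjacency[, 2] %in% supra, , drop = FALSE]
      lab <- uf_components(matrix(match(keep, supra), ncol = 2),
                           length(supra))
      for (k in unique(lab)) {
        mem <- supra[lab == k]
        out[[length(out) + 1L]] <- list(members = mem,
                                        mass = sum(tv[mem]))
      }
    }
    out
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    Tm <- t_from_means(S %*% D / n, q, n)
    for (r in seq_len(nb)) {
      cl <- clusters_of(Tm[r, ])
      null_max[done + r] <- if (length(cl))
        max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
    }
    done <- done + nb
  }

  obs <- clusters_of(t_obs)
  clusters <- lapply(obs, function(cl) {
    p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    peak <- cl$members[which.max(abs(t_obs[cl$members]))]
    list(members = cl$members, mass = cl$mass, p = p,
         peak_t = t_obs[peak], peak_source = peak,
         peak_coord = if (!is.null(coords)) coords[peak, ] else NULL)
  })
  summary_df <- if (length(clusters)) {
    data.frame(cluster = seq_along(clusters),
               n_sources = vapply(clusters, function(c) length(c$members),
                                  integer(1)),
               sum_t = vapply(clusters, `[[`, numeric(1), "mass"),
               peak_t = vapply(clusters, `[[`, numeric(1), "peak_t"),
               p = vapply(clusters, `[[`, numeric(1), "p"))
  } else data.frame(cluster = integer(0), n_sources = integer(0),
                    sum_t = numeric(0), peak_t = numeric(0),
                    p = numeric(0))
  structure(list(clusters = Filter(function(cl) cl$p < alpha_cluster,
                                   clusters),
                 all_clusters = clusters, summary = summary_df, t = t_obs,
                 null_max = null_max, alpha_init = alpha_init,
                 alpha_cluster = alpha_cluster, n_perm = n_perm),
            class = "cluster_result_set")
}

#' @export
print.cluster_result_set <- function(x, ...) {
  cat(sprintf("<cluster_result_set> %d candidate cluster(s), %d significant at alpha = %g\n",
              nrow(x$summary), length(x$clusters), x$alpha_cluster))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare link distances across connectivity types
#'
#' Computes the Euclidean distance (mm) between the centroids of the two
#' ROIs of every link of each significant network, then tests whether the
#' distance profiles differ across connectivity types with a one-way ANOVA
#' followed by all pairwise post-hoc t-tests, Dunn-Sidak adjusted
#' (`p_adj = 1 - (1 - p)^m` over the `m` pairwise comparisons).
#'
#' @param networks Named list: one `directed_network` (or a data frame of
#'   `src`, `dst` links as ROI row indices) per connectivity type.
#' @param roi_table ROI table with centroid columns `x`, `y`, `z`.
#' @return List with `distances` (per-link data frame), `anova`
#'   (F, df, p), and `posthoc` (pairwise raw and adjusted p).
#' @export
link_distance_anova <- function(networks, roi_table) {
  cent <- as.matrix(roi_table[, c("x", "y", "z")])
  dist_df <- NULL
  for (nm in names(networks)) {
    lk <- networks[[nm]]
    if (inherits(lk, "directed_network")) lk <- lk$links
    if (is.null(lk) || nrow(lk) < 2) {
      warning("connectivity type '", nm, "' has fewer than 2 links; excluded")
      next
    }
    dd <- sqrt(rowSums((cent[lk$src, , drop = FALSE] -
                          cent[lk$dst, , drop = FALSE])^2))
    dist_df <- rbind(dist_df, data.frame(measure = nm, src = lk$src,
                                         dst = lk$dst, distance = dd))
  }
  if (is.null(dist_df) || length(unique(dist_df$measure)) < 2)
    stop("need at least 2 connectivity types with >= 2 links each")
  dist_df$measure <- factor(dist_df$measure)
  fit <- stats::aov(distance ~ measure, data = dist_df)
  an <- summary(fit)[[1]]
  groups <- levels(dist_df$measure)
  cmb <- utils::combn(groups, 2)
  m <- ncol(cmb)
  posthoc <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                        p_raw = NA_real_, p_sidak = NA_real_)
  for (i in seq_len(m)) {
    x1 <- dist_df$distance[dist_df$measure == cmb[1, i]]
    x2 <- dist_df$distance[dist_df$measure == cmb[2, i]]
    p <- stats::t.test(x1, x2)$p.value
    posthoc$p_raw[i] <- p
    posthoc$p_sidak[i] <- 1 - (1 - p)^m
  }
  list(distances = dist_df,
       anova = data.frame(F = an$`F value`[1], df_between = an$Df[1],
                          df_within = an$Df[2], p = an$`Pr(>F)`[1]),
       posthoc = posthoc)
}

#' Export a directed network as edge-list and node tables
#'
#' @param net A `directed_network`.
#' @param prefix Output path prefix; writes `<prefix>_links.tsv`
#'   (src, dst, t and labels if present) and `<prefix>_nodes.tsv`
#'   (node, type, degree).
#' @return The two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "directed_network"))
  lp <- paste0(prefix, "_links.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  utils::write.table(net$links, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, np, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(lp, np))
}
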