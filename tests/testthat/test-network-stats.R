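rand_antisym_logit <- function(n_roi) {
  g <- matrix(rnorm(n_roi^2), n_roi)
  m <- g - t(g)
  diag(m) <- NA
  m
}

test_that("weak components ignore direction and match the igraph oracle", {
  wc <- weak_components(rbind(c(1, 2), c(2, 3)), n_nodes = 4)
  expect_equal(wc$membership[1:3], rep(wc$membership[1], 3))
  expect_equal(max(wc$n_links), 2)
  empty <- weak_components(matrix(integer(0), 0, 2), n_nodes = 5)
  expect_equal(empty$n_components, 5)  # all singletons, no links
  expect_true(all(empty$n_links == 0))
  skip_if_not_installed("igraph")
  set.seed(10)
  for (i in 1:10) {
    n <- 20
    ne <- sample(5:40, 1)
    edges <- cbind(sample(n, ne, TRUE), sample(n, ne, TRUE))
    mine <- weak_components(edges, n)$membership
    ref <- oracle_weak_components(edges, n)
    # same partition up to label permutation
    expect_equal(length(unique(mine)), length(unique(ref)))
    expect_true(all(tapply(ref, mine, function(v) length(unique(v))) == 1))
  }
})

test_that("node typing follows the in/out link pattern", {
  ch <- classify_nodes(data.frame(src = c("A", "B"), dst = c("B", "C")))
  expect_equal(ch$type[match(c("A", "B", "C"), ch$node)],
               c("source", "intermediate", "sink"))
  ab <- classify_nodes(data.frame(src = "A", dst = "B"))
  expect_equal(ab$type[match(c("A", "B"), ab$node)], c("source", "sink"))
  star <- classify_nodes(data.frame(src = c("P", "Q", "R", "S"),
                                    dst = rep("H", 4)))
  expect_equal(star$type[star$node == "H"], "sink")
  expect_equal(star$degree[star$node == "H"], 4L)
})

test_that("cluster permutation: null self-comparison and planted effects", {
  set.seed(20)
  coords <- cbind(rep(1:5, 4), rep(1:4, each = 5), 0)  # 20 sources on a grid
  adj <- adjacency_from_coords(coords)
  pa <- matrix(rnorm(10 * 20), 10, 20)
  # identical conditions: no suprathreshold source at all
  r0 <- cluster_perm_power(pa, pa, adj, n_perm = 100, seed = 1)
  expect_length(r0$clusters, 0)
  expect_equal(nrow(r0$summary), 0)
  # isolated single-source effect: one significant 1-source cluster
  pb <- pa + matrix(rnorm(10 * 20, sd = 0.3), 10, 20)
  pb[, 7] <- pb[, 7] - 3
  r1 <- cluster_perm_power(pa, pb, cbind(integer(0), integer(0)),
                           alpha_init = 5e-4, n_perm = 1000, seed = 2)
  expect_equal(nrow(r1$summary), 1)
  expect_equal(r1$all_clusters[[1]]$members, 7L)
  expect_lt(r1$all_clusters[[1]]$p, 0.05)
})

test_that("cluster formation groups adjacent suprathreshold sources with summed mass", {
  # 6 sources on a chain; strong planted effects at 2-3-4 only
  set.seed(21)
  adj <- cbind(1:5, 2:6)
  n_sub <- 10
  d <- matrix(rnorm(n_sub * 6, sd = 0.05), n_sub, 6)
  d[, 2:4] <- d[, 2:4] + 1
  r <- cluster_perm_power(d, matrix(0, n_sub, 6), adj, alpha_init = 5e-4,
                          n_perm = 200, seed = 3, coords = cbind(1:6, 0, 0))
  expect_equal(nrow(r$summary), 1)
  cl <- r$all_clusters[[1]]
  expect_equal(sort(cl$members), 2:4)
  expect_equal(cl$mass, sum(r$t[2:4]))
  expect_equal(cl$peak_coord[1], cl$peak_source)
})

test_that("paired directed NBS: null, recovery and FWER-relevant p-values", {
  set.seed(30)
  n_sub <- 12
  a <- lapply(1:n_sub, function(i) matrix(rnorm(64), 8))
  # identical conditions: empty result, no error (all links flagged flat)
  expect_warning(r_id <- nbs_paired(a, a, n_perm = 50, seed = 1),
                 "zero-variance")
  expect_length(r_id$networks, 0)
  # planted component: links 1->2, 2->3, 3->1 stronger in condition a
  b <- lapply(1:n_sub, function(i) matrix(rnorm(64), 8))
  a2 <- lapply(a, function(m) {
    m[1, 2] <- m[1, 2] + 4
    m[2, 3] <- m[2, 3] + 4
    m[3, 1] <- m[3, 1] + 4
    m
  })
  r <- nbs_paired(a2, b, n_perm = 500, seed = 2,
                  labels = LETTERS[1:8])
  expect_gte(length(r$networks), 1)
  net <- r$networks[[1]]
  expect_lt(net$p, 0.05)
  got <- paste(net$links$src, net$links$dst)
  expect_true(all(c("1 2", "2 3", "3 1") %in% got))
  expect_true(all(net$links$src_label %in% LETTERS[1:8]))
  # permutation p-values live on the discrete grid (k+1)/(n_perm+1)
  expect_true(all(r$components$p >= 1 / 501 & r$components$p <= 1))
})

test_that("one-sample dPLI NBS finds consistent leads and is transpose-equivariant", {
  set.seed(31)
  n_sub <- 12
  # a consistent 3-link chain 4 -> 9 -> 2 -> 5: single links are rarely
  # significant under the max-component null, components are
  chain <- rbind(c(4, 9), c(9, 2), c(2, 5))
  mats <- lapply(1:n_sub, function(i) {
    m <- rand_antisym_logit(10)
    for (k in 1:3) {
      m[chain[k, 1], chain[k, 2]] <- abs(m[chain[k, 1], chain[k, 2]]) + 3
      m[chain[k, 2], chain[k, 1]] <- -m[chain[k, 1], chain[k, 2]]
    }
    m
  })
  r <- nbs_onesample_dpli(mats, n_perm = 500, seed = 5)
  expect_gte(length(r$networks), 1)
  links <- do.call(rbind, lapply(r$networks, `[[`, "links"))
  expect_true(all(paste(chain[, 1], chain[, 2]) %in%
                    paste(links$src, links$dst)))
  # all-zero matrices: nothing to report
  z <- lapply(1:n_sub, function(i) {
    m <- matrix(0, 10, 10)
    diag(m) <- NA
    m
  })
  expect_warning(rz <- nbs_onesample_dpli(z, n_perm = 50, seed = 1),
                 "zero-variance")
  expect_length(rz$networks, 0)
  # transposing every input reverses all links, p-values unchanged
  rt <- nbs_onesample_dpli(lapply(mats, t), n_perm = 500, seed = 5)
  expect_equal(rt$components$p, r$components$p)
  lt <- do.call(rbind, lapply(rt$networks, `[[`, "links"))
  expect_setequal(paste(lt$dst, lt$src), paste(links$src, links$dst))
  expect_error(nbs_onesample_dpli(lapply(1:12, function(i)
    matrix(rnorm(100), 10))), "anti-symmetric")
  expect_error(nbs_onesample_dpli(mats[1:2], n_perm = 10), "3 subjects")
})

test_that("link-distance ANOVA matches the sum-of-squares oracle and Sidak rule", {
  # centroids on a line so link distances are exactly the planted lists
  tab <- data.frame(id = 1:10, abbrev = paste0("R", 1:10),
                    x = c(0, 10, 11, 12, 30, 31, 32, 50, 51, 52),
                    y = 0, z = 0)
  nets <- list(
    theta = data.frame(src = 1, dst = c(2, 3, 4)),     # 10, 11, 12 mm
    gamma = data.frame(src = 1, dst = c(5, 6, 7)),     # 30, 31, 32 mm
    pac = data.frame(src = 1, dst = c(8, 9, 10)))      # 50, 51, 52 mm
  res <- link_distance_anova(nets, tab)
  expect_equal(sort(res$distances$distance),
               c(10, 11, 12, 30, 31, 32, 50, 51, 52))
  ref <- oracle_anova(res$distances$distance, res$distances$measure)
  expect_equal(res$anova$F, ref$F)
  expect_equal(res$anova$p, ref$p)
  expect_equal(res$posthoc$p_sidak, 1 - (1 - res$posthoc$p_raw)^3)
  # identical distance lists: F = 0, adjusted p ~ 1
  same <- list(a = data.frame(src = 1, dst = c(2, 3, 4)),
               b = data.frame(src = 1, dst = c(2, 3, 4)))
  res0 <- link_distance_anova(same, tab)
  expect_equal(res0$anova$F, 0)
  expect_gt(min(res0$posthoc$p_sidak), 0.99)
  expect_warning(
    expect_error(link_distance_anova(list(a = nets$theta,
                                          b = data.frame(src = 1, dst = 2)),
                                     tab), "at least 2"),
    "fewer than 2 links")
})
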