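# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately avoid the code paths they validate:
# explicit loops, direct formula evaluation, eigendecompositions and igraph.

# Heaviside-sum dPLI, explicit loop, H(0) = 0.5.
oracle_dpli <- function(phase_x, phase_y) {
  total <- 0
  for (t in seq_along(phase_x)) {
    d <- phase_x[t] - phase_y[t]
    d <- ((d + pi) %% (2 * pi)) - pi
    if (d == -pi) d <- pi
    total <- total + if (d > 0) 1 else if (d < 0) 0 else 0.5
  }
  total / length(phase_x)
}

# Direct nMI formula, explicit accumulation of the complex sum.
oracle_nmi <- function(phase_lo, amp_hi) {
  n <- length(amp_hi)
  acc <- 0 + 0i
  ss <- 0
  for (t in seq_len(n)) {
    acc <- acc + amp_hi[t] * exp(1i * phase_lo[t])
    ss <- ss + amp_hi[t]^2
  }
  Mod(acc) / (sqrt(n) * sqrt(ss))
}

# Leading component of a time x k block via the eigendecomposition of the
# k x k Gram matrix (independent of svd()); returns the time course before
# any sign convention.
oracle_leading_component <- function(block) {
  g <- crossprod(block)            # k x k
  e <- eigen(g, symmetric = TRUE)
  v <- e$vectors[, 1]
  as.vector(block %*% v)           # = u1 * d1 up to sign
}

# Weak components through igraph on the undirected projection.
oracle_weak_components <- function(edges, n_nodes) {
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < n_nodes)
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  igraph::components(g, mode = "weak")$membership
}

# Textbook one-way ANOVA by explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(lapply(split(values, groups), function(v)
    (v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Frequency-domain analytic-signal oracle built bin by bin.
oracle_analytic_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  for (k in seq_len(n)) {
    freq_index <- k - 1
    if (freq_index == 0 || (n %% 2 == 0 && freq_index == n / 2)) {
      # DC and Nyquist kept as-is
    } else if (freq_index < n / 2) {
      X[k] <- 2 * X[k]
    } else {
      X[k] <- 0
    }
  }
  stats::fft(X, inverse = TRUE) / n
}

# Squared magnitude response of a digital filter at frequency f (Hz),
# evaluated directly from the transfer-function polynomials (forward +
# backward application squares the magnitude).
oracle_filtfilt_gain <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(filt$b * z^(seq_along(filt$b) - 1)) /
    sum(filt$a * z^(seq_along(filt$a) - 1))
  Mod(h)^2
}

# Small random helpers shared across tests.
rand_phases <- function(n) stats::runif(n, -pi, pi)
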