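# Independent oracles and small fixture builders used across the suite.

# Closed-form evidence of the constant-mean Gaussian model with a uniform
# prior on [lo, hi]: the Gaussian integral over the mean, truncated to the
# prior box (via the normal CDF), divided by the prior width.
analytic_const_logZ <- function(y, sd, lo = 0, hi = 10) {
  n <- length(y)
  yb <- mean(y)
  S <- sum((y - yb)^2)
  -n / 2 * log(2 * pi * sd^2) - S / (2 * sd^2) +
    log(sqrt(2 * pi * sd^2 / n) *
          (pnorm((hi - yb) * sqrt(n) / sd) - pnorm((lo - yb) * sqrt(n) / sd))) -
    log(hi - lo)
}

# Brute-force two-sided Fisher p: sum of all hypergeometric outcomes with
# probability <= that of the observed table (row/column margins fixed).
fisher_p_enum <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All-pairs conserved-ordering edge recount in plain R (oracle for the
# compiled kernel): support(i, j) = #datasets with both present and t_i < t_j.
edges_brute_force <- function(tp, quorum) {
  g <- nrow(tp)
  edges <- 0L
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    ok <- !is.na(tp[i, ]) & !is.na(tp[j, ])
    if (sum(tp[i, ok] < tp[j, ok]) >= quorum) edges <- edges + 1L
  }
  edges
}

# Exact null distribution of the conserved-edge count for a complete 3x3
# peak-time matrix under independent within-column permutations: enumerate
# all (3!)^3 arrangements.
exact_edge_null_3x3 <- function(tp, quorum = 3) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  counts <- integer(0)
  for (p1 in perms) for (p2 in perms) for (p3 in perms) {
    m <- cbind(tp[p1, 1], tp[p2, 2], tp[p3, 3])
    counts <- c(counts, edges_brute_force(m, quorum))
  }
  counts
}

# A small bundle with controllable maxima, used by the io tests.
make_test_bundle <- function(n = 6, seed = 1, dataset_id = "DSX") {
  times <- c(0, 30, 60, 120, 240)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tcs <- lapply(seq_len(n), function(i) {
      base <- runif(1, 0, 30)
      expr <- matrix(base + runif(3 * length(times), 0, 5), nrow = 3)
      time_course(sprintf("tss%02d", i), sprintf("gene%02d", (i + 1) %/% 2),
                  if (i %% 2) "coding" else "noncoding", dataset_id,
                  times, expr)
    })
    dataset_bundle(dataset_id, tcs, ieg_labels = c("gene01", "gene02"))
  })
}

grid12 <- c(0, 15, 30, 45, 60, 80, 100, 120, 160, 200, 240, 300)
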