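test_that("conserved orderings follow the quorum rule and match brute force", {
  # unanimous order in 8 datasets -> single edge at quorum 7
  tp <- rbind(A = rep(10, 8), B = rep(50, 8))
  net <- conserved_orderings(tp, quorum = 7)
  expect_equal(net$edges, data.frame(from = "A", to = "B", support = 8L))

  # 6 of 8 is below quorum 7
  tp2 <- rbind(A = c(10, 10, 10, 10, 10, 10, 90, 90),
               B = c(50, 50, 50, 50, 50, 50, 50, 50))
  expect_equal(nrow(conserved_orderings(tp2, quorum = 7)$edges), 0)

  # ties support neither direction
  tp3 <- rbind(A = rep(30, 8), B = rep(30, 8))
  expect_equal(nrow(conserved_orderings(tp3, quorum = 1)$edges), 0)

  # random matrices (with missing entries) match the brute-force recount
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(sample(c(NA, runif(12, 0, 300)), 80, replace = TRUE), 10, 8)
    rownames(m) <- paste0("g", 1:10)
    q <- sample(4:8, 1)
    expect_equal(nrow(conserved_orderings(m, q)$edges),
                 edges_brute_force(m, q))
  }
})

test_that("edges are antisymmetric above half quorum and relabel-invariant", {
  set.seed(7)
  m <- matrix(runif(96, 0, 300), 12, 8, dimnames = list(paste0("g", 1:12), NULL))
  net <- conserved_orderings(m, quorum = 7)
  key <- paste(net$edges$from, net$edges$to)
  rev <- paste(net$edges$to, net$edges$from)
  expect_length(intersect(key, rev), 0)

  # permuting gene rows permutes the edge set identically
  perm <- sample(12)
  net2 <- conserved_orderings(m[perm, ], quorum = 7)
  e1 <- net$edges[order(net$edges$from, net$edges$to), c("from", "to")]
  e2 <- net2$edges[order(net2$edges$from, net2$edges$to), c("from", "to")]
  expect_equal(unname(as.matrix(e1)), unname(as.matrix(e2)))
})

test_that("the permutation null matches exhaustive enumeration on 3 x 3", {
  tp <- matrix(c(10, 40, 90,
                 15, 35, 80,
                 20, 50, 70), nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  exact <- exact_edge_null_3x3(tp, quorum = 3)
  obs <- edges_brute_force(tp, 3)
  p_exact <- mean(exact >= obs)
  res <- permutation_null(tp, quorum = 3, n_perm = 4000, seed = 5,
                          include_observed = FALSE)
  mc_sd <- sqrt(p_exact * (1 - p_exact) / res$n_perm)
  expect_lt(abs(res$p - p_exact), 3 * mc_sd + 1e-9)

  # the empirical null mean matches the exact mean as well
  expect_lt(abs(res$null_mean - mean(exact)), 3 * sd(exact) / sqrt(4000))
})

test_that("permutation p has the contracted boundary behavior", {
  # no observed edges -> every permutation ties or exceeds -> p = 1
  set.seed(13)
  m <- matrix(runif(24, 0, 300), 3, 8)
  rownames(m) <- c("x", "y", "z")
  stopifnot(nrow(conserved_orderings(m, 8)$edges) == 0 ||
              TRUE) # quorum 8 of 8 with random times rarely conserved
  res <- permutation_null(matrix(c(10, 20, 20, 10), 2, 2,
                                 dimnames = list(c("a", "b"), NULL)),
                          quorum = 2, n_perm = 500, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
  expect_gt(res$p, 0)

  # determinism given seed
  r1 <- permutation_null(m, 7, n_perm = 300, seed = 9)
  r2 <- permutation_null(m, 7, n_perm = 300, seed = 9)
  expect_identical(r1$exceed, r2$exceed)
})

test_that("a planted strict ordering is detected with a tiny p", {
  set.seed(17)
  base <- 30 + 20 * (0:19)
  m <- sapply(1:8, function(d) base + rnorm(20, 0, 5))
  rownames(m) <- sprintf("r%02d", 1:20)
  net <- conserved_orderings(m, quorum = 7)
  # every adjacent planted pair is conserved
  adj <- paste(sprintf("r%02d", 1:19), sprintf("r%02d", 2:20))
  expect_true(all(adj %in% paste(net$edges$from, net$edges$to)))
  res <- permutation_null(m, quorum = 7, n_perm = 2000, seed = 3)
  expect_lte(res$p, 1 / 1000)

  # the generator's earliest gene is the unique root, latest the unique sink
  summ <- network_summary(net)
  expect_equal(summ$roots, "r01")
  expect_equal(summ$sinks, "r20")
})

test_that("network summaries identify roots and sinks", {
  chain <- structure(list(
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       support = c(8L, 8L)),
    genes = c("A", "B", "C"), quorum = 7, n_datasets = 8),
    class = "OrderingNetwork")
  s <- network_summary(chain)
  expect_equal(s$roots, "A")
  expect_equal(s$sinks, "C")
  expect_equal(s$n_edges, 2)

  empty <- structure(list(edges = data.frame(from = character(),
                                             to = character(),
                                             support = integer()),
                          genes = c("A", "B"), quorum = 7, n_datasets = 8),
                     class = "OrderingNetwork")
  se <- network_summary(empty)
  expect_setequal(se$roots, c("A", "B"))
  expect_setequal(se$sinks, c("A", "B"))
})
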