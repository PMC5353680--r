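test_that("pair_counts counts joint bits exactly and conserves the pool size", {
  pool <- pool_of(c(1, 1), c(1, 0))
  pc <- pair_counts(pool, 1, 2)
  expect_equal(pc$n11, 1); expect_equal(pc$n10, 1)
  expect_equal(pc$n00, 0); expect_equal(pc$n01, 0)

  ident <- matrix(rep(c(1L, 0L, 1L), 10), nrow = 10, byrow = TRUE)
  pc2 <- pair_counts(ident, 1, 3)
  expect_equal(pc2$n11, 10)
  expect_equal(pc2$n00 + pc2$n01 + pc2$n10, 0)

  set.seed(1)
  rnd <- matrix(rbinom(60, 1, 0.4), nrow = 20)
  pc3 <- pair_counts(rnd, 2, 3)
  expect_equal(pc3$N, 20)
  expect_error(pair_counts(rnd, 2, 2), "distinct")
  expect_error(pair_counts(rnd[0, , drop = FALSE], 1, 2), "empty")
})

test_that("chi2/mi on canonical tables and SIM conjunction", {
  even <- pc_from_table(matrix(c(4, 4, 4, 4), 2))
  diag2 <- pc_from_table(matrix(c(5, 0, 0, 5), 2))
  expect_equal(chi2_pair(even), 0)
  expect_equal(chi2_pair(diag2), 10)
  expect_equal(mi_pair(even), 0)
  expect_equal(mi_pair(diag2), 1)
  skew <- pc_from_table(matrix(c(2, 1, 1, 2), 2))
  expect_equal(mi_pair(skew), mi_oracle(matrix(c(2, 1, 1, 2), 2)),
               tolerance = 1e-12)

  expect_equal(sim_pair(diag2), 1L)   # chi2 = 10 >= 3.84 and MI = 1
  expect_equal(sim_pair(even), 0L)

  # degenerate margins contribute 0 rather than NaN
  degen <- pc_from_table(matrix(c(7, 0, 3, 0), 2))
  expect_equal(chi2_pair(degen), 0)
})

test_that("chi2 and mi agree with textbook oracles on 1000 random tables", {
  set.seed(7)
  for (rep in 1:1000) {
    tab <- matrix(rpois(4, 5) + 1, 2)   # +1 keeps margins non-degenerate
    pc <- pc_from_table(tab)
    expect_equal(chi2_pair(pc), chi2_oracle(tab), tolerance = 1e-9)
    expect_equal(mi_pair(pc), mi_oracle(tab), tolerance = 1e-9)
  }
})

test_that("sim firing implies the 3.84 chi-square rule would also fire", {
  set.seed(8)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0) next
    pc <- pc_from_table(tab)
    if (sim_pair(pc) == 1L) expect_gte(chi2_pair(pc), 3.84)
  }
})

test_that("marginal entropy matches closed forms and ignores bit labels", {
  half <- pool_of(1, 1, 0, 0)
  expect_equal(marginal_entropy(half, 1), 1)
  const <- pool_of(1, 1, 1, 1)
  expect_equal(marginal_entropy(const, 1), 0)
  quarter <- pool_of(1, 0, 0, 0)
  expect_equal(marginal_entropy(quarter, 1), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  # relabeling invariance: p and 1-p give the same entropy
  expect_equal(marginal_entropy(pool_of(0, 1, 1, 1), 1),
               marginal_entropy(quarter, 1))
})

test_that("build_edge_set fires per criterion; mi never keeps fewer than sim", {
  # column 2 duplicates column 1, balanced, N = 20 -> chi2 = 20
  dup <- cbind(rep(c(1L, 0L), 10), rep(c(1L, 0L), 10), rbinom(20, 1, 0.5))
  e_chi <- build_edge_set(dup, "chi2")
  expect_true(any(e_chi$i == 1 & e_chi$j == 2))
  expect_equal(e_chi$strength[e_chi$i == 1 & e_chi$j == 2], 20)

  # exactly independent balanced columns: all cells at expectation -> no edges
  indep <- as.matrix(expand.grid(0:1, 0:1))
  colnames(indep) <- NULL
  expect_equal(nrow(build_edge_set(indep, "chi2")), 0L)

  set.seed(9)
  for (rep in 1:20) {
    pool <- matrix(rbinom(8 * 6, 1, 0.5), nrow = 8)
    expect_gte(nrow(build_edge_set(pool, "mi")), nrow(build_edge_set(pool, "sim")))
  }
  expect_equal(nrow(build_edge_set(dup, "none")), 0L)
})

test_that("dependency_stats matrices are symmetric, zero-diagonal, consistent", {
  set.seed(10)
  pool <- matrix(rbinom(12 * 5, 1, 0.5), nrow = 12)
  st <- dependency_stats(pool)
  expect_equal(st$chi2, t(st$chi2))
  expect_equal(st$mi, t(st$mi))
  expect_true(all(diag(st$chi2) == 0) && all(diag(st$mi) == 0))
  expect_true(all(st$chi2 >= 0) && all(st$mi >= -1e-12))
  expect_equal(st$chi2[1, 2], chi2_pair(pair_counts(pool, 1, 2)), tolerance = 1e-9)
  expect_equal(st$mi[3, 4], mi_pair(pair_counts(pool, 3, 4)), tolerance = 1e-9)
  expect_equal(st$entropy[2], marginal_entropy(pool, 2))
})

test_that("build_forest keeps the maximum-strength forest with min-entropy roots", {
  edges <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                      strength = c(10, 8, 5))
  f <- build_forest(edges, 3, entropies = c(0.5, 1.0, 0.7))
  kept <- apply(f$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(kept, c("1-2", "2-3"))
  expect_equal(f$roots, 1L)           # lowest entropy in its component
  expect_equal(f$parent[2], 1L)       # oriented away from the root
  expect_equal(f$parent[3], 2L)

  # empty edge list: all singletons, all roots
  f0 <- build_forest(data.frame(i = integer(0), j = integer(0),
                                strength = numeric(0)),
                     4, entropies = rep(1, 4))
  expect_equal(length(f0$components), 4L)
  expect_equal(f0$roots, 1:4)
  expect_equal(nrow(f0$edges), 0L)

  # min-entropy root rule picks the 0.5-entropy node in a 2-node component
  f2 <- build_forest(data.frame(i = 1, j = 2, strength = 5), 2,
                     entropies = c(1.0, 0.5))
  expect_equal(f2$roots, 2L)

  # the random-root baseline is seeded and keeps the same undirected edges
  fr1 <- build_forest(edges, 3, root_rule = "random", seed = 4)
  fr2 <- build_forest(edges, 3, root_rule = "random", seed = 4)
  expect_identical(fr1$roots, fr2$roots)
  expect_setequal(apply(fr1$edges, 1, function(e) paste(sort(e), collapse = "-")),
                  kept)
})

test_that("forest invariants: one parent per non-root, disjoint components, acyclic", {
  set.seed(11)
  for (rep in 1:30) {
    l <- sample(3:7, 1)
    edges <- random_edges(l, sample(0:min(10, l * (l - 1) / 2), 1))
    f <- build_forest(edges, l, entropies = runif(l))
    expect_equal(sort(unlist(f$components)), 1:l)
    expect_equal(sum(lengths(f$components)), l)
    expect_equal(length(f$roots), length(f$components))
    expect_true(all(is.na(f$parent[f$roots])))
    expect_equal(sum(!is.na(f$parent)), l - length(f$components))  # acyclic
  }
})

test_that("forest structure is invariant under edge-list permutation", {
  set.seed(12)
  edges <- random_edges(6, 9)
  f1 <- build_forest(edges, 6, entropies = rep(0.5, 6))
  f2 <- build_forest(edges[sample(nrow(edges)), ], 6, entropies = rep(0.5, 6))
  expect_identical(f1$parent, f2$parent)
  expect_identical(f1$roots, f2$roots)
})
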