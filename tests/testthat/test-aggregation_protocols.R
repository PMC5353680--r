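# minimal hand-built run_result stand-ins for the pure aggregation arithmetic
fake_run <- function(bits, acc, dep = NULL, final_edges = NULL, seed = 1L) {
  l <- length(bits)
  structure(list(
    best = list(bits = as.integer(bits), fitness = acc, holdout_accuracy = acc),
    dependency_counts = if (is.null(dep)) matrix(0L, l, l) else dep,
    final_msf_edges = final_edges,
    evaluations = 0L, seed = as.integer(seed),
    fitness_trace = data.frame(iter = 0L, best_fitness = acc,
                               mean_fitness = acc, n_edges = 0L,
                               converged = FALSE)
  ), class = "run_result")
}

test_that("average_relevance filters on the accuracy floor (strict)", {
  runs <- list(fake_run(c(1, 0, 1), 0.90), fake_run(c(1, 1, 0), 0.85))
  expect_equal(average_relevance(runs, 0.80), c(1.0, 0.5, 0.5))
  expect_equal(average_relevance(runs, 0.88), c(1, 0, 1))
  expect_equal(average_relevance(runs, 0), c(1.0, 0.5, 0.5))
  # exactly at the floor is excluded (strictly greater)
  expect_equal(average_relevance(runs, 0.85), c(1, 0, 1))
  expect_error(average_relevance(runs, 0.99), "no repetition passed")
})

test_that("select_relevant uses strict cutoffs and is monotone", {
  avg <- c(1.0, 0.5, 0.72)
  expect_equal(select_relevant(avg, 0.7), c(1L, 3L))
  expect_equal(select_relevant(avg, 1.0), integer(0))
  expect_equal(select_relevant(avg, 0), 1:3)
  for (cut in seq(0, 1, by = 0.1)) {
    expect_true(all(select_relevant(avg, cut + 0.1) %in% select_relevant(avg, cut)))
  }
})

test_that("dependency counts aggregate per mode and stay symmetric", {
  dep <- matrix(0L, 3, 3); dep[1, 2] <- dep[2, 1] <- 4L
  e23 <- data.frame(parent = 2L, child = 3L)
  runs <- list(fake_run(c(1, 1, 0), 0.9, dep = dep, final_edges = e23),
               fake_run(c(1, 1, 0), 0.9, final_edges = e23),
               fake_run(c(1, 1, 0), 0.9, final_edges = data.frame(
                 parent = 1L, child = 2L)))
  fin <- aggregate_dependency_counts(runs, "final_msf")
  expect_equal(fin[2, 3], 2L)   # edge (2,3) in 2 of 3 final forests
  expect_equal(fin[1, 2], 1L)
  expect_equal(fin, t(fin))
  expect_true(all(diag(fin) == 0))
  alli <- aggregate_dependency_counts(runs, "all_iterations")
  expect_equal(alli[1, 2], 4L)

  bad <- c(runs, list(fake_run(c(1, 0), 0.9)))
  expect_error(aggregate_dependency_counts(bad), "disagree")
})

test_that("consensus_tree is the Kruskal tree on inverse counts", {
  counts <- matrix(0, 3, 3)
  counts[1, 2] <- counts[2, 1] <- 90
  counts[2, 3] <- counts[3, 2] <- 80
  counts[1, 3] <- counts[3, 1] <- 10
  tree <- consensus_tree(counts)
  expect_equal(nrow(tree), 2L)
  expect_setequal(paste(tree$i, tree$j), c("1 2", "2 3"))

  # two disconnected groups give a forest of two trees
  counts4 <- matrix(0, 4, 4)
  counts4[1, 2] <- counts4[2, 1] <- 5
  counts4[3, 4] <- counts4[4, 3] <- 7
  tree4 <- consensus_tree(counts4)
  expect_equal(nrow(tree4), 2L)
  expect_setequal(paste(tree4$i, tree4$j), c("1 2", "3 4"))

  single <- matrix(0, 3, 3); single[1, 3] <- single[3, 1] <- 2
  expect_equal(nrow(consensus_tree(single)), 1L)
  expect_warning(empty <- consensus_tree(matrix(0, 3, 3)), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("consensus_tree matches the exhaustive forest oracle on small matrices", {
  set.seed(50)
  for (rep in 1:40) {
    l <- sample(3:6, 1)
    counts <- matrix(0, l, l)
    pairs <- which(upper.tri(counts), arr.ind = TRUE)
    pick <- sample(nrow(pairs), sample(2:min(8, nrow(pairs)), 1))
    counts[pairs[pick, , drop = FALSE]] <- sample(1:50, length(pick))
    counts <- counts + t(counts)
    tree <- consensus_tree(counts)
    got <- sum(counts[cbind(tree$i, tree$j)])
    idx <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
    edges <- data.frame(i = idx[, 1], j = idx[, 2], strength = counts[idx])
    expect_equal(got, max_forest_weight_oracle(edges, l), tolerance = 1e-9)
  }
})

test_that("discovery_score does the set arithmetic and bubble_tally conserves mass", {
  sc <- discovery_score(c(1, 2, 4), 1:3, 4:8)
  expect_equal(sc$n_relevant_found, 2)
  expect_equal(sc$n_noise_found, 4)
  perfect <- discovery_score(1:3, 1:3, 4:8)
  expect_equal(unlist(perfect), c(n_relevant_found = 3, n_noise_found = 5))
  none <- discovery_score(integer(0), 1:3, 4:8)
  expect_equal(none$n_noise_found, 5)
  expect_error(discovery_score(1, 1:3, 3:5), "overlap")

  scores <- c(replicate(98, list(perfect)), replicate(2, list(sc)))
  tal <- bubble_tally(scores, 3, 5)
  expect_equal(sum(tal), 100)
  expect_equal(tal["3", "5"], 98L)
  expect_equal(tal["2", "4"], 2L)
  expect_error(bubble_tally(list(perfect), 2, 5), "out of tally range")
})

test_that("repeat_protocol derives seeds, repeats identically, shuffle keeps shape", {
  ds <- make_toy_classification("xor2", m = 120, n_noise = 1, seed = 60)
  cfg <- search_config(pool_size = 8, max_iters = 4)
  r1 <- repeat_protocol(ds, cfg, reps = 2, base_seed = 3, train_fraction = 0.5)
  r2 <- repeat_protocol(ds, cfg, reps = 2, base_seed = 3, train_fraction = 0.5)
  expect_identical(lapply(r1, `[[`, "best"), lapply(r2, `[[`, "best"))
  expect_identical(r1[[1]]$seed, 4L)
  expect_identical(r1[[2]]$seed, 5L)

  r3 <- repeat_protocol(ds, cfg, reps = 1, base_seed = 3, shuffle = TRUE,
                        train_fraction = 0.5)
  expect_length(r3[[1]]$best$bits, 3L)

  agg <- aggregate_runs(r1, cutoff = 0.5)
  expect_s3_class(agg, "aggregate_result")
  expect_length(agg$avg_relevance, 3L)
  js <- jsonlite::fromJSON(aggregate_to_json(agg))
  expect_equal(js$protocol$reps, 2)
})
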