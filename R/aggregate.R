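#' Repeat a search protocol with derived seeds
#'
#' Runs `reps` independent searches. Repetition `r` uses seed
#' `base_seed + r`; with `shuffle = TRUE` the instance order is permuted
#' before splitting (the extra variability used in the 100-repetition
#' protocol). Each repetition re-splits the data into train/test.
#'
#' @param ds a preprocessed [kiedra_dataset()].
#' @param cfg a [search_config()]; its `seed` field is overridden per
#'   repetition.
#' @param reps number of repetitions, >= 1.
#' @param base_seed integer base seed.
#' @param shuffle permute instance order per repetition before splitting.
#' @param train_fraction fraction of rows for training (0.25 reproduces the
#'   25%/75% epistasis protocol; 0.5 the equal-size benchmark protocol).
#' @param variant `"kiedra"` or `"wkiera"`.
#' @param stratified stratify the splits (default `TRUE`).
#' @return List of `run_result` objects, one per repetition.
#' @export
repeat_protocol <- function(ds, cfg = search_config(), reps = 30L,
                            base_seed = 1L, shuffle = FALSE,
                            train_fraction = 0.25,
                            variant = c("kiedra", "wkiera"),
                            stratified = TRUE) {
  variant <- match.arg(variant)
  if (reps < 1L) stop("reps must be at least 1")
  lapply(seq_len(reps), function(r) {
    seed_r <- as.integer(base_seed + r)
    d <- if (shuffle) shuffle_rows(ds, seed_r + 50021L) else ds
    parts <- split_train_test(d, train_fraction, seed = seed_r,
                              stratified = stratified)
    cfg_r <- cfg
    cfg_r$seed <- seed_r
    run_search(parts$train, parts$test, cfg_r, variant)
  })
}

#' Average best-candidate relevance over accepted repetitions
#'
#' Mean of the best candidates' bit vectors across runs whose held-out
#' accuracy exceeds `accuracy_floor` (strictly). A floor of 0 averages all
#' runs, as in the epistasis protocol; 0.8 reproduces the "accuracy greater
#' than 80%" filter of the medical-domain protocol.
#'
#' @param runs list of `run_result`s.
#' @param accuracy_floor held-out accuracy threshold in `[0, 1)`.
#' @return Length-`l` vector of averaged relevance factors in `[0, 1]`.
#' @export
average_relevance <- function(runs, accuracy_floor = 0) {
  accs <- vapply(runs, function(r) r$best$holdout_accuracy, numeric(1))
  if (accuracy_floor > 0) {
    keep <- !is.na(accs) & accs > accuracy_floor
  } else {
    keep <- rep(TRUE, length(runs))
  }
  if (!any(keep)) {
    stop("no repetition passed the accuracy floor of ", accuracy_floor,
         " (best observed: ", format(max(accs, na.rm = TRUE)), ")")
  }
  bits <- vapply(runs[keep], function(r) as.numeric(r$best$bits),
                 numeric(length(runs[[1]]$best$bits)))
  rowMeans(matrix(bits, ncol = sum(keep)))
}

#' Threshold averaged relevance factors
#'
#' Indices whose averaged factor is strictly greater than the cutoff (0.7 in
#' the epistasis protocol, 0.5 in the medical-domain protocol).
#'
#' @param avg relevance vector in `[0, 1]^l`.
#' @param cutoff threshold.
#' @return Integer vector of selected (1-based) feature indices.
#' @export
select_relevant <- function(avg, cutoff = 0.7) {
  which(avg > cutoff)
}

#' Aggregate dependency edges across repetitions
#'
#' @param runs list of `run_result`s over the same number of features.
#' @param mode `"all_iterations"` sums every iteration's forest-edge
#'   inclusions (the heatmap payload); `"final_msf"` counts, per unordered
#'   pair, in how many runs the final forest contains the edge.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
aggregate_dependency_counts <- function(runs,
                                        mode = c("all_iterations", "final_msf")) {
  mode <- match.arg(mode)
  ls <- vapply(runs, function(r) ncol(r$dependency_counts), integer(1))
  if (length(unique(ls)) != 1L) stop("runs disagree on the number of features")
  l <- ls[1]
  total <- matrix(0L, l, l)
  for (r in runs) {
    if (mode == "all_iterations") {
      total <- total + r$dependency_counts
    } else if (!is.null(r$final_msf_edges) && nrow(r$final_msf_edges) > 0L) {
      for (e in seq_len(nrow(r$final_msf_edges))) {
        a <- r$final_msf_edges$parent[e]; b <- r$final_msf_edges$child[e]
        total[a, b] <- total[a, b] + 1L
        total[b, a] <- total[b, a] + 1L
      }
    }
  }
  total
}

#' Kruskal consensus tree over aggregated dependency counts
#'
#' Takes the inverse of each positive count as an edge cost and runs
#' Kruskal's algorithm, i.e. a maximum-count spanning forest: pairs never
#' seen together carry no edge, and disconnected groups yield one tree each.
#' Ties break lexicographically by pair.
#'
#' @param counts symmetric non-negative matrix from
#'   [aggregate_dependency_counts()].
#' @return Data frame with columns `i`, `j` (`i < j`) and `count`; zero rows
#'   (with a warning) when all counts are zero.
#' @export
consensus_tree <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  l <- ncol(counts)
  idx <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("all dependency counts are zero; consensus tree is empty")
    return(data.frame(i = integer(0), j = integer(0), count = numeric(0)))
  }
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      strength = counts[idx])   # max count == min 1/count
  forest <- build_forest(edges, l, entropies = rep(0, l),
                         root_rule = "min_entropy")
  kept <- forest$edges
  out <- data.frame(i = pmin(kept$parent, kept$child),
                    j = pmax(kept$parent, kept$child))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out$count <- counts[cbind(out$i, out$j)]
  out
}

#' Discovery coordinate (#R, #N) against the ground truth
#'
#' `n_relevant_found` counts truly relevant features that were selected;
#' `n_noise_found` counts truly noisy features that were correctly excluded.
#' A perfect run on a k-way problem with p noise features scores (k, p).
#'
#' @param selected integer vector of selected feature indices.
#' @param truth_relevant,truth_noisy disjoint ground-truth index sets.
#' @return List with `n_relevant_found` and `n_noise_found`.
#' @export
discovery_score <- function(selected, truth_relevant, truth_noisy) {
  if (length(intersect(truth_relevant, truth_noisy)) > 0L) {
    stop("truth_relevant and truth_noisy overlap")
  }
  list(n_relevant_found = length(intersect(selected, truth_relevant)),
       n_noise_found = length(setdiff(truth_noisy, selected)))
}

#' Tally discovery coordinates into a bubble-frequency matrix
#'
#' @param scores list of [discovery_score()] results.
#' @param max_R,max_N the truth set sizes (matrix bounds).
#' @return `(max_R+1) x (max_N+1)` count matrix; entry `[r+1, n+1]` is the
#'   number of scores at coordinate `(r, n)`; the total equals
#'   `length(scores)`.
#' @export
bubble_tally <- function(scores, max_R, max_N) {
  tally <- matrix(0L, max_R + 1L, max_N + 1L,
                  dimnames = list(R = 0:max_R, N = 0:max_N))
  for (s in scores) {
    if (s$n_relevant_found > max_R || s$n_noise_found > max_N) {
      stop("discovery score out of tally range")
    }
    tally[s$n_relevant_found + 1L, s$n_noise_found + 1L] <-
      tally[s$n_relevant_found + 1L, s$n_noise_found + 1L] + 1L
  }
  tally
}

#' Bundle repetition results into an aggregate summary
#'
#' Convenience wrapper applying the standard post-processing chain:
#' accuracy-floored relevance averaging, cutoff selection, dependency-count
#' aggregation and the Kruskal consensus tree.
#'
#' @param runs list of `run_result`s.
#' @param cutoff relevance cutoff for [select_relevant()].
#' @param accuracy_floor held-out accuracy floor for [average_relevance()].
#' @param dep_mode aggregation mode for [aggregate_dependency_counts()].
#' @return An `aggregate_result`: list with `avg_relevance`, `relevant_set`,
#'   `dep_counts`, `consensus_tree`, `per_run` (best fitness / held-out
#'   accuracy / evaluations per run), `protocol` echo.
#' @export
aggregate_runs <- function(runs, cutoff = 0.7, accuracy_floor = 0,
                           dep_mode = c("all_iterations", "final_msf")) {
  dep_mode <- match.arg(dep_mode)
  avg <- average_relevance(runs, accuracy_floor)
  dep <- aggregate_dependency_counts(runs, dep_mode)
  tree <- if (any(dep > 0)) consensus_tree(dep) else
    data.frame(i = integer(0), j = integer(0), count = numeric(0))
  per_run <- data.frame(
    rep = seq_along(runs),
    seed = vapply(runs, function(r) r$seed, integer(1)),
    best_fitness = vapply(runs, function(r) r$best$fitness, numeric(1)),
    holdout_accuracy = vapply(runs, function(r) r$best$holdout_accuracy,
                              numeric(1)),
    evaluations = vapply(runs, function(r) r$evaluations, integer(1))
  )
  structure(list(avg_relevance = avg,
                 relevant_set = select_relevant(avg, cutoff),
                 dep_counts = dep,
                 consensus_tree = tree,
                 per_run = per_run,
                 protocol = list(reps = length(runs), cutoff = cutoff,
                                 accuracy_floor = accuracy_floor,
                                 dep_mode = dep_mode)),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat("<aggregate_result> ", x$protocol$reps, " repetitions\n", sep = "")
  cat("  avg relevance: ",
      paste(formatC(x$avg_relevance, digits = 2, format = "f"),
            collapse = " "), "\n", sep = "")
  cat("  relevant set (cutoff ", x$protocol$cutoff, "): {",
      paste(x$relevant_set, collapse = ", "), "}\n", sep = "")
  cat("  consensus tree: ", nrow(x$consensus_tree), " edges\n", sep = "")
  invisible(x)
}

#' Serialize an aggregate result to JSON
#'
#' @param agg an `aggregate_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
aggregate_to_json <- function(agg, path = NULL) {
  js <- jsonlite::toJSON(unclass(agg), auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
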