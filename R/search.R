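#' Search configuration for the model-building evolution
#'
#' Defaults follow the epistasis-discovery protocol: a pool of `n = 20`
#' candidates, 80 iterations, the SIM edge criterion, minimum-entropy roots,
#' truncation of the top half as the elite, RBF kernel with `sigma = 10` and
#' `C = 100`, 5-fold fitness cross-validation.
#'
#' @param pool_size pool size `n`, even and >= 4.
#' @param max_iters iteration budget.
#' @param criterion dependency edge criterion: `"sim"`, `"chi2"`, `"mi"` or
#'   `"none"` (no edges; forces the univariate model).
#' @param root_rule forest root choice, `"min_entropy"` or `"random"`.
#' @param elite_fraction fraction of the pool kept as the elite `B`; 0.5 is
#'   the only value consistent with `sample(P, n/2) U B` keeping the pool at
#'   `n`.
#' @param convergence_delta early stop when every marginal is within this of
#'   0 or 1.
#' @param smoothing Laplace pseudo-count for model estimation.
#' @param kernel a [kernel_spec()].
#' @param folds fitness CV folds.
#' @param seed integer master seed; every random draw of the run derives from
#'   it.
#' @param n_vars number of variables, only needed when running against a
#'   surrogate cost function with no dataset.
#' @return A `search_config` list.
#' @export
search_config <- function(pool_size = 20L, max_iters = 80L,
                          criterion = c("sim", "chi2", "mi", "none"),
                          root_rule = c("min_entropy", "random"),
                          elite_fraction = 0.5, convergence_delta = 0.01,
                          smoothing = 1, kernel = kernel_spec(),
                          folds = 5L, seed = 1L, n_vars = NULL) {
  criterion <- match.arg(criterion)
  root_rule <- match.arg(root_rule)
  pool_size <- as.integer(pool_size)
  if (pool_size < 4L || pool_size %% 2L != 0L) {
    stop("pool_size must be even and at least 4")
  }
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    stop("elite_fraction must lie strictly between 0 and 1")
  }
  structure(list(pool_size = pool_size, max_iters = as.integer(max_iters),
                 criterion = criterion, root_rule = root_rule,
                 elite_fraction = elite_fraction,
                 convergence_delta = convergence_delta,
                 smoothing = smoothing, kernel = kernel,
                 folds = as.integer(folds), seed = as.integer(seed),
                 n_vars = n_vars),
            class = "search_config")
}

#' Run the kernel-guided model-building evolution
#'
#' Iteration 0 draws `n` candidates from the uniform Bernoulli(0.5) model and
#' scores each by the wrapper fitness (CV accuracy of the weighted-kernel
#' SVM, or a surrogate `cost_fn`). Every following iteration: the elite `B`
#' (top half by fitness) defines dependency edges under the configured
#' criterion, a maximum-strength spanning forest with minimum-entropy roots,
#' and the frequentist model parameters; `n/2` fresh candidates are sampled
#' ancestrally and united with `B`; the pool is re-ranked and truncated. The
#' `"wkiera"` variant skips structure learning (empty edge set), degenerating
#' the model to independent per-variable marginals (UMDA).
#'
#' @param train training-split [kiedra_dataset()] (fitness is measured here);
#'   may be `NULL` when `cost_fn` is supplied.
#' @param test optional held-out split; when present, the best candidate's
#'   held-out accuracy is reported.
#' @param cfg a [search_config()].
#' @param variant `"kiedra"` (bivariate) or `"wkiera"` (univariate).
#' @param cost_fn optional surrogate cost: `function(bits) -> fitness in
#'   [0,1]`, replacing the classifier (used to test the optimizer in
#'   isolation; requires `cfg$n_vars`).
#' @return A `run_result`: list with `best` (`bits`, `fitness`,
#'   `holdout_accuracy`), `fitness_trace` (data frame per iteration),
#'   `final_model`, `final_msf_edges`, `dependency_counts` (symmetric l x l
#'   matrix of per-iteration forest-edge inclusions), `evaluations`, `seed`,
#'   `variant`, `config`.
#' @export
run_search <- function(train, test = NULL, cfg = search_config(),
                       variant = c("kiedra", "wkiera"), cost_fn = NULL) {
  variant <- match.arg(variant)
  if (is.null(cost_fn)) {
    if (is.null(train)) stop("need a training dataset or a cost_fn")
    l <- n_features(train)
    if (!is.null(test)) {
      if (n_features(test) != l) stop("train/test feature count mismatch")
      if (!identical(levels(train$labels), levels(test$labels))) {
        stop("train/test class sets differ")
      }
    }
    if (length(levels(train$labels)) < 2L) stop("degenerate labels")
    fold_id <- make_folds(train$labels, cfg$folds, seed = cfg$seed)
  } else {
    if (is.null(cfg$n_vars)) stop("cost_fn runs need cfg$n_vars")
    l <- as.integer(cfg$n_vars)
    fold_id <- NULL
  }
  criterion <- if (variant == "wkiera") "none" else cfg$criterion
  n <- cfg$pool_size
  n_elite <- max(1L, round(cfg$elite_fraction * n))
  n_new <- n - n_elite
  rng <- local_rng(cfg$seed)
  cache <- new.env(parent = emptyenv())
  evaluations <- 0L

  score <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- if (is.null(cost_fn)) {
      evaluate_candidate(train, bits, cfg$kernel, cfg$folds,
                         fold_id = fold_id)$cv_accuracy
    } else {
      cost_fn(bits)
    }
    evaluations <<- evaluations + 1L
    cache[[key]] <- fit
    fit
  }
  score_pool <- function(pool) {
    vapply(seq_len(nrow(pool)), function(r) score(pool[r, ]), numeric(1))
  }

  # iteration 0: uniform Bernoulli(0.5) pool of size n
  pool <- matrix(as.integer(runif_rng(rng, n * l) < 0.5), nrow = n, ncol = l)
  fitness <- score_pool(pool)
  ord <- order(-fitness, seq_len(n))
  best_bits <- pool[ord[1], ]
  best_fit <- fitness[ord[1]]
  elite <- pool[ord[seq_len(n_elite)], , drop = FALSE]
  elite_fit <- fitness[ord[seq_len(n_elite)]]

  dep_counts <- matrix(0L, l, l)
  trace <- vector("list", cfg$max_iters + 1L)
  trace[[1]] <- data.frame(iter = 0L, best_fitness = best_fit,
                           mean_fitness = mean(fitness), n_edges = 0L,
                           converged = FALSE)
  model <- NULL
  forest <- NULL
  for (t in seq_len(cfg$max_iters)) {
    edges <- build_edge_set(elite, criterion)
    ent <- vapply(seq_len(l), function(i) marginal_entropy(elite, i), numeric(1))
    forest <- build_forest(edges, l, ent, cfg$root_rule,
                           seed = cfg$seed + 7919L * t)
    model <- estimate_model(elite, forest, cfg$smoothing)
    if (nrow(forest$edges) > 0L) {
      for (r in seq_len(nrow(forest$edges))) {
        a <- forest$edges$parent[r]; b <- forest$edges$child[r]
        dep_counts[a, b] <- dep_counts[a, b] + 1L
        dep_counts[b, a] <- dep_counts[b, a] + 1L
      }
    }
    converged <- has_converged(model, cfg$convergence_delta)
    if (converged) {
      trace[[t + 1L]] <- data.frame(iter = t, best_fitness = best_fit,
                                    mean_fitness = mean(elite_fit),
                                    n_edges = nrow(forest$edges),
                                    converged = TRUE)
      break
    }
    fresh <- sample_candidates(model, n_new, seed = rng)
    pool <- rbind(elite, fresh)                   # S = sample(P, n/2) U B
    fitness <- c(elite_fit, score_pool(fresh))
    ord <- order(-fitness, seq_len(n))
    if (fitness[ord[1]] > best_fit) {
      best_fit <- fitness[ord[1]]
      best_bits <- pool[ord[1], ]
    }
    elite <- pool[ord[seq_len(n_elite)], , drop = FALSE]
    elite_fit <- fitness[ord[seq_len(n_elite)]]
    trace[[t + 1L]] <- data.frame(iter = t, best_fitness = best_fit,
                                  mean_fitness = mean(fitness),
                                  n_edges = nrow(forest$edges),
                                  converged = FALSE)
  }
  holdout <- NA_real_
  if (is.null(cost_fn) && !is.null(test)) {
    holdout <- holdout_accuracy(train, test, best_bits, cfg$kernel)
  }
  structure(list(
    best = list(bits = best_bits, fitness = best_fit,
                holdout_accuracy = holdout),
    fitness_trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
    final_model = model,
    final_msf_edges = if (is.null(forest)) NULL else forest$edges,
    dependency_counts = dep_counts,
    evaluations = evaluations,
    seed = cfg$seed,
    variant = variant,
    config = cfg
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", x$variant, ", best fitness ",
      formatC(x$best$fitness, digits = 4, format = "f"), sep = "")
  if (!is.na(x$best$holdout_accuracy)) {
    cat(", held-out ", formatC(x$best$holdout_accuracy, digits = 4,
                               format = "f"), sep = "")
  }
  cat(", ", x$evaluations, " evaluations, ",
      max(x$fitness_trace$iter), " iterations\n", sep = "")
  cat("  best bits: ", paste(x$best$bits, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Serialize a run result to JSON
#'
#' @param res a `run_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
run_result_to_json <- function(res, path = NULL) {
  payload <- list(
    variant = res$variant,
    seed = res$seed,
    best = res$best,
    evaluations = res$evaluations,
    fitness_trace = res$fitness_trace,
    dependency_counts = res$dependency_counts,
    final_msf_edges = res$final_msf_edges
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
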