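#' Estimate the forest-factored bivariate model from a candidate pool
#'
#' Frequentist counting over the pool: `rho_i[a]` is the number of candidates
#' with bit `a` at position `i`, and for every forest edge `(parent j, child
#' i)` `rho_ij[a, b]` counts joint occurrences of child bit `a` with parent
#' bit `b`. Probabilities are derived lazily with Laplace smoothing `s`:
#' marginal `P(X_i = 1) = (rho_i[1] + s) / (n + 2s)` and conditional
#' `P(X_i = 1 | X_j = b) = (rho_ij[1, b] + s) / (rho_j[b] + 2s)`. Without
#' smoothing a conditional on an unseen parent value divides by zero and
#' probabilities saturate at exactly 0/1, freezing the evolution; `s = 0` is
#' allowed for purists.
#'
#' @param pool 0/1 candidate matrix (rows = candidates).
#' @param structure a `dependency_forest` from [build_forest()] over the same
#'   number of features.
#' @param smoothing Laplace pseudo-count `s >= 0`, default 1.
#' @return A `forest_model`: list with `structure`, `rho1` (count of ones per
#'   variable), `rho_edge` (list of 2x2 joint count matrices, child bit in
#'   rows), `pool_size`, `smoothing`.
#' @export
estimate_model <- function(pool, structure, smoothing = 1) {
  l <- ncol(pool)
  if (structure$l != l) stop("structure is over ", structure$l,
                             " variables but the pool has ", l)
  if (nrow(pool) < 1L) stop("empty candidate pool")
  rho1 <- colSums(pool == 1L)
  rho_edge <- NULL
  if (nrow(structure$edges) > 0L) {
    rho_edge <- lapply(seq_len(nrow(structure$edges)), function(r) {
      pa <- structure$edges$parent[r]
      ch <- structure$edges$child[r]
      cnt <- matrix(0, 2, 2,
                    dimnames = list(child = c("0", "1"), parent = c("0", "1")))
      for (a in 0:1) for (b in 0:1) {
        cnt[a + 1, b + 1] <- sum(pool[, ch] == a & pool[, pa] == b)
      }
      cnt
    })
  }
  structure(list(structure = structure, rho1 = rho1, rho_edge = rho_edge,
                 pool_size = nrow(pool), smoothing = smoothing, l = l),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat("<forest_model> ", x$l, " variables, ", nrow(x$structure$edges),
      " edges, pool size ", x$pool_size, ", smoothing ", x$smoothing, "\n",
      sep = "")
  invisible(x)
}

#' Smoothed marginal probabilities P(X_i = 1) of a forest model
#' @param model a `forest_model`.
#' @return Numeric vector of length `l`.
#' @export
model_marginals <- function(model) {
  (model$rho1 + model$smoothing) / (model$pool_size + 2 * model$smoothing)
}

# P(child = 1 | parent = b) for edge r, b in {0,1}
model_conditional <- function(model, r, b) {
  cnt <- model$rho_edge[[r]]
  s <- model$smoothing
  (cnt[2, b + 1] + s) / (sum(cnt[, b + 1]) + 2 * s)
}

# index of the edge whose child is `ch`, or NA
edge_index_of_child <- function(structure, ch) {
  match(ch, structure$edges$child)
}

#' Ancestral sampling of new candidates from a forest model
#'
#' Roots are drawn from their smoothed marginals, children from the smoothed
#' conditional given their already-sampled parent, following the forest's
#' topological order (roots first, then by increasing depth, lowest index
#' first within a level). Deterministic under a fixed seed.
#'
#' @param model a `forest_model`.
#' @param count number of candidates to draw.
#' @param seed integer seed, or a private RNG handle.
#' @return 0/1 integer matrix with `count` rows.
#' @export
sample_candidates <- function(model, count, seed = 1L) {
  if (count < 1L) stop("count must be at least 1")
  rng <- if (is.environment(seed)) seed else local_rng(seed)
  l <- model$l
  st <- model$structure
  marg <- model_marginals(model)
  out <- matrix(0L, nrow = count, ncol = l)
  u <- matrix(runif_rng(rng, count * l), nrow = count)  # one draw per cell
  for (node in st$topo_order) {
    pa <- st$parent[node]
    if (is.na(pa)) {
      out[, node] <- as.integer(u[, node] < marg[node])
    } else {
      r <- edge_index_of_child(st, node)
      p1 <- model_conditional(model, r, 1L)
      p0 <- model_conditional(model, r, 0L)
      p <- ifelse(out[, pa] == 1L, p1, p0)
      out[, node] <- as.integer(u[, node] < p)
    }
  }
  out
}

#' Exact probability of a candidate under a forest model
#'
#' Product of smoothed root marginals and edge conditionals evaluated at the
#' candidate's bits. Sums to 1 over all `2^l` candidates.
#'
#' @param model a `forest_model`.
#' @param bits 0/1 vector of length `l`.
#' @return Probability in (0, 1) for positive smoothing.
#' @export
candidate_probability <- function(model, bits) {
  if (length(bits) != model$l) stop("candidate length != model size")
  st <- model$structure
  marg <- model_marginals(model)
  p <- 1
  for (node in seq_len(model$l)) {
    pa <- st$parent[node]
    if (is.na(pa)) {
      pi1 <- marg[node]
    } else {
      r <- edge_index_of_child(st, node)
      pi1 <- model_conditional(model, r, bits[pa])
    }
    p <- p * if (bits[node] == 1L) pi1 else 1 - pi1
  }
  p
}

#' Has the model converged to saturation?
#'
#' True when every marginal probability lies within `delta` of 0 or 1, i.e.
#' the sampling distribution has effectively collapsed onto one candidate.
#'
#' @param model a `forest_model`.
#' @param delta saturation tolerance; with positive smoothing, `delta = 0`
#'   can never trigger.
#' @return Logical flag.
#' @export
has_converged <- function(model, delta = 0.01) {
  marg <- model_marginals(model)
  all(pmin(marg, 1 - marg) < delta)
}

#' Serialize a forest model to JSON
#'
#' @param model a `forest_model`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(
    l = model$l,
    pool_size = model$pool_size,
    smoothing = model$smoothing,
    rho1 = model$rho1,
    parent = model$structure$parent,
    roots = model$structure$roots,
    edges = model$structure$edges,
    rho_edge = lapply(model$rho_edge, function(m) as.vector(m))
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
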