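#' @name dependency-stats
#' @title Pairwise dependency statistics over a candidate pool
#'
#' @description
#' A candidate pool is a 0/1 integer matrix with one row per candidate
#' relevance vector and one column per feature. The bivariate model derives
#' its structure from pairwise statistics of the pool columns: the Pearson
#' chi-square statistic, the plug-in mutual information (bits), and the SIM
#' indicator that requires both a significant chi-square p-value and positive
#' information.
NULL

#' Joint 2x2 counts of two pool positions
#'
#' @param pool 0/1 matrix, candidates in rows.
#' @param i,j distinct column indices.
#' @return A `pair_counts` object: list with `n00,n01,n10,n11,N` where `nab`
#'   counts rows with bit `a` at `i` and bit `b` at `j`.
#' @export
pair_counts <- function(pool, i, j) {
  if (nrow(pool) < 1L) stop("empty candidate pool")
  if (i == j) stop("pair_counts needs two distinct positions")
  bi <- pool[, i]; bj <- pool[, j]
  n11 <- sum(bi == 1L & bj == 1L)
  n10 <- sum(bi == 1L & bj == 0L)
  n01 <- sum(bi == 0L & bj == 1L)
  n00 <- sum(bi == 0L & bj == 0L)
  structure(list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
                 N = n00 + n01 + n10 + n11),
            class = "pair_counts")
}

as_table2 <- function(c) {
  matrix(c(c$n00, c$n01, c$n10, c$n11), nrow = 2, byrow = TRUE)
}

#' Pearson chi-square statistic of a 2x2 count table
#'
#' `sum (o - e)^2 / e` with `e = row * col / N`; cells whose expected count is
#' zero (a degenerate margin) contribute 0, so constant positions yield 0
#' rather than NaN.
#'
#' @param c a [pair_counts()] object.
#' @return The statistic (non-negative real).
#' @export
chi2_pair <- function(c) {
  o <- as_table2(c)
  e <- outer(rowSums(o), colSums(o)) / c$N
  terms <- (o - e)^2 / e
  terms[e == 0] <- 0
  sum(terms)
}

#' Plug-in mutual information of a 2x2 count table, in bits
#'
#' `sum p_ab log2(p_ab / (p_a p_b))`, with `0 log 0 = 0`.
#'
#' @param c a [pair_counts()] object.
#' @return Mutual information in bits (non-negative up to round-off; clamped
#'   at 0).
#' @export
mi_pair <- function(c) {
  o <- as_table2(c)
  p <- o / c$N
  pa <- rowSums(p); pb <- colSums(p)
  terms <- p * log2(p / outer(pa, pb))
  terms[p == 0] <- 0
  max(0, sum(terms))
}

#' Combined significance-and-information (SIM) dependency indicator
#'
#' Fires (returns 1) when the chi-square test is significant at level `alpha`
#' (1 df) *and* the mutual information exceeds `mi_tol`. At the default
#' `alpha = 0.05` the chi-square condition is the classic `chi2 >= 3.84` rule.
#'
#' @param c a [pair_counts()] object.
#' @param alpha significance level for the chi-square p-value.
#' @param mi_tol positive-information tolerance; the literal "MI > 0" fires on
#'   almost any finite sample, so a tiny tolerance guards round-off only.
#' @return 0 or 1.
#' @export
sim_pair <- function(c, alpha = 0.05, mi_tol = 1e-12) {
  chi2 <- chi2_pair(c)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  as.integer(p <= alpha && mi_pair(c) > mi_tol)
}

#' Marginal entropy of one pool position, in bits
#'
#' Shannon entropy of the empirical bit frequency at column `i` of the pool.
#' Low-entropy (near-saturated) positions are information-rich and are the
#' preferred roots of the dependency forest.
#'
#' @param pool 0/1 candidate matrix.
#' @param i column index.
#' @return Entropy in `[0, 1]` bits.
#' @export
marginal_entropy <- function(pool, i) {
  if (nrow(pool) < 1L) stop("empty candidate pool")
  p <- mean(pool[, i] == 1L)
  ent2(p)
}

ent2 <- function(p) {
  q <- c(p, 1 - p)
  q <- q[q > 0]
  -sum(q * log2(q))
}

# Vectorized 2x2 statistics over all unordered pairs; returns symmetric
# matrices. The heavy lifting for build_edge_set and dependency heatmaps.
pool_pair_stats <- function(pool) {
  l <- ncol(pool)
  n <- nrow(pool)
  P <- pool
  n11 <- crossprod(P)                 # t(P) %*% P
  ri <- matrix(colSums(P), l, l)      # row margins (count of 1s at i)
  n10 <- ri - n11
  n01 <- t(ri) - n11
  n00 <- n - n11 - n10 - n01
  chi2 <- matrix(0, l, l)
  mi <- matrix(0, l, l)
  for (a in 0:1) for (b in 0:1) {
    o <- switch(paste0(a, b), "00" = n00, "01" = n01, "10" = n10, "11" = n11)
    pa <- if (a == 1) ri else n - ri
    pb <- if (b == 1) t(ri) else n - t(ri)
    e <- pa * pb / n
    term <- (o - e)^2 / e
    term[e == 0] <- 0
    chi2 <- chi2 + term
    p <- o / n
    mterm <- p * log2(p * n^2 / (pa * pb))
    mterm[o == 0] <- 0
    mi <- mi + mterm
  }
  mi <- pmax(mi, 0)
  diag(chi2) <- 0; diag(mi) <- 0
  list(chi2 = chi2, mi = mi)
}

#' All dependency matrices of a candidate pool
#'
#' @param pool 0/1 candidate matrix.
#' @param alpha,mi_tol SIM parameters, see [sim_pair()].
#' @return List with symmetric `chi2`, `mi`, `sim` matrices (zero diagonal)
#'   and the `entropy` vector of marginal entropies, all in bits.
#' @export
dependency_stats <- function(pool, alpha = 0.05, mi_tol = 1e-12) {
  st <- pool_pair_stats(pool)
  pval <- stats::pchisq(st$chi2, df = 1, lower.tail = FALSE)
  sim <- (pval <= alpha & st$mi > mi_tol) * 1
  diag(sim) <- 0
  entropy <- vapply(seq_len(ncol(pool)), function(i) marginal_entropy(pool, i),
                    numeric(1))
  list(chi2 = st$chi2, mi = st$mi, sim = sim, entropy = entropy)
}

#' Candidate dependency edges of a pool under a firing criterion
#'
#' Scans all unordered feature pairs and keeps those where the chosen
#' criterion fires: `chi2` keeps pairs with statistic at least 3.84 (the 5%
#' critical value at 1 df), `mi` pairs with information above `mi_tol`, and
#' `sim` pairs passing both conditions. Each kept edge carries a strength -
#' the chi-square statistic under `chi2`, the mutual information under `mi`
#' and `sim`. `"none"` returns the empty edge set (the univariate/UMDA
#' degeneration).
#'
#' @param pool 0/1 candidate matrix with at least 2 columns.
#' @param criterion `"chi2"`, `"mi"`, `"sim"` or `"none"`.
#' @param alpha,mi_tol SIM/chi-square parameters.
#' @return Data frame with columns `i`, `j` (1-based, `i < j`) and `strength`.
#' @export
build_edge_set <- function(pool, criterion = c("sim", "chi2", "mi", "none"),
                           alpha = 0.05, mi_tol = 1e-12) {
  criterion <- match.arg(criterion)
  l <- ncol(pool)
  empty <- data.frame(i = integer(0), j = integer(0), strength = numeric(0))
  if (criterion == "none" || l < 2L) return(empty)
  st <- pool_pair_stats(pool)
  pval <- stats::pchisq(st$chi2, df = 1, lower.tail = FALSE)
  keep <- switch(criterion,
    chi2 = st$chi2 >= 3.84,    # the 5% critical value at 1 df, as printed
    mi = st$mi > mi_tol,
    sim = pval <= alpha & st$mi > mi_tol)
  strength <- if (criterion == "chi2") st$chi2 else st$mi
  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  data.frame(i = idx[, 1], j = idx[, 2],
             strength = strength[idx])
}

#' Maximum-dependency spanning forest with entropy-minimizing roots
#'
#' Kruskal's greedy scan over the candidate edges sorted by decreasing
#' strength (ties broken by lexicographic `(i, j)`) keeps every edge joining
#' two distinct trees, yielding the spanning forest of maximum total
#' dependency strength. Features untouched by any edge become singleton
#' components. Per component one root is chosen - the minimum marginal
#' entropy node under `root_rule = "min_entropy"` (ties to the lowest index),
#' or a seeded uniform draw under `"random"` (the classic baseline) - and all
#' edges are oriented away from it.
#'
#' @param edges data frame from [build_edge_set()].
#' @param l number of features (nodes).
#' @param entropies length-`l` vector of marginal entropies (required for
#'   `min_entropy`).
#' @param root_rule `"min_entropy"` (default) or `"random"`.
#' @param seed seed for the random root rule.
#' @return A `dependency_forest`: list with `parent` (integer vector, `NA` at
#'   roots), `roots`, `edges` (data frame `parent`,`child`), `components`
#'   (list of index vectors), `component_id` (length-`l`).
#' @export
build_forest <- function(edges, l, entropies = NULL,
                         root_rule = c("min_entropy", "random"), seed = 1L) {
  root_rule <- match.arg(root_rule)
  if (root_rule == "min_entropy" && is.null(entropies)) {
    stop("min_entropy root rule needs the entropies vector")
  }
  if (nrow(edges) > 0L) {
    edges$i <- as.integer(edges$i)
    edges$j <- as.integer(edges$j)
    if (max(edges$i, edges$j) > l) stop("edge endpoint exceeds the number of nodes")
  }
  uf <- seq_len(l)
  find <- function(x) { while (uf[x] != x) x <- uf[x]; x }
  kept <- matrix(integer(0), ncol = 2)
  if (nrow(edges) > 0L) {
    ord <- order(-edges$strength, edges$i, edges$j)
    for (r in ord) {
      a <- find(edges$i[r]); b <- find(edges$j[r])
      if (a != b) {
        uf[a] <- b
        kept <- rbind(kept, c(edges$i[r], edges$j[r]))
      }
    }
  }
  comp_root <- vapply(seq_len(l), find, integer(1))
  comp_ids <- unique(comp_root)
  components <- lapply(comp_ids, function(cid) which(comp_root == cid))
  # order components by their lowest member for determinism
  components <- components[order(vapply(components, min, integer(1)))]
  component_id <- integer(l)
  for (k in seq_along(components)) component_id[components[[k]]] <- k

  rng <- if (root_rule == "random") local_rng(seed) else NULL
  roots <- vapply(components, function(v) {
    if (root_rule == "min_entropy") {
      v[which.min(entropies[v])]   # which.min ties -> first = lowest index
    } else {
      v[sample_int(rng, length(v))[1]]
    }
  }, integer(1))

  # orient kept edges away from the roots (BFS per component)
  adj <- vector("list", l)
  if (nrow(kept) > 0L) {
    for (r in seq_len(nrow(kept))) {
      a <- kept[r, 1]; b <- kept[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  parent <- rep(NA_integer_, l)
  order_visit <- integer(0)
  visited <- logical(l)
  for (root in roots) {
    queue <- root
    visited[root] <- TRUE
    while (length(queue)) {
      # expand lowest-index first for deterministic topological order
      queue <- sort(queue)
      node <- queue[1]; queue <- queue[-1]
      order_visit <- c(order_visit, node)
      for (nb in adj[[node]]) {
        if (!visited[nb]) {
          visited[nb] <- TRUE
          parent[nb] <- node
          queue <- c(queue, nb)
        }
      }
    }
  }
  edges_out <- data.frame(parent = parent[!is.na(parent)],
                          child = which(!is.na(parent)))
  structure(list(parent = parent, roots = sort(roots), edges = edges_out,
                 components = components, component_id = component_id,
                 topo_order = order_visit, l = l),
            class = "dependency_forest")
}

#' @export
print.dependency_forest <- function(x, ...) {
  cat("<dependency_forest> ", x$l, " nodes, ", length(x$components),
      " components, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Write a symmetric dependency matrix as TSV
#'
#' Serializes a feature-by-feature matrix (chi-square, MI, or aggregated edge
#' counts - the heatmap payload) with feature-name headers.
#'
#' @param mat symmetric numeric matrix.
#' @param path output path.
#' @param feature_names optional names for rows/columns.
#' @return `path`, invisibly.
#' @export
write_dependency_matrix <- function(mat, path, feature_names = NULL) {
  if (!is.null(feature_names)) dimnames(mat) <- list(feature_names, feature_names)
  utils::write.table(mat, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
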