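# Shared fixture builders; everything is generated in code at test time.

# write a small CSV and return its path
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# a pool matrix from candidate row vectors
pool_of <- function(...) {
  rows <- list(...)
  matrix(as.integer(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

pc_from_table <- function(tab) {
  # tab[a+1, b+1] = count of (bit_i = a, bit_j = b)
  structure(list(n00 = tab[1, 1], n01 = tab[1, 2],
                 n10 = tab[2, 1], n11 = tab[2, 2],
                 N = sum(tab)),
            class = "pair_counts")
}

# independent textbook oracles ---------------------------------------------

chi2_oracle <- function(tab) {
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

mi_oracle <- function(tab) {
  # entropy identity H(A) + H(B) - H(A,B), in bits
  N <- sum(tab)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ent(rowSums(tab) / N) + ent(colSums(tab) / N) - ent(as.vector(tab) / N)
}

# exhaustive maximum-weight spanning forest by enumerating acyclic edge
# subsets (<= 12 edges); returns the maximum achievable total weight
max_forest_weight_oracle <- function(edges, l) {
  ne <- nrow(edges)
  stopifnot(ne <= 12)
  best <- 0
  acyclic <- function(rows) {
    uf <- seq_len(l)
    find <- function(x) { while (uf[x] != x) x <- uf[x]; x }
    for (r in rows) {
      a <- find(as.integer(edges$i[r])); b <- find(as.integer(edges$j[r]))
      if (a == b) return(FALSE)
      uf[a] <- b
    }
    TRUE
  }
  if (ne == 0) return(0)
  for (mask in 0:(2^ne - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    if (length(rows) == 0) next
    if (acyclic(rows)) {
      w <- sum(edges$strength[rows])
      if (w > best) best <- w
    }
  }
  best
}

# random weighted edge list over l nodes
random_edges <- function(l, n_edges, weight_fn = function(n) runif(n, 0.1, 10)) {
  pairs <- which(upper.tri(matrix(0, l, l)), arr.ind = TRUE)
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(i = pairs[pick, 1], j = pairs[pick, 2],
             strength = weight_fn(length(pick)))
}
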