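#' Generate a pure k-way epistatic case-control dataset
#'
#' Simulates `k` SNP genotype columns (values 0/1/2, Hardy-Weinberg with the
#' given minor-allele frequency) and assigns disease status by the parity of
#' the genotypes: `class = (sum_i g_i) mod 2`. With allele frequency 0.5 each
#' genotype is odd with probability 1/2 independently, so any proper subset of
#' the `k` SNPs carries (in expectation) zero mutual information about the
#' class while the full set determines it - the defining property of "pure"
#' (NoLow) epistasis, with no marginal or lower-order effects to latch onto.
#'
#' A small marginal effect can be mixed back in via `leak`: with that
#' probability per instance the label is overwritten by the parity of the
#' first SNP alone, emulating non-NoLow variants.
#'
#' @param k interaction order (number of relevant SNPs), at least 2.
#' @param m number of instances, at least 50.
#' @param allele_freq allele frequency in (0,1); 0.5 gives balanced parity.
#' @param leak probability of replacing the label with a single-SNP marginal
#'   signal; default 0 (pure interaction).
#' @param seed integer seed; same spec + seed regenerates bit-identically.
#' @return A [kiedra_dataset()] with columns `snp_1..snp_k`, labels
#'   `"case"`/`"control"`, and `meta$truth_relevant` = 1..k.
#' @export
generate_epistasis_dataset <- function(k, m, allele_freq = 0.5, leak = 0,
                                       seed = 1L) {
  if (k < 2L) stop("interaction order k must be at least 2")
  if (m < 50L) stop("need at least m = 50 instances")
  if (allele_freq <= 0 || allele_freq >= 1) stop("allele_freq must be in (0,1)")
  rng <- local_rng(seed)
  # genotype = number of minor alleles, Binomial(2, p) per Hardy-Weinberg
  G <- matrix(rbinom_rng(rng, m * k, 2L, allele_freq), nrow = m, ncol = k)
  parity <- rowSums(G %% 2) %% 2
  if (leak > 0) {
    flip <- runif_rng(rng, m) < leak
    parity[flip] <- (G[flip, 1] %% 2)
  }
  labels <- ifelse(parity == 1, "case", "control")
  kiedra_dataset(G, labels, paste0("snp_", seq_len(k)),
                 meta = list(generator = "epistasis_parity", k = k, m = m,
                             allele_freq = allele_freq, leak = leak,
                             seed = seed,
                             truth_relevant = seq_len(k),
                             truth_noisy = integer(0)))
}

#' Append irrelevant uniform-noise features
#'
#' Adds `n_noise` columns of i.i.d. Uniform(low, high) draws, named
#' `noise_1..`, leaving the original columns untouched. The ground-truth
#' relevant/noisy index sets are recorded in `meta` for discovery scoring.
#'
#' @param ds a [kiedra_dataset()].
#' @param n_noise number of noise columns to append (0 returns `ds` as is).
#' @param low,high uniform range; defaults 0 and 10.
#' @param seed integer seed.
#' @return The widened dataset.
#' @export
add_noise_features <- function(ds, n_noise, low = 0, high = 10, seed = 1L) {
  if (n_noise < 0L) stop("n_noise must be non-negative")
  if (n_noise == 0L) return(ds)
  if (low >= high) stop("noise range is empty: low >= high")
  rng <- local_rng(seed)
  m <- n_instances(ds)
  N <- matrix(runif_rng(rng, m * n_noise, low, high), nrow = m)
  colnames(N) <- paste0("noise_", seq_len(n_noise))
  feats <- cbind(ds$features, N)
  meta <- ds$meta
  l0 <- n_features(ds)
  meta$truth_relevant <- if (is.null(meta$truth_relevant)) seq_len(l0) else meta$truth_relevant
  meta$truth_noisy <- c(meta$truth_noisy, l0 + seq_len(n_noise))
  meta$noise <- list(n = n_noise, low = low, high = high, seed = seed)
  kiedra_dataset(feats, ds$labels, colnames(feats), meta = meta)
}

#' Small synthetic fixtures for kernel and search tests
#'
#' * `xor2`: two Bernoulli(0.5) binary features whose XOR is the class - no
#'   single feature is informative - plus `n_noise` Uniform(0,1) columns.
#' * `linear`: uniform features on (0,1); class is the sign of `f1 + f2 - 1`,
#'   linearly separable by construction.
#'
#' @param kind `"xor2"` or `"linear"`.
#' @param m number of instances, at least 40.
#' @param n_noise number of Uniform(0,1) noise columns appended.
#' @param seed integer seed.
#' @return A [kiedra_dataset()] with truth index sets in `meta`.
#' @export
make_toy_classification <- function(kind = c("xor2", "linear"), m = 400L,
                                    n_noise = 0L, seed = 1L) {
  kind <- match.arg(kind)
  if (m < 40L) stop("need at least m = 40 instances")
  rng <- local_rng(seed)
  if (kind == "xor2") {
    F2 <- matrix(rbinom_rng(rng, m * 2L, 1L, 0.5), nrow = m)
    labels <- ifelse(xor(F2[, 1] == 1, F2[, 2] == 1), "pos", "neg")
  } else {
    F2 <- matrix(runif_rng(rng, m * 2L), nrow = m)
    labels <- ifelse(F2[, 1] + F2[, 2] - 1 > 0, "pos", "neg")
  }
  colnames(F2) <- c("f1", "f2")
  ds <- kiedra_dataset(F2, labels, colnames(F2),
                       meta = list(generator = kind, seed = seed,
                                   truth_relevant = 1:2,
                                   truth_noisy = integer(0)))
  if (n_noise > 0L) {
    ds <- add_noise_features(ds, n_noise, low = 0, high = 1,
                             seed = seed + 1000L)
  }
  ds
}

#' Plug-in mutual information between the class and a feature subset
#'
#' Treats the selected columns as discrete (values taken verbatim) and
#' computes `I(class; X_S) = H(class) + H(X_S) - H(class, X_S)` in bits from
#' the empirical joint frequencies. Used to verify the no-lower-order-effects
#' property of generated epistasis problems.
#'
#' @param ds a [kiedra_dataset()] with discrete-valued columns in `cols`.
#' @param cols feature column indices forming the subset.
#' @return Mutual information in bits.
#' @export
class_mi <- function(ds, cols) {
  joint <- apply(ds$features[, cols, drop = FALSE], 1, paste, collapse = "|")
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  ent(ds$labels) + ent(joint) - ent(paste(ds$labels, joint, sep = "#"))
}
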