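#' Kernel and soft-margin classifier configuration
#'
#' The wrapper's classifier is a soft-margin support-vector machine with an
#' RBF kernel `exp(-sigma * sum_i w_i (x_i - z_i)^2)` or a polynomial kernel
#' `(sum_i w_i x_i z_i)^d`, where `w` are per-feature relevance weights.
#' Because both kernels are additive in the features, the weighted kernel on
#' `(x, z)` equals the unweighted kernel on sqrt(w)-scaled inputs, so any
#' standard solver serves as the weighted machine after rescaling the data.
#'
#' @param family `"rbf"` or `"poly"`.
#' @param sigma RBF width multiplier, > 0 (paper-style convention: larger
#'   sigma = narrower kernel). Default 10.
#' @param degree polynomial degree, >= 1.
#' @param C soft-margin regularization, > 0. Default 100.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(family = c("rbf", "poly"), sigma = 10, degree = 2,
                        C = 100) {
  family <- match.arg(family)
  if (family == "rbf" && sigma <= 0) stop("sigma must be positive")
  if (family == "poly" && degree < 1) stop("degree must be at least 1")
  if (C <= 0) stop("C must be positive")
  structure(list(family = family, sigma = sigma, degree = degree, C = C),
            class = "kernel_spec")
}

#' Weighted kernel evaluation
#'
#' Direct evaluation of the weighted RBF or polynomial kernel; mainly used to
#' verify the sqrt-scaling equivalence against [scale_dataset()].
#'
#' @param x,z numeric vectors of equal length.
#' @param w weights in `[0, 1]` per dimension.
#' @param spec a [kernel_spec()].
#' @return The kernel value.
#' @export
weighted_kernel_value <- function(x, z, w, spec) {
  if (length(x) != length(z) || length(x) != length(w)) {
    stop("x, z and w must have equal length")
  }
  if (spec$family == "rbf") {
    exp(-spec$sigma * sum(w * (x - z)^2))
  } else {
    sum(w * x * z)^spec$degree
  }
}

#' Rescale a dataset by the square roots of relevance weights
#'
#' Multiplies feature column `i` by `sqrt(w_i)`. For binary weights this
#' zeroes deselected columns and leaves selected ones untouched; for any `w`
#' the unweighted kernel on the scaled data equals the weighted kernel on the
#' original data.
#'
#' @param ds a [kiedra_dataset()].
#' @param w non-negative weight vector of length `l`.
#' @return The rescaled dataset.
#' @export
scale_dataset <- function(ds, w) {
  if (length(w) != n_features(ds)) stop("weight length != number of features")
  if (any(w < 0)) stop("negative weights are not allowed")
  out <- ds
  out$features <- sweep(ds$features, 2, sqrt(w), "*")
  out
}

#' Deterministic stratified CV fold assignment
#'
#' Assigns each instance a fold id in `1..folds`, keeping classes balanced
#' across folds. When some class has fewer instances than `folds`, the fold
#' count is reduced with a warning.
#'
#' @param labels factor of class labels.
#' @param folds requested number of folds, >= 2.
#' @param seed integer seed.
#' @return Integer vector of fold ids, with `n_folds` attribute.
#' @export
make_folds <- function(labels, folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds")
  min_class <- min(table(labels))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning("reduced CV folds to ", folds,
            ": smallest class has only ", min_class, " instances")
  }
  rng <- local_rng(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample_int(rng, length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  attr(fold, "n_folds") <- folds
  fold
}

#' Wrapper fitness: cross-validated accuracy of the weighted-kernel SVM
#'
#' The candidate's bits rescale the dataset (scaling equivalence), then a
#' stratified k-fold cross-validation of a soft-margin SVM with the
#' unweighted kernel measures the mean fold accuracy. All-zero candidates
#' short-circuit to the majority-class rate without training. Identical
#' (candidate, fold partition) pairs hit the cache: resampled duplicates are
#' frequent late in convergence and retraining them is waste.
#'
#' @param ds a preprocessed [kiedra_dataset()].
#' @param bits 0/1 relevance vector of length `l` (or any weights in `[0,1]`).
#' @param spec a [kernel_spec()].
#' @param folds number of CV folds, default 5.
#' @param seed seed for the fold partition (ignored when `fold_id` is given).
#' @param cache optional environment used as a fitness cache.
#' @param fold_id optional precomputed fold assignment from [make_folds()],
#'   letting all candidates of a run share one partition so comparisons are
#'   paired.
#' @return A `fitness_record`: list with `bits`, `cv_accuracy`, `fold_count`,
#'   `cached`.
#' @export
evaluate_candidate <- function(ds, bits, spec = kernel_spec(), folds = 5L,
                               seed = 1L, cache = NULL, fold_id = NULL) {
  l <- n_features(ds)
  if (length(bits) != l) stop("candidate length != number of features")
  key <- paste(bits, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) {
    rec <- cache[[key]]
    rec$cached <- TRUE
    return(rec)
  }
  if (is.null(fold_id)) fold_id <- make_folds(ds$labels, folds, seed)
  nf <- attr(fold_id, "n_folds")
  if (all(bits == 0)) {
    acc <- max(table(ds$labels)) / length(ds$labels)
  } else {
    Xs <- ds$features * rep(sqrt(bits), each = nrow(ds$features))
    y0 <- as.integer(ds$labels) - 1L
    acc <- .cv_svm_accuracy_cpp(Xs, y0, fold_id - 1L,
                                nclass = length(levels(ds$labels)),
                                nfold = nf,
                                family = if (spec$family == "rbf") 0L else 1L,
                                sigma = spec$sigma, degree = spec$degree,
                                C = spec$C, tol = 1e-3,
                                max_iter = 100000L)
  }
  rec <- structure(list(bits = bits, cv_accuracy = acc, fold_count = nf,
                        cached = FALSE),
                   class = "fitness_record")
  if (!is.null(cache)) cache[[key]] <- rec
  rec
}

#' Held-out accuracy of the SVM trained on the full training split
#'
#' Rescales both splits by the candidate's bits, trains on the whole training
#' split and reports plain accuracy on the test split. This is the number the
#' repetition protocols filter on (the "accuracy floor").
#'
#' @param train,test [kiedra_dataset()] pair sharing features and classes.
#' @param bits 0/1 relevance vector.
#' @param spec a [kernel_spec()].
#' @return Accuracy in `[0, 1]`.
#' @export
holdout_accuracy <- function(train, test, bits, spec = kernel_spec()) {
  if (n_features(train) != n_features(test)) stop("train/test feature mismatch")
  if (!identical(levels(train$labels), levels(test$labels))) {
    stop("train/test class sets differ")
  }
  if (all(bits == 0)) {
    maj <- names(which.max(table(train$labels)))
    return(mean(as.character(test$labels) == maj))
  }
  sb <- rep(sqrt(bits), each = nrow(train$features))
  Xtr <- train$features * sb
  Xte <- test$features * rep(sqrt(bits), each = nrow(test$features))
  .svm_holdout_accuracy_cpp(Xtr, as.integer(train$labels) - 1L,
                            Xte, as.integer(test$labels) - 1L,
                            nclass = length(levels(train$labels)),
                            family = if (spec$family == "rbf") 0L else 1L,
                            sigma = spec$sigma, degree = spec$degree,
                            C = spec$C, tol = 1e-3, max_iter = 100000L)
}
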