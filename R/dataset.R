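#' Tabular classification dataset
#'
#' Lightweight container for a feature matrix, a class label per instance and
#' bookkeeping metadata. This is the object `D` that candidate relevance
#' vectors rescale before classifier training; all preprocessing operations
#' ([impute_missing()], [normalize_minmax()], [split_train_test()]) take and
#' return it.
#'
#' @param features numeric matrix, m instances by l features. `NA` marks a
#'   missing entry.
#' @param labels vector of class symbols, one per row of `features`. Coerced
#'   to factor.
#' @param feature_names optional character vector of l unique names; defaults
#'   to the matrix column names, or `f1..fl`.
#' @param meta named list of provenance notes (source path, generator spec,
#'   seeds, ground-truth index sets for synthetic data).
#'
#' @return An object of class `kiedra_dataset` with fields `features`,
#'   `labels`, `feature_names`, `class_values`, `meta`.
#' @export
kiedra_dataset <- function(features, labels, feature_names = NULL, meta = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 2L) stop("a dataset needs at least 2 instances")
  if (ncol(features) < 1L) stop("a dataset needs at least 1 feature")
  if (length(labels) != nrow(features)) {
    stop("number of labels (", length(labels), ") != number of rows (",
         nrow(features), ")")
  }
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  feature_names <- as.character(feature_names)
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (length(feature_names) != ncol(features)) {
    stop("feature_names length != number of feature columns")
  }
  colnames(features) <- feature_names
  labels <- factor(labels)
  structure(
    list(features = features, labels = labels, feature_names = feature_names,
         class_values = levels(labels), meta = meta),
    class = "kiedra_dataset"
  )
}

#' @export
print.kiedra_dataset <- function(x, ...) {
  cat("<kiedra_dataset> ", nrow(x$features), " instances x ",
      ncol(x$features), " features, ", length(x$class_values),
      " classes (", paste(utils::head(x$class_values, 5), collapse = ", "),
      ")\n", sep = "")
  nmiss <- sum(is.na(x$features))
  if (nmiss > 0) cat("  missing entries: ", nmiss, "\n", sep = "")
  if (length(x$meta)) cat("  meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.kiedra_dataset <- function(x) dim(x$features)

n_features <- function(ds) ncol(ds$features)
n_instances <- function(ds) nrow(ds$features)

#' Read a delimited table into a dataset
#'
#' Parses a header-row CSV/TSV, pulls one column out as the class label and
#' treats the rest as numeric features. Cells that are empty, `"?"` or `"NA"`
#' (the usual UCI dialects) are flagged missing.
#'
#' @param path file path to a delimited text file with a header row.
#' @param class_column column name or 1-based index holding the class labels.
#' @param delimiter field separator, default `","` (use `"\t"` for TSV).
#' @return A [kiedra_dataset()].
#' @export
load_table <- function(path, class_column = "class", delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "?", "NA"), strip.white = TRUE)
  if (is.numeric(class_column)) {
    if (class_column < 1 || class_column > ncol(raw)) {
      stop("class column index out of range: ", class_column)
    }
    cls_idx <- as.integer(class_column)
  } else {
    cls_idx <- match(class_column, names(raw))
    if (is.na(cls_idx)) stop("class column not found: ", class_column)
  }
  labels <- raw[[cls_idx]]
  if (anyNA(labels)) stop("missing values in the class column are not supported")
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: class column has fewer than 2 distinct values")
  }
  feat_raw <- raw[, -cls_idx, drop = FALSE]
  if (ncol(feat_raw) < 1L) stop("no feature columns besides the class column")
  features <- vapply(feat_raw, function(col) {
    suppressWarnings(as.numeric(col))  # unparseable cells become NA (missing)
  }, numeric(nrow(raw)))
  features <- matrix(features, nrow = nrow(raw),
                     dimnames = list(NULL, names(feat_raw)))
  kiedra_dataset(features, labels, names(feat_raw),
                 meta = list(source = path))
}

#' Write a dataset back to a delimited table
#'
#' Mirrors [load_table()]: features first, class column last (named `class`),
#' missing entries as empty cells, so preprocessed datasets round-trip.
#'
#' @param ds a [kiedra_dataset()].
#' @param path output file path.
#' @param delimiter field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_table <- function(ds, path, delimiter = ",") {
  df <- as.data.frame(ds$features)
  df$class <- as.character(ds$labels)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Fill in missing feature values
#'
#' `naive_bayes` follows the benchmark-preprocessing recipe: each feature with
#' holes is discretized into equal-width bins over its observed values and a
#' naive-Bayes classifier (trained on the complete co-observed rows, with the
#' other features also discretized) predicts the missing bin; the hole is
#' filled with that bin's midpoint. `mode_mean` uses the per-feature mode when
#' the feature looks categorical (fewer than 10 distinct observed values) and
#' the mean otherwise.
#'
#' @param ds a [kiedra_dataset()], possibly with `NA` entries.
#' @param method `"naive_bayes"` (default) or `"mode_mean"`.
#' @param bins number of equal-width bins for the naive-Bayes discretization.
#' @return The dataset with no missing entries.
#' @export
impute_missing <- function(ds, method = c("naive_bayes", "mode_mean"), bins = 5L) {
  method <- match.arg(method)
  X <- ds$features
  if (!anyNA(X)) return(ds)
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    stop("feature(s) missing in every row: ",
         paste(ds$feature_names[all_missing], collapse = ", "))
  }
  for (j in which(colSums(is.na(X)) > 0L)) {
    holes <- which(is.na(X[, j]))
    filled <- NA_real_
    if (method == "naive_bayes") {
      filled <- nb_impute_column(X, j, holes, bins)
      if (anyNA(filled)) {
        warning("naive_bayes imputation fell back to mode_mean for feature ",
                ds$feature_names[j], " (no complete co-observed rows)")
        filled <- NULL
      }
    }
    if (method == "mode_mean" || is.null(filled)) {
      filled <- rep(mode_mean_value(X[, j]), length(holes))
    }
    X[holes, j] <- filled
  }
  out <- ds
  out$features <- X
  out
}

mode_mean_value <- function(col) {
  obs <- col[!is.na(col)]
  if (length(unique(obs)) < 10L) {
    tab <- table(obs)
    as.numeric(names(tab)[which.max(tab)])  # ties: lowest value (table order)
  } else {
    mean(obs)
  }
}

# Predict the bin of feature j for rows `holes` with a naive-Bayes classifier
# over the other features, discretized into equal-width bins; returns the bin
# midpoints, or NA if no usable training rows exist.
nb_impute_column <- function(X, j, holes, bins) {
  obs <- !is.na(X[, j])
  others <- setdiff(seq_len(ncol(X)), j)
  cuts <- lapply(seq_len(ncol(X)), function(k) equal_width_cuts(X[, k], bins))
  disc <- vapply(seq_len(ncol(X)), function(k) bin_of(X[, k], cuts[[k]]),
                 integer(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X))
  y <- disc[obs, j]
  train <- disc[obs, others, drop = FALSE]
  if (nrow(train) == 0L) return(rep(NA_real_, length(holes)))
  classes <- sort(unique(y))
  prior <- vapply(classes, function(cl) sum(y == cl), numeric(1)) + 1
  # conditional tables with Laplace smoothing, per other-feature
  log_lik <- function(row) {
    vapply(seq_along(classes), function(ci) {
      cl <- classes[ci]
      lp <- log(prior[ci])
      for (fi in seq_along(others)) {
        b <- row[fi]
        if (is.na(b)) next
        sel <- y == cl & !is.na(train[, fi])
        cnt <- sum(train[sel, fi] == b, na.rm = TRUE)
        lp <- lp + log((cnt + 1) / (sum(sel) + bins))
      }
      lp
    }, numeric(1))
  }
  mids <- bin_midpoints(cuts[[j]])
  vapply(holes, function(r) {
    ll <- log_lik(disc[r, others])
    mids[classes[which.max(ll)]]
  }, numeric(1))
}

equal_width_cuts <- function(col, bins) {
  obs <- col[!is.na(col)]
  lo <- min(obs); hi <- max(obs)
  if (hi == lo) hi <- lo + 1  # constant feature: single effective bin
  seq(lo, hi, length.out = bins + 1L)
}

bin_of <- function(col, cuts) {
  b <- findInterval(col, cuts, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(b)
}

bin_midpoints <- function(cuts) {
  (cuts[-1] + cuts[-length(cuts)]) / 2
}

#' Min-max normalize every feature to [0, 1]
#'
#' Each feature is mapped by `(x - min) / (max - min)`; constant features map
#' to 0 everywhere. Requires a complete dataset (run [impute_missing()] first).
#'
#' @param ds a complete [kiedra_dataset()].
#' @return The normalized dataset.
#' @export
normalize_minmax <- function(ds) {
  X <- ds$features
  if (anyNA(X)) stop("dataset has missing entries; run impute_missing() first")
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  span[const] <- 1
  X <- sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
  X[, const] <- 0
  out <- ds
  out$features <- X
  out
}

#' Split a dataset into train and test parts
#'
#' Draws a seeded random partition of the rows; `train_fraction` of them
#' (rounded) go to training. Stratified splits (the default) keep per-class
#' proportions within one instance of exact proportionality.
#'
#' @param ds a [kiedra_dataset()] with at least 4 instances.
#' @param train_fraction fraction of rows assigned to training, in (0, 1).
#' @param seed integer seed; equal seeds give identical splits.
#' @param stratified keep class proportions (default `TRUE`); requires at
#'   least 2 instances per class.
#' @return A list with elements `train` and `test`, both `kiedra_dataset`.
#' @export
split_train_test <- function(ds, train_fraction = 0.5, seed = 1L,
                             stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  m <- n_instances(ds)
  if (m < 4L) stop("need at least 4 instances to split")
  n_train <- round(train_fraction * m)
  n_train <- max(1L, min(m - 1L, as.integer(n_train)))
  rng <- local_rng(seed)
  if (stratified) {
    cls_n <- table(ds$labels)
    if (any(cls_n < 2L)) {
      stop("stratified split needs at least 2 instances per class")
    }
    idx_by_class <- split(seq_len(m), ds$labels)
    # largest-remainder apportionment of n_train across classes
    quota <- n_train * as.numeric(cls_n) / m
    take <- floor(quota)
    rem <- n_train - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    take <- pmin(pmax(take, 1L), as.numeric(cls_n) - 1L)
    train_idx <- unlist(Map(function(idx, k) {
      idx[sample_int(rng, length(idx))][seq_len(k)]
    }, idx_by_class, take), use.names = FALSE)
  } else {
    train_idx <- sample_int(rng, m)[seq_len(n_train)]
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(m), train_idx)
  list(train = subset_rows(ds, train_idx), test = subset_rows(ds, test_idx))
}

subset_rows <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]  # levels preserved
  out
}

shuffle_rows <- function(ds, seed) {
  rng <- local_rng(seed)
  subset_rows(ds, sample_int(rng, n_instances(ds)))
}

# --- seeded RNG scoped away from the global stream ------------------------

# Evaluates expressions under a private RNG state so library calls do not
# perturb (or depend on) the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

sample_int <- function(rng, n) with_rng(rng, sample.int(n))
runif_rng <- function(rng, n, lo = 0, hi = 1) with_rng(rng, stats::runif(n, lo, hi))
rbinom_rng <- function(rng, n, size, prob) with_rng(rng, stats::rbinom(n, size, prob))
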