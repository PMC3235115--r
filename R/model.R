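# Nearest-neighbour classification, jackknife cross-validation and
# incremental feature selection.

#' Cosine-derived distance between two feature vectors
#'
#' `D(a, b) = 1 - <a, b> / (|a| |b|)`; 0 for identical directions,
#' 1 for orthogonal vectors, 2 for opposite directions.
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   non-zero entry.
#' @return Distance in `[0, 2]`.
#' @export
nna_distance <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("vector dimensions differ (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine distance is undefined for a zero vector", call. = FALSE)
  1 - sum(a * b) / (na * nb)
}

# Row norms with zero-norm guard: zero-norm rows are given similarity
# 0 (distance 1) to everything, so sparse one-hot subsets cannot
# produce undefined distances inside jackknife/IFS.
.safe_norms <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- Inf
  n
}

#' Predict labels with the nearest-neighbour rule
#'
#' Each query is assigned the label of the training sample at minimum
#' cosine distance; ties go to the lowest training-sample index.
#'
#' @param train A `feature_matrix` (or numeric matrix plus `labels`).
#' @param query Numeric vector or matrix of query rows.
#' @param labels Training labels when `train` is a plain matrix.
#' @return Character vector of predicted labels.
#' @export
nna_predict <- function(train, query, labels = NULL) {
  if (inherits(train, "feature_matrix")) {
    labels <- labels %||% train$labels
    train <- train$values
  }
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(train))
    stop(sprintf("query has %d features but training set has %d",
                 ncol(query), ncol(train)), call. = FALSE)
  sim <- tcrossprod(query / .safe_norms(query), train / .safe_norms(train))
  labels[max.col(sim, ties.method = "first")]
}

#' Jackknife (leave-one-out) evaluation of the nearest-neighbour rule
#'
#' Every sample is predicted by the classifier trained on all other
#' samples, restricted to `feature_subset`; the confusion counts are
#' accumulated over all samples.
#'
#' @param x A `feature_matrix` (or numeric matrix plus `labels`).
#' @param feature_subset Column indices to use (default: all).
#' @param labels Labels when `x` is a plain matrix.
#' @param positive Label counted as the positive class (default
#'   `"positive"`).
#' @return Object of class `confusion_counts`: list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
jackknife <- function(x, feature_subset = NULL, labels = NULL,
                      positive = "positive") {
  if (inherits(x, "feature_matrix")) {
    labels <- labels %||% x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  feature_subset <- feature_subset %||% seq_len(ncol(x))
  if (length(feature_subset) == 0L)
    stop("empty feature subset", call. = FALSE)
  xs <- x[, feature_subset, drop = FALSE]
  sim <- tcrossprod(xs / .safe_norms(xs))
  diag(sim) <- -Inf
  pred <- labels[max.col(sim, ties.method = "first")]
  confusion_counts(labels, pred, positive)
}

#' Build confusion counts from true and predicted labels
#' @param truth,pred Label vectors.
#' @param positive Positive-class label.
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(truth, pred, positive = "positive") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d\n", x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/total`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' If any factor under the square root is zero the MCC is reported as
#' 0; a zero Sn or Sp denominator likewise yields 0.
#'
#' @param counts `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / total
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  c(sensitivity = sn, specificity = sp, accuracy = acc, mcc = mcc)
}

#' Incremental feature selection over an mRMR ranking
#'
#' Evaluates the nearest-neighbour classifier under jackknife
#' cross-validation on growing prefixes of the ranked feature list
#' (sizes `1, 1 + stride, ...` up to all features) and records
#' Sn/Sp/Acc/MCC for each prefix. The similarity matrix is updated
#' incrementally as columns are appended, so the full sweep costs one
#' rank-one update per feature rather than a fresh evaluation.
#'
#' @param x A `feature_matrix` (or numeric matrix plus `labels`).
#' @param ranking `ranked_features` from [mrmr_rank()] (or an index
#'   permutation).
#' @param labels Labels when `x` is a plain matrix.
#' @param stride Evaluate every `stride`-th prefix size (default 1; the
#'   final prefix containing all features is always evaluated).
#' @param positive Positive-class label.
#' @return Object of class `ifs_table`: list with `records` (data.frame
#'   of k, TP, TN, FP, FN, sensitivity, specificity, accuracy, mcc) and
#'   `optimal_k` (smallest k attaining the maximum MCC).
#' @export
ifs <- function(x, ranking, labels = NULL, stride = 1L,
                positive = "positive") {
  if (inherits(x, "feature_matrix")) {
    labels <- labels %||% x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  ord <- if (inherits(ranking, "ranked_features")) ranking$order else ranking
  if (length(ord) != ncol(x) || anyDuplicated(ord) ||
      !all(sort(ord) == seq_len(ncol(x))))
    stop("ranking must be a complete permutation of the feature columns",
         call. = FALSE)
  xr <- x[, ord, drop = FALSE]
  n <- nrow(xr)
  p <- ncol(xr)
  ks <- unique(c(seq(1L, p, by = as.integer(stride)), p))
  gram <- matrix(0, n, n)
  norms2 <- numeric(n)
  prev <- 0L
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    block <- xr[, (prev + 1L):k, drop = FALSE]
    gram <- gram + tcrossprod(block)
    norms2 <- norms2 + rowSums(block^2)
    prev <- k
    nrm <- sqrt(norms2)
    nrm[nrm == 0] <- Inf
    sim <- gram / outer(nrm, nrm)
    diag(sim) <- -Inf
    pred <- labels[max.col(sim, ties.method = "first")]
    cc <- confusion_counts(labels, pred, positive)
    rows[[i]] <- data.frame(k = k, TP = cc$TP, TN = cc$TN, FP = cc$FP,
                            FN = cc$FN, t(compute_metrics(cc)))
  }
  records <- do.call(rbind, rows)
  optimal_k <- records$k[which.max(records$mcc)]
  structure(list(records = records, optimal_k = optimal_k,
                 order = ord),
            class = "ifs_table")
}

#' @export
print.ifs_table <- function(x, ...) {
  best <- x$records[x$records$k == x$optimal_k, ]
  cat(sprintf(
    "IFS over %d prefix sizes; optimal subset: %d features (MCC %.4f)\n",
    nrow(x$records), x$optimal_k, best$mcc))
  invisible(x)
}

#' Write an IFS table as TSV
#' @param x `ifs_table` object.
#' @param path Output path.
#' @export
write_ifs_table <- function(x, path) {
  utils::write.table(
    x$records[, c("k", "sensitivity", "specificity", "accuracy", "mcc")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Family- and site-wise composition of a feature subset
#'
#' @param schema Feature schema from [build_schema()].
#' @param subset Column indices of the selected features.
#' @return Object of class `feature_set_analysis`: list with
#'   `counts_by_family` (named over the 8 feature families) and
#'   `counts_by_site` (named over window sites).
#' @export
analyze_feature_set <- function(schema, subset) {
  if (anyDuplicated(subset))
    stop("duplicate indices in feature subset", call. = FALSE)
  if (length(subset) > 0 &&
      (min(subset) < 1L || max(subset) > nrow(schema)))
    stop("feature subset index out of schema range", call. = FALSE)
  sel <- schema[subset, , drop = FALSE]
  fam <- table(factor(sel$family, levels = FEATURE_FAMILIES))
  site <- table(factor(sel$site, levels = seq_len(max(schema$site))))
  structure(list(counts_by_family = stats::setNames(as.integer(fam),
                                                    names(fam)),
                 counts_by_site = stats::setNames(as.integer(site),
                                                  names(site)),
                 n = length(subset)),
            class = "feature_set_analysis")
}

#' @export
print.feature_set_analysis <- function(x, ...) {
  cat(sprintf("Feature subset of size %d\n", x$n))
  cat("By family:\n")
  print(x$counts_by_family)
  cat("By window site:\n")
  print(x$counts_by_site)
  invisible(x)
}

#' Write a feature-set analysis as TSV
#' @param x `feature_set_analysis` object.
#' @param path_family,path_site Output paths for the two count tables.
#' @export
write_feature_set_analysis <- function(x, path_family, path_site) {
  utils::write.table(
    data.frame(family = names(x$counts_by_family),
               count = x$counts_by_family),
    path_family, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(site = names(x$counts_by_site), count = x$counts_by_site),
    path_site, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_family)
}
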