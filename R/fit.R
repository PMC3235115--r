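# Top-level fitting interface: mRMR ranking + incremental feature
# selection wrapped as a classed model object.

#' Fit a pyroglutamate-site predictor
#'
#' Runs the full feature-selection pipeline on an encoded training set:
#' features are discretized and ranked by maximum-relevance
#' minimum-redundancy mutual information, then evaluated by jackknife
#' cross-validation of a cosine-distance nearest-neighbour classifier
#' on growing prefixes of the ranking (incremental feature selection).
#' The optimal feature subset is the smallest prefix attaining the
#' maximum Matthews correlation coefficient.
#'
#' @param x A `feature_matrix` from [encode_windows()] /
#'   [generate_matrix()], or a numeric samples x features matrix.
#' @param labels Class labels when `x` is a plain matrix.
#' @param rule [discretization_rule()] used for mutual-information
#'   estimation.
#' @param variant mRMR criterion form, `"mid"` or `"miq"`.
#' @param stride IFS prefix-size stride (default 1).
#' @param positive Positive-class label.
#' @return Object of class `pyrosite_fit` with components `ranking`
#'   (`ranked_features`), `ifs` (`ifs_table`), `optimal_k`,
#'   `optimal_features` (column indices), `metrics` (at the optimum),
#'   `train` (the training `feature_matrix`), and `schema` (if known).
#' @examples
#' sch <- build_schema(2)
#' fm <- generate_matrix(synthetic_spec(n_positive = 20, seed = 3,
#'                                      n_features = 30,
#'                                      informative_columns = 1:5))
#' fit <- pyrosite_fit(fm)
#' print(fit)
#' @export
pyrosite_fit <- function(x, labels = NULL, rule = discretization_rule(),
                         variant = c("mid", "miq"), stride = 1L,
                         positive = "positive") {
  variant <- match.arg(variant)
  if (!inherits(x, "feature_matrix")) {
    if (is.null(labels)) stop("labels required for a plain matrix",
                              call. = FALSE)
    x <- feature_matrix(x, labels)
  }
  ranking <- mrmr_rank(x, rule = rule, variant = variant)
  ifs_tab <- ifs(x, ranking, stride = stride, positive = positive)
  k <- ifs_tab$optimal_k
  best <- ifs_tab$records[ifs_tab$records$k == k, ]
  structure(list(
    ranking = ranking,
    ifs = ifs_tab,
    optimal_k = k,
    optimal_features = ranking$order[seq_len(k)],
    metrics = c(sensitivity = best$sensitivity,
                specificity = best$specificity,
                accuracy = best$accuracy, mcc = best$mcc),
    train = x,
    schema = x$schema,
    positive = positive,
    call = match.call()),
    class = "pyrosite_fit")
}

#' @export
print.pyrosite_fit <- function(x, ...) {
  cat("Pyroglutamate-site predictor (mRMR + IFS + nearest neighbour)\n")
  cat(sprintf("  training set: %d samples x %d features\n",
              nrow(x$train$values), ncol(x$train$values)))
  cat(sprintf("  optimal subset: %d features\n", x$optimal_k))
  cat(sprintf("  jackknife at optimum: Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f\n",
              x$metrics["sensitivity"], x$metrics["specificity"],
              x$metrics["accuracy"], x$metrics["mcc"]))
  invisible(x)
}

#' @export
summary.pyrosite_fit <- function(object, top = 10L, ...) {
  print(object)
  top <- min(top, object$optimal_k)
  cat(sprintf("\nTop %d ranked features:\n", top))
  idx <- object$ranking$order[seq_len(top)]
  print(data.frame(round = seq_len(top), feature = object$ranking$names[idx],
                   relevance = signif(object$ranking$relevance[idx], 4)))
  if (!is.null(object$schema)) {
    cat("\nOptimal-subset composition:\n")
    print(analyze_feature_set(object$schema, object$optimal_features))
  }
  invisible(object)
}

#' Plot the incremental-feature-selection curve
#'
#' MCC of the jackknifed nearest-neighbour classifier against the
#' number of top-ranked features used; the optimum is marked.
#'
#' @param x `pyrosite_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pyrosite_fit <- function(x, ...) {
  rec <- x$ifs$records
  graphics::plot(rec$k, rec$mcc, type = "l", xlab = "Number of features",
                 ylab = "MCC (jackknife)", ...)
  graphics::abline(v = x$optimal_k, lty = 2, col = "grey40")
  graphics::points(x$optimal_k, max(rec$mcc), pch = 19)
  invisible(x)
}

#' Predict modification-site labels for new feature vectors
#'
#' Applies the fitted nearest-neighbour rule using the optimal feature
#' subset selected by IFS.
#'
#' @param object `pyrosite_fit` object.
#' @param newdata Numeric matrix (or `feature_matrix`) with the same
#'   feature columns as the training data.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.pyrosite_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(object$train$values))
    stop(sprintf("newdata has %d features but the model was trained on %d",
                 ncol(newdata), ncol(object$train$values)), call. = FALSE)
  sub <- object$optimal_features
  nna_predict(object$train$values[, sub, drop = FALSE],
              newdata[, sub, drop = FALSE],
              labels = object$train$labels)
}
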