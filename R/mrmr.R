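# Maximum-relevance minimum-redundancy feature ranking with
# mutual-information scoring.

#' Mutual information between two discrete vectors (bits)
#'
#' Plug-in estimate over the empirical joint distribution:
#' `sum p(x,y) * log2( p(x,y) / (p(x) p(y)) )`.
#'
#' @param x,y Discrete vectors of equal length (any atomic type or
#'   factor; values are compared by equality).
#' @return Non-negative mutual information in bits.
#' @examples
#' x <- rep(0:1, 50)
#' mutual_information(x, x)  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("vector lengths differ (%d vs %d)", length(x), length(y)),
         call. = FALSE)
  tab <- table(x, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

# MI in bits from pre-coded integer vectors in 1..nx / 1..ny. Same
# plug-in estimate as mutual_information(), on a fast tabulation path.
.mi_coded <- function(xi, yi, nx, ny) {
  joint <- tabulate((xi - 1L) * ny + yi, nx * ny) / length(xi)
  dim(joint) <- c(ny, nx)
  px <- colSums(joint)
  py <- rowSums(joint)
  nz <- joint > 0
  e <- outer(py, px)
  sum(joint[nz] * log2(joint[nz] / e[nz]))
}

#' Discretization rule for mutual-information estimation
#'
#' @param scheme One of `"three-state-mean-sigma"` (default; values
#'   below `mean - k * sd` map to state 0, above `mean + k * sd` to
#'   state 2, the rest to state 1), `"equal-frequency"` (quantile
#'   bins), or `"none"` (values already categorical).
#' @param parameter Sigma multiplier `k` (default 1) or bin count for
#'   equal-frequency binning.
#' @return Object of class `discretization_rule`.
#' @export
discretization_rule <- function(scheme = c("three-state-mean-sigma",
                                           "equal-frequency", "none"),
                                parameter = NULL) {
  scheme <- match.arg(scheme)
  parameter <- parameter %||% switch(scheme,
                                     "three-state-mean-sigma" = 1,
                                     "equal-frequency" = 3,
                                     "none" = NA_real_)
  structure(list(scheme = scheme, parameter = parameter),
            class = "discretization_rule")
}

#' Discretize one feature column
#'
#' @param column Numeric vector of finite values.
#' @param rule A [discretization_rule()].
#' @return Integer category codes. Constant columns map to a single
#'   category.
#' @export
discretize <- function(column, rule = discretization_rule()) {
  switch(rule$scheme,
    "three-state-mean-sigma" = {
      mu <- mean(column)
      sdev <- stats::sd(column)
      if (!is.finite(sdev) || sdev == 0) return(rep(0L, length(column)))
      k <- rule$parameter
      ifelse(column <= mu - k * sdev, 0L,
             ifelse(column >= mu + k * sdev, 2L, 1L))
    },
    "equal-frequency" = {
      br <- unique(stats::quantile(column, probs = seq(0, 1,
                                   length.out = rule$parameter + 1)))
      if (length(br) <= 2L) return(rep(0L, length(column)))
      as.integer(cut(column, br, include.lowest = TRUE)) - 1L
    },
    "none" = as.integer(factor(column)) - 1L)
}

#' Rank features by maximum relevance, minimum redundancy
#'
#' Greedy forward selection over discretized feature columns. The first
#' feature maximizes relevance, the mutual information with the class
#' label; each later round selects the candidate maximizing
#' `MI(f, class) - mean(MI(f, already-selected))` (`variant = "mid"`,
#' the difference form) or the corresponding quotient
#' (`variant = "miq"`). Ties go to the lowest original column index.
#'
#' @param x A `feature_matrix`, or a numeric samples x features matrix.
#' @param labels Class labels (taken from `x` when it is a
#'   `feature_matrix`).
#' @param rule [discretization_rule()] applied per column before MI
#'   estimation.
#' @param variant `"mid"` (difference, default) or `"miq"` (quotient).
#' @return Object of class `ranked_features`: list with `order` (column
#'   indices, best first), `round_index` (per-feature selection round),
#'   `scores` (per-round criterion value), `relevance`, and `names`.
#' @export
mrmr_rank <- function(x, labels = NULL, rule = discretization_rule(),
                      variant = c("mid", "miq")) {
  variant <- match.arg(variant)
  if (inherits(x, "feature_matrix")) {
    labels <- labels %||% x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("class label vector is constant; relevance is undefined",
         call. = FALSE)
  p <- ncol(x)
  disc <- matrix(0L, nrow(x), p)
  ncat <- integer(p)
  for (j in seq_len(p)) {
    d <- discretize(x[, j], rule)
    disc[, j] <- as.integer(factor(d)) # recode to 1..ncat
    ncat[j] <- max(disc[, j])
  }
  yi <- as.integer(factor(labels))
  ny <- max(yi)
  relevance <- vapply(seq_len(p), function(j)
    .mi_coded(disc[, j], yi, ncat[j], ny), numeric(1))
  order_out <- integer(p)
  scores <- numeric(p)
  redsum <- numeric(p)
  remaining <- rep(TRUE, p)
  for (h in seq_len(p)) {
    crit <- if (h == 1L) relevance else switch(variant,
      mid = relevance - redsum / (h - 1L),
      miq = relevance / pmax(redsum / (h - 1L), .Machine$double.eps))
    crit[!remaining] <- -Inf
    s <- which.max(crit)  # first maximum = lowest index on ties
    order_out[h] <- s
    scores[h] <- crit[s]
    remaining[s] <- FALSE
    if (h < p) {
      for (j in which(remaining))
        redsum[j] <- redsum[j] +
          .mi_coded(disc[, j], disc[, s], ncat[j], ncat[s])
    }
  }
  round_index <- integer(p)
  round_index[order_out] <- seq_len(p)
  structure(list(order = order_out, round_index = round_index,
                 scores = scores, relevance = relevance,
                 names = colnames(x) %||% as.character(seq_len(p)),
                 variant = variant, rule = rule),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10L, ...) {
  cat(sprintf("mRMR feature ranking (%s): %d features\n",
              toupper(x$variant), length(x$order)))
  top <- utils::head(x$order, n)
  print(data.frame(round = seq_along(top), feature = x$names[top],
                   score = signif(x$scores[seq_along(top)], 4)))
  invisible(x)
}

#' Write an mRMR ranking as TSV
#' @param ranking `ranked_features` object.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(
    data.frame(round = seq_along(ranking$order),
               feature_index = ranking$order,
               feature = ranking$names[ranking$order],
               score = ranking$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
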