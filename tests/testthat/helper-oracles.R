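# Independent brute-force oracles used to cross-check the
# implementation, deliberately written with naive enumeration.

# Mutual information (bits) by direct double summation over the
# empirical joint distribution.
mi_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0)
      s <- s + pxy * log2(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  s
}

# Greedy mRMR (difference form) recomputing relevance and redundancy
# from scratch every round.
mrmr_oracle <- function(x, y) {
  p <- ncol(x)
  sel <- integer(0)
  rem <- seq_len(p)
  rel <- vapply(seq_len(p), function(j) mi_oracle(x[, j], y), numeric(1))
  for (h in seq_len(p)) {
    crit <- vapply(rem, function(j)
      if (h == 1) rel[j]
      else rel[j] - mean(vapply(sel, function(s)
        mi_oracle(x[, j], x[, s]), numeric(1))), numeric(1))
    best <- rem[which.max(crit)]
    sel <- c(sel, best)
    rem <- setdiff(rem, best)
  }
  sel
}

# Leave-one-out nearest-neighbour evaluation rebuilding the training
# set for every held-out sample.
jackknife_oracle <- function(x, lab) {
  pred <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- apply(x[-i, , drop = FALSE], 1,
               function(r) nna_distance(r, x[i, ]))
    pred[i] <- lab[-i][which.min(d)]
  }
  confusion_counts(lab, pred)
}

# Tiny deterministic protein set with annotated internal glutamines,
# used across the dataset tests. Sequences are long enough that every
# annotated site yields a distinct 21-mer.
toy_proteins <- function() {
  set.seed(404)
  n <- 12L
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(setdiff(AA_ALPHABET, "Q"), 60, TRUE)
    s[c(8, 20, 31, 45, 57)] <- "Q"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("P%02d", seq_len(n))
  ann <- data.frame(protein_id = rep(names(seqs)[1:4], each = 1),
                    position = c(8L, 20L, 31L, 45L),
                    residue = "Q", stringsAsFactors = FALSE)
  list(seqs = seqs, ann = ann)
}
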