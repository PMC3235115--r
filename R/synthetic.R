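# Synthetic fixtures: peptide windows, annotation tracks and feature
# matrices with planted informative structure, so every pipeline stage
# is testable without external sequence databases or predictors.

#' Specification for a synthetic dataset
#'
#' Defaults mirror the real training conditions: 333 positive windows,
#' a 1:5 positive:negative ratio and 21-residue windows. Planted-signal
#' matrices default to a 3-standard-deviation class separation on the
#' informative columns.
#'
#' @param n_positive Number of positive samples (default 333).
#' @param neg_ratio Negatives per positive (default 5).
#' @param flank Window flank (default 10).
#' @param informative_columns Indices of label-informative feature
#'   columns (default none).
#' @param effect_size Class mean separation on informative columns, in
#'   units of the column standard deviation (default 3).
#' @param seed Integer seed (default 1).
#' @param n_features Number of feature columns for schema-free
#'   matrices (default 200).
#' @param background Residue sampling weights for window generation
#'   (named over [AA_ALPHABET]; default uniform).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 333L, neg_ratio = 5L, flank = 10L,
                           informative_columns = integer(),
                           effect_size = 3, seed = 1L,
                           n_features = 200L, background = NULL) {
  stopifnot(effect_size >= 0, n_positive >= 1, neg_ratio >= 1)
  bg <- background %||% stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  structure(list(n_positive = as.integer(n_positive),
                 neg_ratio = as.integer(neg_ratio),
                 flank = as.integer(flank),
                 informative_columns = as.integer(informative_columns),
                 effect_size = effect_size, seed = as.integer(seed),
                 n_features = as.integer(n_features),
                 background = bg / sum(bg)),
            class = "synthetic_spec")
}

#' Generate synthetic peptide windows
#'
#' Draws unique full-width windows with a glutamine at the centre and
#' background-composition residues elsewhere, labelled positive or
#' negative in the spec's ratio.
#'
#' @param spec A [synthetic_spec()].
#' @return Window data.frame as produced by the dataset builders.
#' @export
generate_windows <- function(spec) {
  width <- 2L * spec$flank + 1L
  n <- spec$n_positive * (1L + spec$neg_ratio)
  with_seed(spec$seed, {
    seen <- character()
    while (length(seen) < n) {
      m <- matrix(sample(AA_ALPHABET, (n - length(seen)) * width, TRUE,
                         spec$background), ncol = width)
      m[, spec$flank + 1L] <- "Q"
      seen <- unique(c(seen, apply(m, 1, paste, collapse = "")))
    }
    res <- seen[seq_len(n)]
    .new_windows(sprintf("SYN%05d", seq_len(n)), spec$flank + 1L, res,
                 rep(c("positive", "negative"),
                     c(spec$n_positive, n - spec$n_positive)))
  })
}

#' Generate a feature matrix with planted informative columns
#'
#' Non-informative columns are label-independent unit-variance noise;
#' informative columns separate the class means by
#' `spec$effect_size` standard deviations. When a feature schema is
#' supplied, one-hot families (secondary structure, accessibility)
#' remain valid one-hot blocks, with class-dependent category
#' probabilities on informative blocks instead of mean shifts.
#'
#' @param spec A [synthetic_spec()].
#' @param schema Optional [build_schema()] result; without it a plain
#'   `spec$n_features`-column Gaussian matrix is generated.
#' @return A `feature_matrix`.
#' @export
generate_matrix <- function(spec, schema = NULL) {
  n <- spec$n_positive * (1L + spec$neg_ratio)
  lab <- rep(c("positive", "negative"),
             c(spec$n_positive, n - spec$n_positive))
  is_pos <- lab == "positive"
  with_seed(spec$seed, {
    if (is.null(schema)) {
      p <- spec$n_features
      if (length(spec$informative_columns) > 0 &&
          max(spec$informative_columns) > p)
        stop("informative column index exceeds n_features", call. = FALSE)
      vals <- matrix(stats::rnorm(n * p), n, p)
      vals[is_pos, spec$informative_columns] <-
        vals[is_pos, spec$informative_columns] + spec$effect_size
      colnames(vals) <- sprintf("F%03d", seq_len(p))
      return(feature_matrix(vals, lab))
    }
    p <- nrow(schema)
    if (length(spec$informative_columns) > 0 &&
        max(spec$informative_columns) > p)
      stop("informative column index exceeds schema size", call. = FALSE)
    vals <- matrix(0, n, p)
    onehot <- schema$family %in% c("SecondaryStructure", "Accessibility")
    cont <- which(!onehot)
    vals[, cont] <- stats::rnorm(n * length(cont))
    inf_cont <- intersect(spec$informative_columns, cont)
    vals[is_pos, inf_cont] <- vals[is_pos, inf_cont] + spec$effect_size
    # one-hot blocks: sample one category per site and sample
    blocks <- split(which(onehot),
                    paste(schema$site[onehot], schema$family[onehot]))
    shift <- spec$effect_size / (1 + spec$effect_size)  # probability tilt
    for (b in blocks) {
      k <- length(b)
      pr <- rep(1 / k, k)
      inf_b <- match(intersect(spec$informative_columns, b), b)
      draw_one <- function(prob, m)
        sample.int(k, m, TRUE, prob)
      if (length(inf_b) > 0) {
        pr_pos <- pr
        pr_pos[inf_b] <- pr_pos[inf_b] + shift
        pr_pos <- pr_pos / sum(pr_pos)
        cls <- integer(n)
        cls[is_pos] <- draw_one(pr_pos, sum(is_pos))
        cls[!is_pos] <- draw_one(pr, sum(!is_pos))
      } else cls <- draw_one(pr, n)
      vals[cbind(seq_len(n), b[cls])] <- 1
    }
    colnames(vals) <- schema$name
    feature_matrix(vals, lab, schema)
  })
}

#' Write a complete synthetic input fixture to disk
#'
#' Emits everything the extraction/encoding pipeline consumes: a FASTA
#' file of synthetic proteins, a site-annotation TSV marking the
#' positive glutamines, one PSI-BLAST-dialect ASCII PSSM file per
#' protein, and disorder / secondary-structure / accessibility track
#' TSVs. With `bias > 0`, PSSM scores on the upstream flank of positive
#' sites are shifted so the encoded dataset carries a label signal.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @param protein_length Length of each synthetic protein (default 60).
#' @param bias Label-dependent PSSM shift (score units; default 0).
#' @return Invisibly, a list of the paths written (`fasta`, `sites`,
#'   `pssm_dir`, `disorder`, `ss`, `acc`).
#' @export
generate_fixture <- function(spec, dir, protein_length = 60L, bias = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  n_sites_needed <- spec$n_positive * (1L + spec$neg_ratio)
  with_seed(spec$seed, {
    # residue background with boosted glutamine frequency so each
    # protein carries several candidate sites
    bg <- spec$background
    bg["Q"] <- bg["Q"] + 0.12
    bg <- bg / sum(bg)
    seqs <- character()
    q_sites <- list()
    while (sum(lengths(q_sites)) < ceiling(1.3 * n_sites_needed)) {
      s <- paste(sample(AA_ALPHABET, protein_length, TRUE, bg),
                 collapse = "")
      id <- sprintf("SYNP%04d", length(seqs) + 1L)
      seqs[id] <- s
      qs <- gregexpr("Q", s, fixed = TRUE)[[1]]
      q_sites[[id]] <- qs[qs >= 2L]
    }
    all_sites <- do.call(rbind, lapply(names(q_sites), function(id)
      if (length(q_sites[[id]]) > 0)
        data.frame(protein_id = id, position = as.integer(q_sites[[id]]),
                   residue = "Q", stringsAsFactors = FALSE)))
    pos_idx <- sample.int(nrow(all_sites), spec$n_positive)
    sites <- all_sites[sort(pos_idx), , drop = FALSE]
    # tracks and PSSM profiles per protein
    dis <- list(); sst <- list(); act <- list()
    for (id in names(seqs)) {
      L <- nchar(seqs[[id]])
      pm <- matrix(round(stats::rnorm(L * 20L, 0, 3)), L, 20L,
                   dimnames = list(strsplit(seqs[[id]], "")[[1]],
                                   AA_ALPHABET))
      if (bias > 0) {
        for (p in sites$position[sites$protein_id == id]) {
          up <- max(1L, p - spec$flank):max(1L, p - 1L)
          pm[up, ] <- pm[up, ] + round(bias)
        }
      }
      write_pssm(pm, file.path(pssm_dir, paste0(id, ".pssm")))
      dis[[id]] <- data.frame(protein_id = id, position = seq_len(L),
                              value = round(stats::runif(L), 4))
      sst[[id]] <- data.frame(protein_id = id, position = seq_len(L),
                              class = sample(SS_CLASSES, L, TRUE,
                                             c(0.35, 0.25, 0.40)))
      act[[id]] <- data.frame(protein_id = id, position = seq_len(L),
                              class = sample(ACC_CLASSES, L, TRUE,
                                             c(0.45, 0.55)))
    }
    fasta <- file.path(dir, "sequences.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
    paths <- list(fasta = fasta,
                  sites = file.path(dir, "sites.tsv"),
                  pssm_dir = pssm_dir,
                  disorder = file.path(dir, "disorder.tsv"),
                  ss = file.path(dir, "ss.tsv"),
                  acc = file.path(dir, "acc.tsv"))
    utils::write.table(sites, paths$sites, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (nm in c("disorder", "ss", "acc")) {
      tab <- do.call(rbind, switch(nm, disorder = dis, ss = sst, acc = act))
      utils::write.table(tab, paths[[nm]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    invisible(paths)
  })
}
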