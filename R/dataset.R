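# Peptide window dataset construction: positive windows around annotated
# modification sites, negatives sampled from unannotated glutamines.

#' Extract a fixed-width peptide window around a residue
#'
#' Cuts a `2 * flank + 1`-residue fragment centred on position `center`,
#' padding positions that fall outside the sequence with `"-"` so the
#' result always has the full width.
#'
#' @param sequence Amino-acid string (single element).
#' @param center 1-based residue index of the centre site.
#' @param flank Number of residues kept on each side (default 10, giving
#'   21-residue windows).
#' @param protein_id Optional id used in error messages.
#' @return A character scalar of length `2 * flank + 1`.
#' @examples
#' extract_window("MKTQAV", 4)   # "-------MKTQAV--------"
#' @export
extract_window <- function(sequence, center, flank = 10L, protein_id = "?") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (center < 1L || center > n)
    stop(sprintf("site position %d out of bounds for protein '%s' (length %d)",
                 center, protein_id, n), call. = FALSE)
  lo <- center - flank
  hi <- center + flank
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep(PAD_CHAR, left_pad), core, strrep(PAD_CHAR, right_pad))
}

.new_windows <- function(protein_id, center_pos, residues, label) {
  data.frame(protein_id = as.character(protein_id),
             center_pos = as.integer(center_pos),
             residues = as.character(residues),
             label = as.character(label),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a (possibly multi-record) amino-acid FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Read modification-site annotations from TSV
#'
#' Expects columns `protein_id`, `position`, `residue` (tab-separated,
#' with header). Positions are 1-based.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the three columns plus `is_internal`.
#' @param min_internal_pos Smallest position counted as internal
#'   (default 2: everything but the initiator residue).
#' @export
read_sites <- function(path, min_internal_pos = 2L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$position <- as.integer(df$position)
  df$is_internal <- df$position >= min_internal_pos
  df
}

.validate_sites <- function(sequences, annotations) {
  missing <- setdiff(unique(annotations$protein_id), names(sequences))
  if (length(missing) > 0L)
    stop("annotations reference protein(s) absent from the sequence set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  at <- substr(sequences[annotations$protein_id],
               annotations$position, annotations$position)
  bad <- which(at != annotations$residue)
  if (length(bad) > 0L)
    stop(sprintf(
      "annotation residue mismatch at %s:%d (annotated '%s', sequence '%s')",
      annotations$protein_id[bad[1]], annotations$position[bad[1]],
      annotations$residue[bad[1]], at[bad[1]]), call. = FALSE)
  invisible(annotations)
}

#' Build the positive window set from site annotations
#'
#' Extracts one window per internal annotated site and removes exact
#' duplicate fragments (first occurrence in input order is kept).
#'
#' @param sequences Named character vector of protein sequences.
#' @param annotations Data.frame with `protein_id`, `position`,
#'   `residue` columns (see [read_sites()]).
#' @param flank Residues on each side of the site (default 10).
#' @param min_internal_pos Sites at smaller positions are dropped as
#'   N-terminal (default 2).
#' @return Window data.frame (`protein_id`, `center_pos`, `residues`,
#'   `label`) with all labels `"positive"`.
#' @export
build_positive_set <- function(sequences, annotations, flank = 10L,
                               min_internal_pos = 2L) {
  if (nrow(annotations) == 0L)
    return(.new_windows(character(), integer(), character(), character()))
  .validate_sites(sequences, annotations)
  ann <- annotations[annotations$position >= min_internal_pos, , drop = FALSE]
  res <- mapply(function(id, pos)
    extract_window(sequences[[id]], pos, flank, id),
    ann$protein_id, ann$position)
  keep <- !duplicated(res)
  .new_windows(ann$protein_id[keep], ann$position[keep], res[keep], "positive")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample the negative window set
#'
#' Candidate negatives are all internal occurrences of `target_residue`
#' whose position is not an annotated positive site. Candidate windows
#' identical to any positive fragment, or to an earlier candidate, are
#' removed before `ratio * n_positive` windows are drawn uniformly
#' without replacement.
#'
#' @param sequences Named character vector of protein sequences.
#' @param positive_windows Output of [build_positive_set()].
#' @param target_residue Candidate centre residue (default `"Q"`).
#' @param ratio Negative:positive ratio (default 5).
#' @param seed Integer seed making the draw reproducible.
#' @param flank,min_internal_pos As in [build_positive_set()].
#' @return Window data.frame with all labels `"negative"` and attribute
#'   `seed` recording the seed used.
#' @export
build_negative_set <- function(sequences, positive_windows,
                               target_residue = "Q", ratio = 5L, seed = 1L,
                               flank = 10L, min_internal_pos = 2L) {
  pos_key <- paste(positive_windows$protein_id, positive_windows$center_pos)
  cand <- do.call(rbind, lapply(names(sequences), function(id) {
    hits <- gregexpr(target_residue, sequences[[id]], fixed = TRUE)[[1]]
    hits <- hits[hits >= min_internal_pos]
    if (length(hits) == 0L || hits[1] == -1L) return(NULL)
    data.frame(protein_id = id, center_pos = as.integer(hits),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) cand <- data.frame(protein_id = character(),
                                        center_pos = integer())
  cand <- cand[!(paste(cand$protein_id, cand$center_pos) %in% pos_key), ,
               drop = FALSE]
  res <- mapply(function(id, pos)
    extract_window(sequences[[id]], pos, flank, id),
    cand$protein_id, cand$center_pos)
  if (length(res) == 0L) res <- character()
  keep <- !duplicated(res) & !(res %in% positive_windows$residues)
  cand <- cand[keep, , drop = FALSE]
  res <- res[keep]
  n_req <- as.integer(ratio) * nrow(positive_windows)
  if (length(res) < n_req)
    stop(sprintf(
      "negative candidate pool (%d windows) smaller than requested sample (%d)",
      length(res), n_req), call. = FALSE)
  idx <- with_seed(seed, sample.int(length(res), n_req))
  idx <- sort(idx)
  out <- .new_windows(cand$protein_id[idx], cand$center_pos[idx],
                      res[idx], "negative")
  attr(out, "seed") <- seed
  out
}

#' Assemble the full labelled dataset
#'
#' @param positive_windows,negative_windows Outputs of
#'   [build_positive_set()] and [build_negative_set()].
#' @return Single window data.frame, positives first.
#' @export
bind_windows <- function(positive_windows, negative_windows) {
  rbind(positive_windows, negative_windows)
}

#' Write / read a window table as TSV
#' @param windows Window data.frame.
#' @param path Output (input) path.
#' @export
write_windows <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$center_pos <- as.integer(df$center_pos)
  df
}
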