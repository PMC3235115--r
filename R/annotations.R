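# Per-residue annotation tracks: PSI-BLAST PSSM profiles, disorder
# scores, secondary-structure and solvent-accessibility calls.

SS_CLASSES <- c("helix", "strand", "other")
ACC_CLASSES <- c("buried", "exposed")

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the ASCII matrix written by PSI-BLAST's `-Q` option: a header
#' line naming the 20 amino-acid columns followed by one row per
#' residue. The first 20 numeric columns (the log-odds block) are kept;
#' columns are reordered to [AA_ALPHABET].
#'
#' @param path Path to the profile file.
#' @return Numeric matrix, one row per residue of the protein, 20
#'   columns named by [AA_ALPHABET]. Rownames hold the residue letters.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty PSSM file: ", path, call. = FALSE)
  # header: the first line whose tokens start with >= 20 single letters
  header_i <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20L && all(grepl("^[A-Z]$", tok[1:20]))) {
      header_i <- i
      break
    }
  }
  if (is.na(header_i))
    stop("no PSSM column header found in ", path, call. = FALSE)
  alphabet <- strsplit(trimws(lines[header_i]), "\\s+")[[1]][1:20]
  rows <- list()
  res <- character()
  for (i in seq(header_i + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) break  # footer (K, Lambda, ...)
    if (length(tok) < 22L)
      stop(sprintf("malformed PSSM row at line %d of %s: expected 20 score columns, found %d",
                   i, path, max(0L, length(tok) - 2L)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals))
      stop(sprintf("non-numeric PSSM score at line %d of %s", i, path),
           call. = FALSE)
    rows[[length(rows) + 1L]] <- vals
    res <- c(res, tok[2])
  }
  if (length(rows) == 0L)
    stop("PSSM file has a header but no residue rows: ", path, call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- alphabet
  m <- m[, AA_ALPHABET, drop = FALSE]
  rownames(m) <- res
  m
}

#' Write a PSSM matrix in the PSI-BLAST ASCII dialect
#'
#' @param pssm Matrix as returned by [read_pssm()].
#' @param path Output path.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("     ", paste(sprintf("%3s", colnames(pssm)),
                                   collapse = " ")), con)
  res <- rownames(pssm) %||% rep("X", nrow(pssm))
  for (i in seq_len(nrow(pssm)))
    writeLines(paste0(sprintf("%4d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(pssm[i, ])),
                            collapse = " ")), con)
  invisible(path)
}

#' Read a per-residue annotation track from TSV
#'
#' Expects columns `protein_id`, `position`, `value` (numeric tracks
#' such as disorder) or `protein_id`, `position`, `class` (categorical
#' tracks such as secondary structure or accessibility).
#'
#' @param path Path to the TSV file.
#' @return Data.frame with the columns present in the file.
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "position") %in% names(df)))
    stop("track file must have protein_id and position columns", call. = FALSE)
  df$position <- as.integer(df$position)
  df
}

.track_lookup <- function(track, col) {
  stats::setNames(track[[col]], paste(track$protein_id, track$position))
}

#' Assemble per-window residue profiles from per-protein tracks
#'
#' For each window, collects the PSSM row, disorder score and SS/ACC
#' class of every non-pad position; pad positions are `NA`.
#'
#' @param windows Window data.frame ([build_positive_set()] etc.).
#' @param pssms Named list (by protein id) of PSSM matrices from
#'   [read_pssm()].
#' @param disorder,ss,acc Track data.frames from [read_track()]
#'   (`value` column for disorder, `class` for ss/acc).
#' @return A list with one profile per window; each profile is a list
#'   with elements `pssm` (width x 20 matrix), `disorder`, `ss`, `acc`.
#' @export
profiles_from_tracks <- function(windows, pssms, disorder, ss, acc) {
  width <- nchar(windows$residues[1])
  flank <- (width - 1L) %/% 2L
  dis_map <- .track_lookup(disorder, "value")
  ss_map <- .track_lookup(ss, "class")
  acc_map <- .track_lookup(acc, "class")
  lapply(seq_len(nrow(windows)), function(i) {
    id <- windows$protein_id[i]
    if (is.null(pssms[[id]]))
      stop("no PSSM profile available for protein '", id, "'", call. = FALSE)
    positions <- windows$center_pos[i] + seq(-flank, flank)
    pad <- strsplit(windows$residues[i], "")[[1]] == PAD_CHAR
    pm <- matrix(NA_real_, width, 20L, dimnames = list(NULL, AA_ALPHABET))
    pm[!pad, ] <- pssms[[id]][positions[!pad], , drop = FALSE]
    key <- paste(id, positions)
    list(pssm = pm,
         disorder = ifelse(pad, NA_real_, unname(dis_map[key])),
         ss = ifelse(pad, NA_character_, unname(ss_map[key])),
         acc = ifelse(pad, NA_character_, unname(acc_map[key])))
  })
}

#' Synthesize per-window residue profiles
#'
#' Draws deterministic pseudo-profiles for a set of windows: integer
#' PSSM rows, disorder scores in [0, 1], and categorical SS/ACC calls.
#' With `bias > 0`, positive-labelled windows get their PSSM scores at
#' `informative_sites` shifted upward and their SS distribution tilted,
#' planting a detectable label signal; with `bias = 0` profiles are
#' label-independent.
#'
#' @param windows Window data.frame.
#' @param seed Integer seed.
#' @param bias Mean PSSM shift (score units) applied at
#'   `informative_sites` of positive windows (default 0).
#' @param informative_sites Window sites (1-based) receiving the bias
#'   (default the upstream flank).
#' @return List of per-window profiles (see [profiles_from_tracks()]).
#' @export
synthesize_profiles <- function(windows, seed = 1L, bias = 0,
                                informative_sites = NULL) {
  width <- nchar(windows$residues[1])
  if (is.null(informative_sites))
    informative_sites <- seq_len((width - 1L) %/% 2L)
  with_seed(seed, lapply(seq_len(nrow(windows)), function(i) {
    pad <- strsplit(windows$residues[i], "")[[1]] == PAD_CHAR
    pos <- identical(windows$label[i], "positive")
    pm <- matrix(round(stats::rnorm(width * 20L, 0, 3)), width, 20L,
                 dimnames = list(NULL, AA_ALPHABET))
    if (bias > 0 && pos)
      pm[informative_sites, ] <- pm[informative_sites, ] + round(bias)
    pm[pad, ] <- NA_real_
    ss_prob <- if (bias > 0 && pos) c(0.15, 0.10, 0.75) else c(0.35, 0.25, 0.40)
    list(pssm = pm,
         disorder = ifelse(pad, NA_real_, stats::runif(width)),
         ss = ifelse(pad, NA_character_,
                     sample(SS_CLASSES, width, TRUE, ss_prob)),
         acc = ifelse(pad, NA_character_,
                      sample(ACC_CLASSES, width, TRUE, c(0.45, 0.55))))
  }))
}
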