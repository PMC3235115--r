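# Encoding peptide windows into numeric feature vectors.

#' Side-chain carbon-count deviation over a window
#'
#' For each window position, the residue's side-chain carbon atom count
#' minus the mean count over the whole window. Pad positions (`"-"`)
#' enter the calculation with the mean side-chain carbon count of the
#' 20 amino acids. The 21 values of a window always sum to zero.
#'
#' @param window Window residue string (pads allowed).
#' @param tables Property tables from [load_property_tables()].
#' @return Numeric vector, one value per window position.
#' @export
carbon_deviation <- function(window, tables = load_property_tables()) {
  chars <- strsplit(window, "")[[1]]
  bad <- setdiff(chars, c(AA_ALPHABET, PAD_CHAR))
  if (length(bad) > 0L)
    stop("unknown residue letter(s) in window: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  counts <- ifelse(chars == PAD_CHAR, tables$mean_carbons,
                   unname(tables$side_chain_carbons[chars]))
  counts - mean(counts)
}

# Encode one window given its residue profile. Pad positions contribute
# zero to every feature except the carbon deviation, which uses the
# mean-count rule.
encode_window <- function(residues, profile, tables, schema) {
  width <- max(schema$site)
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) != width)
    stop(sprintf("window has %d residues but schema expects %d",
                 length(chars), width), call. = FALSE)
  if (nrow(profile$pssm) != width)
    stop(sprintf("profile has %d rows but window has %d residues",
                 nrow(profile$pssm), width), call. = FALSE)
  pad <- chars == PAD_CHAR
  carbdev <- carbon_deviation(residues, tables)
  out <- numeric(nrow(schema))
  for (s in seq_len(width)) {
    rows <- which(schema$site == s)
    sub <- schema[rows, ]
    v <- numeric(length(rows))
    if (!pad[s]) {
      r <- chars[s]
      v[sub$family == "PSSM"] <- profile$pssm[s, sub$subname[sub$family == "PSSM"]]
      if (any(sub$family == "AAFactor"))
        v[sub$family == "AAFactor"] <-
          tables$aa_factors[r, sub$subname[sub$family == "AAFactor"]]
      v[sub$family == "Disorder"] <- profile$disorder[s]
      v[sub$family == "SecondaryStructure"] <-
        as.numeric(tolower(sub$subname[sub$family == "SecondaryStructure"]) ==
                     profile$ss[s])
      v[sub$family == "Accessibility"] <-
        as.numeric(tolower(sub$subname[sub$family == "Accessibility"]) ==
                     profile$acc[s])
      if (any(sub$family == "InterfaceSurface"))
        v[sub$family == "InterfaceSurface"] <-
          c(tables$interface_propensity[[r]], tables$surface_propensity[[r]])
      if (any(sub$family == "GainLoss"))
        v[sub$family == "GainLoss"] <- tables$gain_loss[[r]]
    }
    v[sub$family == "CarbonDeviation"] <- carbdev[s]
    out[rows] <- v
  }
  out
}

#' Encode a set of windows into a feature matrix
#'
#' @param windows Window data.frame.
#' @param profiles Per-window residue profiles
#'   ([profiles_from_tracks()] or [synthesize_profiles()]).
#' @param tables Property tables from [load_property_tables()].
#' @param schema Feature schema from [build_schema()].
#' @return Object of class `feature_matrix`: a list with `values`
#'   (samples x features numeric matrix, columns named by the schema),
#'   `labels` (character), `schema`, and `sample_ids`.
#' @export
encode_windows <- function(windows, profiles,
                           tables = load_property_tables(),
                           schema = build_schema()) {
  if (length(profiles) != nrow(windows))
    stop(sprintf("%d profiles supplied for %d windows",
                 length(profiles), nrow(windows)), call. = FALSE)
  vals <- t(vapply(seq_len(nrow(windows)), function(i)
    encode_window(windows$residues[i], profiles[[i]], tables, schema),
    numeric(nrow(schema))))
  colnames(vals) <- schema$name
  feature_matrix(vals, windows$label, schema,
                 paste(windows$protein_id, windows$center_pos, sep = ":"))
}

#' Construct a feature matrix container
#'
#' @param values Numeric samples x features matrix.
#' @param labels Per-sample labels (`"positive"` / `"negative"` for
#'   real datasets; any two-level coding is accepted).
#' @param schema Optional [build_schema()] result describing columns.
#' @param sample_ids Optional per-sample identifiers.
#' @return `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels, schema = NULL,
                           sample_ids = NULL) {
  values <- as.matrix(values)
  if (length(labels) != nrow(values))
    stop("labels length does not match sample count", call. = FALSE)
  if (!is.null(schema) && nrow(schema) != ncol(values))
    stop("schema length does not match feature count", call. = FALSE)
  if (anyNA(values))
    stop("feature matrix contains missing values", call. = FALSE)
  structure(list(values = values, labels = as.character(labels),
                 schema = schema,
                 sample_ids = sample_ids %||% as.character(seq_len(nrow(values)))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$labels), names(table(x$labels))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read a feature matrix as TSV with a JSON sidecar
#'
#' The TSV holds one header row of schema names, a `label` column and a
#' `sample_id` column; the sidecar (`<path>.meta.json`) records the
#' flank and the carbon-deviation sign convention.
#'
#' @param x `feature_matrix` object.
#' @param path Output (input) TSV path.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(sample_id = x$sample_ids, label = x$labels,
                   x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(flank = if (!is.null(x$schema)) attr(x$schema, "flank") else NA,
               carbon_deviation_sign = "residue_minus_window_mean",
               n_samples = nrow(x$values), n_features = ncol(x$values))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  schema <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$flank) && !is.na(meta$flank)) {
      sch <- build_schema(meta$flank)
      if (nrow(sch) == ncol(df) - 2L) schema <- sch
    }
  }
  feature_matrix(as.matrix(df[, -(1:2), drop = FALSE]), df$label, schema,
                 df$sample_id)
}
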