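# End-to-end pipeline: extract -> encode -> rank -> IFS -> analyze,
# with resolved-config provenance written next to the outputs.

.default_config <- function() {
  list(flank = 10L, neg_ratio = 5L, seed = 1L,
       discretization = "three-state-mean-sigma",
       discretization_parameter = 1,
       mrmr_variant = "mid", stride = 1L,
       fasta = NULL, sites = NULL, pssm_dir = NULL,
       disorder = NULL, ss = NULL, acc = NULL,
       out_dir = ".")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(.default_config(), cfg)
}

.stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (!quiet)
    message(sprintf("[pyrosite] stage %-8s done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full prediction pipeline
#'
#' Extracts positive and negative peptide windows from the configured
#' FASTA/site inputs, encodes them against the PSSM and structural
#' annotation tracks, ranks features by mRMR, runs incremental feature
#' selection under jackknife cross-validation, and writes the window
#' table, feature matrix, ranking, IFS table, feature-set analysis and
#' the resolved configuration (with an md5 provenance hash) into
#' `config$out_dir`.
#'
#' @param config Config list (see [read_config()]) or path to a
#'   YAML/JSON config file. Required entries: `fasta`, `sites`,
#'   `pssm_dir` (one `<protein_id>.pssm` file per protein), `disorder`,
#'   `ss`, `acc`, `out_dir`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the fitted model and the paths of all
#'   artifacts written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(.default_config(), config)
  for (f in c("fasta", "sites", "pssm_dir", "disorder", "ss", "acc"))
    if (is.null(config[[f]]))
      stop("config entry '", f, "' is required", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  windows <- .stage("extract", quiet, {
    seqs <- read_fasta(config$fasta)
    sites <- read_sites(config$sites)
    pos <- build_positive_set(seqs, sites, flank = config$flank)
    neg <- build_negative_set(seqs, pos, ratio = config$neg_ratio,
                              seed = config$seed, flank = config$flank)
    bind_windows(pos, neg)
  })
  paths <- list(windows = file.path(config$out_dir, "windows.tsv"))
  write_windows(windows, paths$windows)

  fm <- .stage("encode", quiet, {
    ids <- unique(windows$protein_id)
    pssm_files <- file.path(config$pssm_dir, paste0(ids, ".pssm"))
    absent <- ids[!file.exists(pssm_files)]
    if (length(absent) > 0)
      stop("missing PSSM file for protein(s): ",
           paste(absent, collapse = ", "))
    pssms <- stats::setNames(lapply(pssm_files, read_pssm), ids)
    profiles <- profiles_from_tracks(windows, pssms,
                                     read_track(config$disorder),
                                     read_track(config$ss),
                                     read_track(config$acc))
    encode_windows(windows, profiles, schema = build_schema(config$flank))
  })
  paths$matrix <- file.path(config$out_dir, "matrix.tsv")
  write_feature_matrix(fm, paths$matrix)

  fit <- .stage("rank+ifs", quiet, pyrosite_fit(
    fm,
    rule = discretization_rule(config$discretization,
                               config$discretization_parameter),
    variant = config$mrmr_variant, stride = config$stride))
  paths$ranking <- file.path(config$out_dir, "ranking.tsv")
  write_ranking(fit$ranking, paths$ranking)
  paths$ifs <- file.path(config$out_dir, "ifs.tsv")
  write_ifs_table(fit$ifs, paths$ifs)

  an <- .stage("analyze", quiet,
               analyze_feature_set(fm$schema, fit$optimal_features))
  paths$analysis_family <- file.path(config$out_dir, "analysis_family.tsv")
  paths$analysis_site <- file.path(config$out_dir, "analysis_site.tsv")
  write_feature_set_analysis(an, paths$analysis_family, paths$analysis_site)

  paths$config <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE,
                       null = "null")
  if (!quiet)
    message("[pyrosite] config hash: ",
            unname(tools::md5sum(paths$config)))
  invisible(list(fit = fit, windows = windows, matrix = fm,
                 paths = paths))
}
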