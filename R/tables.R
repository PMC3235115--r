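# Amino-acid alphabet and per-residue property tables.

#' Standard amino-acid alphabet
#'
#' The fixed 20-letter alphabet used throughout the package, in
#' alphabetical one-letter order. All PSSM columns, property tables and
#' feature names follow this ordering.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Pad character for truncated peptide windows
#' @format Single character, `"-"`.
#' @export
PAD_CHAR <- "-"

# Atchley's five-factor solution: multivariate summary scores of
# physicochemical amino-acid properties. Factor order: polarity,
# secondary structure, molecular volume, codon diversity,
# electrostatic charge.
.atchley <- matrix(c(
  # pol      ss      vol     codon   charge
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512), # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET,
                  c("Polarity", "Secondary Structure", "Molecular Volume",
                    "Codon Diversity", "Electrostatic Charge")))

# Net gain/loss of each amino acid over protein evolution (relative
# flux, gain minus loss). Documented defaults following the universal
# ordering (Cys/Met/His/Ser/Phe gained; Pro/Ala/Glu/Gly lost);
# user-overridable via load_property_tables().
.gain_loss <- c(
  A = -0.17, C = 0.31, D = -0.05, E = -0.15, F = 0.10,
  G = -0.12, H = 0.13, I = 0.02, K = 0.01, L = 0.00,
  M = 0.23, N = 0.04, P = -0.18, Q = -0.02, R = -0.04,
  S = 0.12, T = 0.03, V = -0.01, W = -0.02, Y = 0.05)

# Propensity of each amino acid to be conserved at protein-protein
# interfaces and on the exposed protein surface. Documented defaults
# (hydrophobic/aromatic residues most conserved at interfaces);
# user-overridable via load_property_tables().
.interface_propensity <- c(
  A = 0.75, C = 1.05, D = 0.80, E = 0.60, F = 1.35,
  G = 0.70, H = 1.00, I = 1.15, K = 0.55, L = 1.10,
  M = 1.30, N = 0.85, P = 0.55, Q = 0.75, R = 0.95,
  S = 0.70, T = 0.80, V = 1.00, W = 1.60, Y = 1.25)

.surface_propensity <- c(
  A = 0.80, C = 1.10, D = 0.90, E = 0.80, F = 1.05,
  G = 0.85, H = 1.00, I = 0.95, K = 0.75, L = 0.95,
  M = 1.00, N = 0.90, P = 0.80, Q = 0.85, R = 0.95,
  S = 0.85, T = 0.85, V = 0.90, W = 1.20, Y = 1.05)

# Side-chain carbon atom counts: chemical constants (Gly has no side
# chain carbon, Trp has nine).
.side_chain_carbons <- c(
  A = 1L, C = 1L, D = 2L, E = 3L, F = 7L,
  G = 0L, H = 4L, I = 4L, K = 4L, L = 4L,
  M = 3L, N = 2L, P = 3L, Q = 3L, R = 4L,
  S = 1L, T = 2L, V = 3L, W = 9L, Y = 7L)

.check_aa_table <- function(x, what) {
  missing <- setdiff(AA_ALPHABET, rownames(x) %||% names(x))
  if (length(missing) > 0L)
    stop(sprintf("property table '%s' is missing amino acid(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load per-amino-acid property tables
#'
#' Returns the five property tables used by the feature encoder: the
#' Atchley five-factor scores (polarity, secondary structure, molecular
#' volume, codon diversity, electrostatic charge), the evolutionary
#' gain/loss flux, interface and surface conservation propensities, and
#' side-chain carbon atom counts. Any table can be overridden with a
#' user-supplied replacement; a replacement must cover all 20 standard
#' amino acids.
#'
#' @param aa_factors Optional 20 x 5 numeric matrix with amino-acid
#'   rownames replacing the built-in factor scores.
#' @param gain_loss,interface_propensity,surface_propensity,side_chain_carbons
#'   Optional named numeric vectors (names over [AA_ALPHABET]) replacing
#'   the corresponding built-in table.
#' @return An object of class `property_tables`: a list with elements
#'   `aa_factors`, `gain_loss`, `interface_propensity`,
#'   `surface_propensity`, `side_chain_carbons`, and `mean_carbons`
#'   (the mean side-chain carbon count over the 20 amino acids, used
#'   for pad positions).
#' @examples
#' tab <- load_property_tables()
#' tab$side_chain_carbons[["G"]]  # glycine: 0
#' @export
load_property_tables <- function(aa_factors = NULL, gain_loss = NULL,
                                 interface_propensity = NULL,
                                 surface_propensity = NULL,
                                 side_chain_carbons = NULL) {
  fac <- .check_aa_table(aa_factors %||% .atchley, "aa_factors")
  fac <- fac[AA_ALPHABET, , drop = FALSE]
  if (ncol(fac) != 5L)
    stop("aa_factors must have exactly 5 factor columns", call. = FALSE)
  pick <- function(user, default, what) {
    v <- .check_aa_table(user %||% default, what)
    v[AA_ALPHABET]
  }
  carb <- pick(side_chain_carbons, .side_chain_carbons, "side_chain_carbons")
  out <- list(
    aa_factors = fac,
    gain_loss = pick(gain_loss, .gain_loss, "gain_loss"),
    interface_propensity = pick(interface_propensity, .interface_propensity,
                                "interface_propensity"),
    surface_propensity = pick(surface_propensity, .surface_propensity,
                              "surface_propensity"),
    side_chain_carbons = carb,
    mean_carbons = mean(carb))
  class(out) <- "property_tables"
  out
}

#' @export
print.property_tables <- function(x, ...) {
  cat("Per-amino-acid property tables (20 residues)\n")
  cat("  aa_factors:", paste(colnames(x$aa_factors), collapse = ", "), "\n")
  cat("  scalar tables: gain_loss, interface_propensity,",
      "surface_propensity, side_chain_carbons\n")
  cat(sprintf("  mean side-chain carbon count: %.2f\n", x$mean_carbons))
  invisible(x)
}
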