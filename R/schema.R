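# Canonical feature schema: the ordered, named feature columns derived
# from a peptide window.

FEATURE_FAMILIES <- c("PSSM", "AAFactor", "Disorder", "SecondaryStructure",
                      "Accessibility", "InterfaceSurface", "GainLoss",
                      "CarbonDeviation")

AA_FACTOR_NAMES <- c("Polarity", "Secondary Structure", "Molecular Volume",
                     "Codon Diversity", "Electrostatic Charge")

#' Build the canonical feature schema
#'
#' Enumerates the feature columns of a `2 * flank + 1`-residue window in
#' a fixed order: sites ascending; within each site, 20 PSSM
#' conservation scores (alphabetical), 5 amino-acid factors, disorder,
#' 3 secondary-structure indicators (helix/strand/other), 2
#' accessibility indicators (buried/exposed), interface and surface
#' conservation propensities, gain/loss, and the side-chain
#' carbon-count deviation. The centre site carries a constant residue
#' (glutamine for real windows), so its residue-identity families
#' (amino-acid factors, interface/surface, gain/loss) are omitted,
#' leaving 27 columns there and 35 at every other site; with the
#' default `flank = 10` the schema has `35 * 20 + 27 = 727` columns.
#'
#' Names follow the `AA<site>-<feature>` convention, e.g.
#' `"AA10-Pssm_A"`, `"AA2-Codon Diversity"`,
#' `"AA1-Secondary Structure Helix"`.
#'
#' @param flank Residues on each side of the centre (default 10).
#' @return Object of class `feature_schema`: a data.frame with columns
#'   `site`, `family`, `subname`, `name`, one row per feature, and
#'   attribute `flank`.
#' @examples
#' sch <- build_schema()
#' nrow(sch)                 # 727
#' table(sch$site)[["11"]]   # 27 at the centre site
#' @export
build_schema <- function(flank = 10L) {
  width <- 2L * as.integer(flank) + 1L
  center <- as.integer(flank) + 1L
  per_site <- function(s) {
    is_center <- s == center
    fam <- c(rep("PSSM", 20L),
             if (!is_center) rep("AAFactor", 5L),
             "Disorder",
             rep("SecondaryStructure", 3L),
             rep("Accessibility", 2L),
             if (!is_center) rep("InterfaceSurface", 2L),
             if (!is_center) "GainLoss",
             "CarbonDeviation")
    sub <- c(AA_ALPHABET,
             if (!is_center) AA_FACTOR_NAMES,
             "Disorder",
             c("Helix", "Strand", "Other"),
             c("Buried", "Exposed"),
             if (!is_center) c("Interface", "Surface"),
             if (!is_center) "GainLoss",
             "CarbonDeviation")
    data.frame(site = s, family = fam, subname = sub,
               stringsAsFactors = FALSE)
  }
  sch <- do.call(rbind, lapply(seq_len(width), per_site))
  sch$name <- with(sch, ifelse(
    family == "PSSM", sprintf("AA%d-Pssm_%s", site, subname),
    ifelse(family == "AAFactor", sprintf("AA%d-%s", site, subname),
    ifelse(family == "Disorder", sprintf("AA%d-Disorder", site),
    ifelse(family == "SecondaryStructure",
           sprintf("AA%d-Secondary Structure %s", site, subname),
    ifelse(family == "Accessibility",
           sprintf("AA%d-Accessibility %s", site, subname),
    ifelse(family == "InterfaceSurface",
           sprintf("AA%d-%s Propensity", site, subname),
    ifelse(family == "GainLoss", sprintf("AA%d-Gain/Loss", site),
           sprintf("AA%d-Side Chain Count of Atom_C Deviation from Mean",
                   site)))))))))
  attr(sch, "flank") <- as.integer(flank)
  class(sch) <- c("feature_schema", "data.frame")
  sch
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("Feature schema: %d columns over %d window sites (flank %d)\n",
              nrow(x), max(x$site), attr(x, "flank")))
  print(table(factor(x$family, levels = FEATURE_FAMILIES)))
  invisible(x)
}
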