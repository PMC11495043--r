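## Closed vocabularies used across the pipeline.

#' Subcellular compartment categories
#'
#' The closed vocabulary of integrated subcellular categories. EC, OM, CW
#' and PP together form the extra-cytoplasmic (secreted) union.
#' @return Character vector of category labels.
#' @export
compartment_categories <- function() {
  c("EXTRACELLULAR", "OUTER_MEMBRANE", "CELL_WALL", "PERIPLASMIC",
    "CYTOPLASMIC_MEMBRANE", "CYTOPLASMIC", "UNKNOWN")
}

#' Extra-cytoplasmic categories
#' @return Character vector: the categories counted as secreted.
#' @export
extra_cytoplasmic_categories <- function() {
  c("EXTRACELLULAR", "OUTER_MEMBRANE", "CELL_WALL", "PERIPLASMIC")
}

#' Enzyme class labels
#' @return Character vector of enzyme classes emitted by the classifiers.
#' @export
enzyme_classes <- function() {
  c("CAZY_GH", "CAZY_CBM", "CAZY_CE", "CAZY_PL",
    "PEPTIDASE_NUTRIENT", "LIPASE", "NUCLEASE", "RNASE", "NUCLEOTIDASE")
}

## Signal-peptide detector ids. The first is the primary method: the
## UNK+SP category is defined by it alone (the tri-method screen applies
## to predicted extracellular proteins; its support is carried separately
## in sp_support).
sp_methods <- function() c("signalp", "predtat", "phobius")

## Versioned normalization table for location labels as printed by
## localization tools in their monoderm/diderm output dialects. Keys are
## matched after lower-casing and removal of spaces/underscores; canonical
## labels map to themselves so normalization is idempotent.
location_vocab_default <- function() {
  c(
    "extracellular"                     = "EXTRACELLULAR",
    "outermembrane"                     = "OUTER_MEMBRANE",
    "cellwall"                          = "CELL_WALL",
    "periplasmic"                       = "PERIPLASMIC",
    "periplasm"                         = "PERIPLASMIC",
    "cytoplasmicmembrane"               = "CYTOPLASMIC_MEMBRANE",
    "innermembrane"                     = "CYTOPLASMIC_MEMBRANE",
    "membrane"                          = "CYTOPLASMIC_MEMBRANE",
    "cytoplasmic"                       = "CYTOPLASMIC",
    "cytoplasm"                         = "CYTOPLASMIC",
    "unknown"                           = "UNKNOWN",
    "unknown(multiplelocalizations)"    = "UNKNOWN"
  )
}

#' Pipeline configuration
#'
#' Builds the configuration list that carries every tunable threshold of
#' the profiling pipeline. Defaults are the published analysis values:
#' CAZymes require detection by at least two methods; peptidase hits must
#' reach e <= 1e-20; the iterative nuclease/RNase/nucleotidase expansion
#' and the lipase search use e <= 1e-10 and e <= 1e-5 respectively;
#' proteins with >= 4 CxxCH sites are multi-heme; per-MAG counts more than
#' 2 standard deviations above the cohort mean are flagged; MAGs above
#' 0.1% mean relative abundance are labelled abundant; orthogroups are
#' ranked to a top-100 list.
#'
#' @param cazy_min_methods minimum number of CAZyme detection methods.
#' @param merops_evalue_cutoff peptidase-database e-value cutoff.
#' @param nuclease_evalue_cutoff e-value cutoff for the iterative
#'   nuclease/RNase/nucleotidase expansion.
#' @param lipase_evalue_cutoff e-value cutoff for the lipase seed search.
#' @param multiheme_min_sites minimum CxxCH motifs for a multi-heme call.
#' @param flag_sd_multiplier multiplier on the standard deviation for the
#'   high-count flag threshold (counts > mean + multiplier * SD).
#' @param abundance_cutoff strict lower bound (% mean relative abundance)
#'   for the "abundant" label.
#' @param top_og_n orthogroups retained by [rank_ogs()].
#' @param max_expansion_iterations cap on homology-expansion rounds.
#' @param evalue_rel_tol relative slack applied to every e-value cutoff
#'   comparison; absorbs the 2-3 significant digits that tool tables print
#'   (so 1.01e-20 passes a 1e-20 cutoff but 1e-19 does not).
#' @param cog_mode `"strict"` excludes peptidases whose COG string contains
#'   any letter besides E; `"contains"` only requires E to be present.
#' @param respiration_keywords descriptor keywords (besides "cytochrome")
#'   that fire the functional-descriptor cytochrome rule.
#' @param heme_secreted_only if `TRUE`, cytochrome classification is
#'   restricted to extra-cytoplasmic and UNK+SP proteins; motif scanning
#'   for the periplasmic/membrane heme counts always covers the whole
#'   proteome.
#' @param location_vocab named character vector mapping squashed raw
#'   location labels to canonical categories.
#' @param vocab_version version tag of the normalization table, recorded in
#'   the run manifest.
#' @return A named list of class `secretome_config`.
#' @export
pipeline_config <- function(cazy_min_methods = 2,
                            merops_evalue_cutoff = 1e-20,
                            nuclease_evalue_cutoff = 1e-10,
                            lipase_evalue_cutoff = 1e-5,
                            multiheme_min_sites = 4,
                            flag_sd_multiplier = 2,
                            abundance_cutoff = 0.1,
                            top_og_n = 100,
                            max_expansion_iterations = 10,
                            evalue_rel_tol = 0.05,
                            cog_mode = c("strict", "contains"),
                            respiration_keywords = c(
                              "respiration", "respiratory", "denitrification",
                              "nitrate reductase", "oxidase", "reductase"),
                            heme_secreted_only = TRUE,
                            location_vocab = location_vocab_default(),
                            vocab_version = "1") {
  cog_mode <- match.arg(cog_mode)
  stopifnot(
    cazy_min_methods %in% 1:3,
    merops_evalue_cutoff > 0, nuclease_evalue_cutoff > 0,
    lipase_evalue_cutoff > 0, multiheme_min_sites >= 1,
    flag_sd_multiplier > 0, abundance_cutoff >= 0, top_og_n >= 1,
    max_expansion_iterations >= 1, evalue_rel_tol >= 0
  )
  structure(list(
    cazy_min_methods = cazy_min_methods,
    merops_evalue_cutoff = merops_evalue_cutoff,
    nuclease_evalue_cutoff = nuclease_evalue_cutoff,
    lipase_evalue_cutoff = lipase_evalue_cutoff,
    multiheme_min_sites = multiheme_min_sites,
    flag_sd_multiplier = flag_sd_multiplier,
    abundance_cutoff = abundance_cutoff,
    top_og_n = top_og_n,
    max_expansion_iterations = max_expansion_iterations,
    evalue_rel_tol = evalue_rel_tol,
    cog_mode = cog_mode,
    respiration_keywords = respiration_keywords,
    heme_secreted_only = heme_secreted_only,
    location_vocab = location_vocab,
    vocab_version = vocab_version
  ), class = "secretome_config")
}

## e-value cutoff test with relative slack (see ?pipeline_config).
evalue_passes <- function(evalue, cutoff, config) {
  evalue <= cutoff * (1 + config$evalue_rel_tol)
}
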