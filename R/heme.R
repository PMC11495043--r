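## CxxCH heme-binding motif scanning and multi-heme cytochrome
## classification. The canonical c-type heme attachment motif is C-x-x-C-H
## where x is any residue; anchor positions require literal C/H (the
## ambiguity letter X does not match an anchor). Overlapping occurrences
## are counted individually. Proteins with >= 4 motifs are multi-heme.

#' Scan a sequence for CxxCH heme-binding motifs
#'
#' Returns every 1-based start position i with `C` at i, `C` at i+3 and
#' `H` at i+4; the two wildcard positions accept any letter (including
#' ambiguity codes). Overlapping motifs are all reported.
#'
#' @param sequence normalized amino-acid string (may be empty).
#' @return integer vector of 1-based motif start positions.
#' @export
scan_heme_motifs <- function(sequence) {
  L <- nchar(sequence)
  if (L < 5L) return(integer(0))
  ch <- strsplit(sequence, "")[[1]]
  i <- which(ch == "C")
  i <- i[i <= L - 4L]
  i[ch[i + 3L] == "C" & ch[i + 4L] == "H"]
}

heme_rules_default <- function() {
  path <- system.file("extdata", "rules", "heme.yaml",
                      package = "magsecretome")
  yaml::read_yaml(path)
}

#' Profile heme-binding proteins and classify cytochromes
#'
#' Scans every protein for CxxCH motifs and, for proteins with at least
#' one motif, applies the cytochrome classification rules:
#' (i) `PROKKA_NAME` -- the gene-caller descriptor contains "cytochrome";
#' (ii) `FUNCTIONAL_DESCRIPTOR` -- the ortholog-mapper descriptor
#' contains "cytochrome" or a respiration-related keyword;
#' (iii) `CYTOCHROME_DOMAIN` -- a conserved-domain hit matches the
#' cytochrome domain list; (iv) `HEAT_SHOCK_MULTIHEME` -- the descriptor
#' contains "heat shock protein" and the protein is multi-heme. All
#' keyword matching is case-insensitive.
#'
#' By default (`config$heme_secreted_only`) cytochrome classification is
#' reported for extra-cytoplasmic and UNK+SP proteins, mirroring the
#' secreted-heme analysis; motif counts are computed for the whole
#' proteome so periplasmic/membrane heme tallies remain available.
#'
#' @param proteins protein data.frame (`protein_id`, `sequence`).
#' @param assignments data.frame from [assign_compartments()].
#' @param annotations data.frame from `read_table("annotation", ...)`.
#' @param domain_hits data.frame from `read_table("domain", ...)`.
#' @param config a [pipeline_config()].
#' @param rules cytochrome evidence lists (defaults to the shipped file).
#' @return data.frame with one row per protein with >= 1 motif:
#'   `protein_id`, `mag_id`, `n_motifs`, `motif_positions`
#'   (";"-separated, 1-based), `is_multiheme`, `in_secreted_scope`,
#'   `is_cytochrome`, `rule_fired` (","-joined), `category`, `unk_sp`.
#' @export
profile_heme_proteins <- function(proteins, assignments, annotations,
                                  domain_hits,
                                  config = pipeline_config(),
                                  rules = heme_rules_default()) {
  pos <- lapply(proteins$sequence, scan_heme_motifs)
  n <- lengths(pos)
  keep <- n >= 1L
  if (!any(keep)) {
    return(data.frame(protein_id = character(0), mag_id = character(0),
                      n_motifs = integer(0),
                      motif_positions = character(0),
                      is_multiheme = logical(0),
                      in_secreted_scope = logical(0),
                      is_cytochrome = logical(0),
                      rule_fired = character(0), category = character(0),
                      unk_sp = logical(0), stringsAsFactors = FALSE))
  }
  ids <- proteins$protein_id[keep]
  n <- n[keep]
  pos <- pos[keep]
  a <- assignments[match(ids, assignments$protein_id), , drop = FALSE]
  multi <- n >= config$multiheme_min_sites
  scope <- a$is_extra_cytoplasmic | a$unk_sp
  scope[is.na(scope)] <- FALSE

  gc <- annotations[annotations$source == "gene_caller", , drop = FALSE]
  og <- annotations[annotations$source == "og_mapper", , drop = FALSE]
  gc_desc <- tolower(gc$descriptor[match(ids, gc$protein_id)])
  og_desc <- tolower(og$descriptor[match(ids, og$protein_id)])
  gc_desc[is.na(gc_desc)] <- ""
  og_desc[is.na(og_desc)] <- ""

  r1 <- grepl("cytochrome", gc_desc, fixed = TRUE)
  resp_kw <- c("cytochrome", tolower(config$respiration_keywords))
  r2 <- vapply(og_desc, function(d) {
    any(vapply(resp_kw, grepl, logical(1), x = d, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  cyt_dom <- tolower(rules$cytochrome_domains)
  dom_hit_ids <- unique(domain_hits$protein_id[
    vapply(tolower(domain_hits$domain_name), function(d) {
      any(vapply(cyt_dom, grepl, logical(1), x = d, fixed = TRUE))
    }, logical(1), USE.NAMES = FALSE)])
  r3 <- ids %in% dom_hit_ids
  r4 <- grepl("heat shock protein", og_desc, fixed = TRUE) & multi

  classify <- if (config$heme_secreted_only) scope else rep(TRUE,
                                                            length(ids))
  fired <- mapply(function(a1, a2, a3, a4, cl) {
    if (!cl) return("")
    paste(c("PROKKA_NAME", "FUNCTIONAL_DESCRIPTOR", "CYTOCHROME_DOMAIN",
            "HEAT_SHOCK_MULTIHEME")[c(a1, a2, a3, a4)], collapse = ",")
  }, r1, r2, r3, r4, classify)

  data.frame(
    protein_id = ids,
    mag_id = a$mag_id,
    n_motifs = n,
    motif_positions = vapply(pos, paste, character(1), collapse = ";"),
    is_multiheme = multi,
    in_secreted_scope = scope,
    is_cytochrome = nzchar(fired),
    rule_fired = unname(fired),
    category = a$category,
    unk_sp = a$unk_sp,
    stringsAsFactors = FALSE
  )
}
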