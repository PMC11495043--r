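## Catabolic-enzyme classification: CAZyme acceptance (>= 2 detection
## methods, biosynthetic exclusion list), nutrient-peptidase filtering
## (e-value + COG-E + glutathione-hydrolase exclusion), lipase
## classification (seed search / annotation keywords + domain accept
## list, PhoD veto), and iterative seed-expansion for nucleases, RNases
## and nucleotidases.

#' Load a domain rule set
#'
#' Rule sets (accept/reject domain lists and annotation keywords) are
#' shipped as editable, versioned YAML under
#' `system.file("extdata/rules", package = "magsecretome")`.
#'
#' @param class_label one of `"NUCLEASE"`, `"RNASE"`, `"NUCLEOTIDASE"`,
#'   `"LIPASE"`.
#' @param path optional path to a custom rules file.
#' @return list with `class_label`, `accept_domains`, `reject_domains`,
#'   `annotation_include_keywords`.
#' @export
load_domain_rules <- function(class_label = c("NUCLEASE", "RNASE",
                                              "NUCLEOTIDASE", "LIPASE"),
                              path = NULL) {
  class_label <- match.arg(class_label)
  if (is.null(path)) {
    path <- system.file("extdata", "rules",
                        paste0(tolower(class_label), ".yaml"),
                        package = "magsecretome")
  }
  r <- yaml::read_yaml(path)
  r$accept_domains <- trimws(as.character(r$accept_domains))
  r$reject_domains <- trimws(as.character(r$reject_domains))
  r$annotation_include_keywords <-
    as.character(r$annotation_include_keywords)
  if (length(intersect(r$accept_domains, r$reject_domains))) {
    stop("integrity error: accept and reject domain lists overlap")
  }
  r
}

cazy_exclusion_labels <- function() {
  path <- system.file("extdata", "rules", "cazy_exclusions.yaml",
                      package = "magsecretome")
  as.character(yaml::read_yaml(path)$excluded_class_labels)
}

enzyme_call <- function(protein_id, enzyme_class, evidence,
                        iteration = NA_integer_) {
  data.frame(protein_id = protein_id, enzyme_class = enzyme_class,
             evidence = evidence, iteration = iteration,
             stringsAsFactors = FALSE)
}

empty_enzyme_calls <- function() {
  enzyme_call(character(0), character(0), character(0), integer(0))
}

#' Filter CAZyme calls
#'
#' Keeps calls detected by at least `cazy_min_methods` methods, drops
#' glycosyltransferase (GT) families and families whose description is on
#' the biosynthetic exclusion list, and maps surviving families to the
#' GH/CBM/CE/PL subtype by prefix. Auxiliary-activity (AA) families pass
#' the family grammar but belong to none of the four secreted classes and
#' are dropped.
#'
#' @param cazy data.frame from `read_table("cazy", ...)`.
#' @param config a [pipeline_config()].
#' @return enzyme-call data.frame (`protein_id`, `enzyme_class`,
#'   `evidence`, `iteration`).
#' @export
filter_cazymes <- function(cazy, config = pipeline_config()) {
  if (nrow(cazy) == 0L) return(empty_enzyme_calls())
  ok_family <- grepl("^(GH|GT|CBM|CE|PL|AA)[0-9]*(_[0-9]+)?$", cazy$family)
  if (any(!ok_family)) {
    stop("format error: CAZy family fails the family grammar: ",
         paste(unique(cazy$family[!ok_family]), collapse = ", "))
  }
  n_methods <- lengths(strsplit(cazy$methods, "+", fixed = TRUE))
  prefix <- sub("^([A-Z]+).*$", "\\1", cazy$family)
  excluded <- tolower(cazy$class_label) %in%
    tolower(cazy_exclusion_labels())
  keep <- n_methods >= config$cazy_min_methods & prefix != "GT" &
    prefix != "AA" & !excluded
  if (!any(keep)) return(empty_enzyme_calls())
  kept <- cazy[keep, , drop = FALSE]
  out <- enzyme_call(
    kept$protein_id,
    paste0("CAZY_", sub("^([A-Z]+).*$", "\\1", kept$family)),
    paste0("family=", kept$family, ";methods=", kept$methods))
  out[!duplicated(out[c("protein_id", "enzyme_class")]), , drop = FALSE]
}

#' Classify nutrient-acquiring peptidases
#'
#' A protein is called a nutrient peptidase when its best (minimum)
#' peptidase-database e-value passes the cutoff, its COG assignment is
#' category E ("Amino acid transport and metabolism") -- strictly E only
#' under `cog_mode = "strict"`, E possibly among others under
#' `"contains"` -- and no descriptor annotates it as a glutathione
#' hydrolase (a housekeeping enzyme). Hits without an annotation row are
#' excluded with a message.
#'
#' @param merops data.frame from `read_table("merops", ...)`.
#' @param annotations data.frame from `read_table("annotation", ...)`.
#' @param config a [pipeline_config()].
#' @return enzyme-call data.frame.
#' @export
classify_peptidases <- function(merops, annotations,
                                config = pipeline_config()) {
  if (nrow(merops) == 0L) return(empty_enzyme_calls())
  best <- tapply(merops$evalue, merops$protein_id, min)
  fam <- merops$merops_family[match(names(best), merops$protein_id)]
  pass_e <- evalue_passes(unname(best), config$merops_evalue_cutoff,
                          config)
  ids <- names(best)[pass_e]
  if (length(ids) == 0L) return(empty_enzyme_calls())

  ann <- annotations[annotations$protein_id %in% ids, , drop = FALSE]
  no_ann <- setdiff(ids, ann$protein_id)
  if (length(no_ann)) {
    message("classify_peptidases: ", length(no_ann),
            " hit(s) without an annotation row excluded")
    ids <- setdiff(ids, no_ann)
  }
  keep <- vapply(ids, function(p) {
    rows <- ann[ann$protein_id == p, , drop = FALSE]
    og <- rows[rows$source == "og_mapper", , drop = FALSE]
    cogs <- paste(og$cog_categories, collapse = "")
    cog_ok <- if (config$cog_mode == "strict") {
      nzchar(cogs) && all(strsplit(cogs, "")[[1]] == "E")
    } else {
      grepl("E", cogs, fixed = TRUE)
    }
    gluta <- any(grepl("glutathione hydrolase",
                       tolower(rows$descriptor), fixed = TRUE))
    cog_ok && !gluta
  }, logical(1))
  ids <- ids[keep]
  if (length(ids) == 0L) return(empty_enzyme_calls())
  e <- unname(best[ids])
  f <- fam[match(ids, names(best))]
  enzyme_call(ids, "PEPTIDASE_NUTRIENT",
              paste0("family=", f, ";evalue=", format_num(e)))
}

#' Iterative homology expansion from a seed database
#'
#' Grows a protein class from a seed database: each round, proteome
#' proteins with a similarity hit (at the class e-value cutoff) to the
#' current database are candidates; candidates carrying at least one
#' accept-list domain are accepted and appended to the database,
#' candidates without one are discarded permanently and never re-tested.
#' Rounds repeat until none is accepted or the iteration cap is reached.
#' The result records the round of first acceptance.
#'
#' @param seed_ids character vector of seed-database identifiers
#'   (non-empty).
#' @param proteome protein data.frame (`protein_id`, `sequence`); only
#'   ids are needed when `hits` is supplied.
#' @param rules a [load_domain_rules()] set with class `NUCLEASE`,
#'   `RNASE` or `NUCLEOTIDASE`.
#' @param domain_hits data.frame from `read_table("domain", ...)`.
#' @param config a [pipeline_config()].
#' @param hits externally supplied similarity table
#'   (`read_table("similarity", ...)` layout) with subjects among seeds
#'   and proteome proteins; when `NULL` the built-in engine searches the
#'   proteome against the seeds and itself.
#' @param seed_db seed protein data.frame, required for engine mode.
#' @param scheme scoring scheme for engine mode.
#' @return enzyme-call data.frame with the acceptance round in
#'   `iteration`.
#' @export
iterative_expansion <- function(seed_ids, proteome, rules, domain_hits,
                                config = pipeline_config(), hits = NULL,
                                seed_db = NULL,
                                scheme = scoring_scheme()) {
  if (length(seed_ids) == 0L) {
    stop("usage error: empty seed database")
  }
  stopifnot(rules$class_label %in% c("NUCLEASE", "RNASE", "NUCLEOTIDASE"))
  cutoff <- config$nuclease_evalue_cutoff
  if (is.null(hits)) {
    if (is.null(seed_db)) {
      stop("usage error: engine mode needs the seed database sequences")
    }
    db <- rbind(seed_db[c("protein_id", "sequence")],
                proteome[c("protein_id", "sequence")])
    hits <- search_similar(proteome, db,
                           evalue_cutoff = cutoff * (1 + config$evalue_rel_tol),
                           scheme = scheme)
  }
  hits <- hits[evalue_passes(hits$evalue, cutoff, config), , drop = FALSE]
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]

  domain_pos <- unique(domain_hits$protein_id[
    trimws(domain_hits$domain_name) %in% rules$accept_domains])

  db <- seed_ids
  accepted <- character(0)
  round_of <- integer(0)
  discarded <- character(0)
  converged <- FALSE
  for (r in seq_len(config$max_expansion_iterations)) {
    cand <- unique(hits$query_id[hits$subject_id %in% db])
    cand <- setdiff(cand, c(accepted, discarded, seed_ids))
    acc <- intersect(cand, domain_pos)
    discarded <- c(discarded, setdiff(cand, acc))
    if (length(acc) == 0L) {
      converged <- TRUE
      break
    }
    accepted <- c(accepted, acc)
    round_of <- c(round_of, rep(r, length(acc)))
    db <- c(db, acc)
  }
  if (!converged) {
    warning("iterative_expansion (", rules$class_label,
            "): iteration cap reached before convergence; ",
            "partial result returned")
  }
  if (length(accepted) == 0L) return(empty_enzyme_calls())
  enzyme_call(accepted, rules$class_label,
              paste0("round=", round_of), iteration = round_of)
}

#' Classify lipases
#'
#' Candidates are proteins with a lipase seed-database hit at the lipase
#' e-value cutoff, plus proteins whose gene-caller descriptor contains
#' one of the annotation keywords (multifunctional esterase, lipase,
#' glycerophosphodiester phosphodiesterase; case-insensitive substring).
#' Candidates are accepted when they carry at least one accept-list
#' lipase domain, and vetoed regardless of other evidence when they carry
#' a PhoD domain.
#'
#' @param hits similarity table of proteome-vs-lipase-seed hits.
#' @param annotations data.frame from `read_table("annotation", ...)`.
#' @param domain_hits data.frame from `read_table("domain", ...)`.
#' @param config a [pipeline_config()].
#' @param rules lipase rule set (defaults to the shipped file).
#' @return enzyme-call data.frame.
#' @export
classify_lipases <- function(hits, annotations, domain_hits,
                             config = pipeline_config(),
                             rules = load_domain_rules("LIPASE")) {
  by_hit <- unique(hits$query_id[
    evalue_passes(hits$evalue, config$lipase_evalue_cutoff, config)])
  gc <- annotations[annotations$source == "gene_caller", , drop = FALSE]
  kw <- tolower(rules$annotation_include_keywords)
  kw_match <- vapply(tolower(gc$descriptor), function(d) {
    any(vapply(kw, grepl, logical(1), x = d, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  by_kw <- unique(gc$protein_id[kw_match])
  cand <- union(by_hit, by_kw)
  if (length(cand) == 0L) return(empty_enzyme_calls())

  dn <- trimws(domain_hits$domain_name)
  has_accept <- unique(domain_hits$protein_id[dn %in% rules$accept_domains])
  has_reject <- unique(domain_hits$protein_id[dn %in% rules$reject_domains])
  acc <- setdiff(intersect(cand, has_accept), has_reject)
  if (length(acc) == 0L) return(empty_enzyme_calls())
  route <- ifelse(acc %in% by_hit & acc %in% by_kw, "seed+keyword",
                  ifelse(acc %in% by_hit, "seed", "keyword"))
  enzyme_call(acc, "LIPASE", paste0("route=", route))
}
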