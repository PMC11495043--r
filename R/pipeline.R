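## End-to-end orchestration: compartment assignment, the four enzyme
## classification procedures, heme profiling, catalog assembly, per-MAG
## profiles, cohort statistics and orthogroup analyses.

#' Run the full secretome-profiling pipeline
#'
#' Takes a cohort (as generated by [generate_cohort()] or read by
#' [read_cohort_dir()]) and produces the per-protein catalog, per-MAG
#' profiles, high-count flags, the cohort summary, the UNK+SP vs
#' extra-cytoplasmic correlation and the orthogroup ranking/clustering.
#'
#' @param cohort list with `proteins`, `tables` (the tool tables;
#'   `tables$similarity` a named list per expansion class) and `seeds`
#'   (seed databases for nuclease/RNase/nucleotidase/lipase).
#' @param config a [pipeline_config()].
#' @return list of class `secretome_result` with elements `catalog`,
#'   `profiles`, `enzyme_calls`, `heme`, `flags`, `summary`,
#'   `correlation`, `og_ranking`, `og_clustering`, `config`.
#' @export
run_secretome_pipeline <- function(cohort, config = pipeline_config()) {
  tb <- cohort$tables
  proteins <- cohort$proteins

  assignments <- assign_compartments(tb$location, tb$signal_peptide,
                                     tb$envelope, proteins)

  calls <- list(
    cazy = filter_cazymes(tb$cazy, config),
    peptidase = classify_peptidases(tb$merops, tb$annotation, config),
    lipase = classify_lipases(
      hits = tb$similarity$lipase, annotations = tb$annotation,
      domain_hits = tb$domain, config = config)
  )
  for (cl in c("nuclease", "rnase", "nucleotidase")) {
    calls[[cl]] <- iterative_expansion(
      seed_ids = cohort$seeds[[cl]]$protein_id,
      proteome = proteins,
      rules = load_domain_rules(toupper(cl)),
      domain_hits = tb$domain, config = config,
      hits = tb$similarity[[cl]])
  }
  enzyme_calls <- do.call(rbind, unname(calls))

  heme <- profile_heme_proteins(proteins, assignments, tb$annotation,
                                tb$domain, config)

  catalog <- assignments
  for (cls in enzyme_classes()) {
    catalog[[tolower(cls)]] <- catalog$protein_id %in%
      enzyme_calls$protein_id[enzyme_calls$enzyme_class == cls]
  }
  hidx <- match(catalog$protein_id, heme$protein_id)
  catalog$n_heme_motifs <- ifelse(is.na(hidx), 0L, heme$n_motifs[hidx])
  catalog$is_multiheme <- !is.na(hidx) & heme$is_multiheme[hidx]
  catalog$is_multiheme[is.na(catalog$is_multiheme)] <- FALSE
  catalog$is_cytochrome <- !is.na(hidx) & heme$is_cytochrome[hidx]
  catalog$is_cytochrome[is.na(catalog$is_cytochrome)] <- FALSE
  catalog$heme_rules <- ifelse(is.na(hidx), "", heme$rule_fired[hidx])

  profiles <- build_mag_profiles(assignments, enzyme_calls, heme,
                                 tb$abundance, config)
  flags <- if (nrow(profiles) >= 2L) flag_profiles(profiles,
                                                   config = config)
  summary <- summarize_cohort(assignments)
  correlation <- tryCatch(correlate_categories(profiles),
                          error = function(e) {
                            message("correlation skipped: ",
                                    conditionMessage(e))
                            NULL
                          })

  og_ranking <- NULL
  og_clustering <- NULL
  if (!is.null(tb$orthogroup) && nrow(tb$orthogroup)) {
    ogm <- og_count_matrix(tb$orthogroup, proteins)
    og_ranking <- rank_ogs(ogm, config = config)
    og_clustering <- tryCatch(cluster_og_matrix(ogm),
                              error = function(e) {
                                message("orthogroup clustering ",
                                        "skipped: ",
                                        conditionMessage(e))
                                NULL
                              })
  }

  structure(list(catalog = catalog, profiles = profiles,
                 enzyme_calls = enzyme_calls, heme = heme,
                 flags = flags, summary = summary,
                 correlation = correlation, og_ranking = og_ranking,
                 og_clustering = og_clustering, config = config),
            class = "secretome_result")
}

#' @export
print.secretome_result <- function(x, ...) {
  cat("Secretome profiling result\n")
  cat("  MAGs:", nrow(x$profiles), " proteins:", nrow(x$catalog), "\n")
  sec <- sum(x$catalog$is_extra_cytoplasmic)
  cat("  extra-cytoplasmic:", sec,
      sprintf("(%.1f%%)", 100 * sec / nrow(x$catalog)),
      " UNK+SP:", sum(x$catalog$unk_sp), "\n")
  cat("  enzyme calls:", nrow(x$enzyme_calls),
      " multi-heme:", sum(x$catalog$is_multiheme),
      " cytochromes:", sum(x$catalog$is_cytochrome), "\n")
  if (!is.null(x$correlation)) {
    cat(sprintf("  UNK+SP vs extra-cytoplasmic: Pearson r = %.3f (p = %.3g)\n",
                x$correlation$r, x$correlation$p))
  }
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Writes the catalog/profile tables and run manifest via
#' [write_outputs()], the cohort summary and flag tables, and the
#' orthogroup dendrograms as Newick files.
#'
#' @param result a `secretome_result` from [run_secretome_pipeline()].
#' @param outdir output directory.
#' @param seed seed recorded in the manifest.
#' @return invisible vector of files written.
#' @export
write_result <- function(result, outdir, seed = NA) {
  files <- write_outputs(result$catalog, result$profiles, outdir,
                         config = result$config, seed = seed)
  f <- file.path(outdir, "cohort_summary.tsv")
  writeLines(c("# magsecretome cohort summary",
               paste(names(result$summary), collapse = "\t"),
               do.call(paste, c(lapply(result$summary, function(col) {
                 if (is.numeric(col)) format_num(col) else col
               }), sep = "\t"))), f)
  files <- c(files, f)
  if (!is.null(result$flags) && nrow(result$flags)) {
    f <- file.path(outdir, "flags.tsv")
    writeLines(c(paste(names(result$flags), collapse = "\t"),
                 do.call(paste, c(unname(as.list(result$flags)),
                                  sep = "\t"))), f)
    files <- c(files, f)
  }
  if (!is.null(result$og_clustering)) {
    f1 <- file.path(outdir, "og_rows.nwk")
    f2 <- file.path(outdir, "og_cols.nwk")
    writeLines(result$og_clustering$row_newick, f1)
    writeLines(result$og_clustering$col_newick, f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
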