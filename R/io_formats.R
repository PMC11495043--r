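## Readers and writers for the external file dialects consumed and produced
## by the pipeline: protein FASTA and the tab-separated tool-output tables
## (localization calls, signal-peptide calls, conserved-domain hits,
## functional annotations, CAZyme overview rows, peptidase-database hits,
## 12-column similarity hits, orthogroup membership, per-MAG abundance,
## envelope types). All tables are one record per line, tab-separated,
## with "#"-prefixed comment lines ignored; empty free-text fields are
## printed as "-". Coordinates in all outputs are 1-based inclusive.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X","B","Z","J","U","O")

#' Read a protein FASTA file
#'
#' Headers follow the `MAGID|PROTEINID` convention, or bare protein ids
#' resolved through a companion two-column mapping. Sequences are
#' upper-cased and trailing `*` stop characters stripped.
#'
#' @param path FASTA file.
#' @param mag_map optional data.frame with columns `protein_id`, `mag_id`
#'   overriding/replacing the header convention.
#' @return data.frame with columns `protein_id`, `mag_id`, `sequence`,
#'   `length` (one row per record).
#' @export
read_fasta <- function(path, mag_map = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("format error: no FASTA records in ", path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  mag <- rep(NA_character_, length(ids))
  piped <- grepl("|", ids, fixed = TRUE)
  mag[piped] <- sub("\\|.*$", "", ids[piped])
  ids[piped] <- sub("^[^|]*\\|", "", ids[piped])
  if (!is.null(mag_map)) {
    mag <- mag_map$mag_id[match(ids, mag_map$protein_id)]
  }
  if (anyDuplicated(ids)) {
    stop("integrity error: duplicate protein_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  s <- toupper(as.character(seqs))
  s <- sub("\\*+$", "", s)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), s)
  if (any(bad)) {
    stop("format error: non-amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(s) == 0L)) {
    stop("format error: empty sequence in record(s): ",
         paste(ids[nchar(s) == 0L], collapse = ", "))
  }
  data.frame(protein_id = unname(ids), mag_id = unname(mag),
             sequence = unname(s), length = nchar(s),
             stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' Inverse of [read_fasta()]: records with a `mag_id` get `MAGID|PROTEINID`
#' headers, records without one (e.g. seed databases) get bare ids.
#'
#' @param proteins data.frame as returned by [read_fasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- ifelse(is.na(proteins$mag_id), proteins$protein_id,
                paste0(proteins$mag_id, "|", proteins$protein_id))
  x <- Biostrings::BStringSet(proteins$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## ---- tabular dialect registry ---------------------------------------------

TABLE_KINDS <- c("location", "signal_peptide", "domain", "annotation",
                 "cazy", "merops", "similarity", "orthogroup", "abundance",
                 "envelope")

table_columns <- function(kind) {
  switch(kind,
    location       = c("protein_id", "raw_location", "score"),
    signal_peptide = c("protein_id", "method", "has_sp", "sp_type"),
    domain         = c("protein_id", "domain_name", "evalue"),
    annotation     = c("protein_id", "source", "descriptor",
                       "cog_categories"),
    cazy           = c("protein_id", "family", "methods", "class_label"),
    merops         = c("protein_id", "merops_family", "evalue"),
    similarity     = c("query_id", "subject_id", "percent_identity",
                       "alignment_length", "mismatches", "gap_opens",
                       "qstart", "qend", "sstart", "send", "evalue",
                       "bitscore"),
    orthogroup     = c("og_id", "protein_id"),
    abundance      = c("mag_id", "mean_relative_abundance"),
    envelope       = c("mag_id", "envelope"),
    stop("usage error: unknown table kind '", kind, "'")
  )
}

## Numeric fields that must parse (format error otherwise), per kind.
table_numeric <- function(kind) {
  switch(kind,
    location   = "score",
    domain     = "evalue",
    merops     = "evalue",
    similarity = c("percent_identity", "alignment_length", "mismatches",
                   "gap_opens", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore"),
    abundance  = "mean_relative_abundance",
    character(0)
  )
}

#' Normalize a raw subcellular-location label
#'
#' Collapses the label variants emitted by localization tools (e.g.
#' `"Cellwall"`, `"CellWall"`, `"cell wall"`) onto the canonical closed
#' vocabulary; idempotent on canonical labels. Both `"Unknown"` variants
#' (including "multiple localizations") collapse to `UNKNOWN`.
#'
#' @param raw character vector of raw labels.
#' @param vocab normalization table (named character vector).
#' @return canonical category labels.
#' @export
normalize_location <- function(raw, vocab = location_vocab_default()) {
  key <- gsub("[ _]", "", tolower(raw))
  out <- unname(vocab[key])
  canon <- gsub("[ _]", "", tolower(compartment_categories()))
  miss <- is.na(out)
  out[miss] <- compartment_categories()[match(key[miss], canon)]
  if (anyNA(out)) {
    stop("format error: unrecognized location label(s): ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  }
  out
}

## Canonicalize a CAZyme methods field like "HMM+HotPep" -> "HMM+HOTPEP"
## (sorted, upper-case tokens from {HMM, HOTPEP, DIAMOND}).
normalize_cazy_methods <- function(methods) {
  vapply(strsplit(methods, "[+,;]"), function(tok) {
    tok <- toupper(trimws(tok))
    tok[tok == "HOTPEP"] <- "HOTPEP"
    ok <- tok %in% c("HMM", "HOTPEP", "DIAMOND")
    if (!all(ok) || length(tok) == 0L) {
      stop("format error: unknown CAZyme detection method token(s): ",
           paste(tok[!ok], collapse = ", "))
    }
    paste(sort(unique(tok)), collapse = "+")
  }, character(1))
}

parse_logical <- function(x, what) {
  u <- toupper(x)
  out <- rep(NA, length(x))
  out[u %in% c("TRUE", "T", "1", "Y", "YES")] <- TRUE
  out[u %in% c("FALSE", "F", "0", "N", "NO")] <- FALSE
  if (anyNA(out)) {
    stop("format error: unparseable boolean in field ", what, ": ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

## Exact-round-trip numeric formatting: shortest of %.15g / %.17g that
## re-parses to the identical double.
format_num <- function(x) {
  s <- sprintf("%.15g", x)
  long <- suppressWarnings(as.numeric(s) != x)
  long[is.na(long)] <- FALSE
  s[long] <- sprintf("%.17g", x[long])
  s
}

#' Read a tool-output table
#'
#' Parses one of the documented tab-separated dialects into typed records
#' with normalized vocabulary. `#`-prefixed comment lines and blank lines
#' are ignored; `-` denotes an empty free-text field. The `similarity`
#' kind is the 12-column tabular hit layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore).
#'
#' @param kind one of `r paste(TABLE_KINDS, collapse = ", ")`.
#' @param path file to read.
#' @return data.frame of typed records; for `location` an extra
#'   `location` column holds the canonical category alongside the raw
#'   label.
#' @export
read_table <- function(kind, path) {
  kind <- as.character(kind)[1]
  cols <- table_columns(kind)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols),
      stringsAsFactors = FALSE)
    for (nc in table_numeric(kind)) out[[nc]] <- numeric(0)
    return(finalize_table(kind, out))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- nfield != length(cols)
  if (any(bad)) {
    stop("format error: line ", lineno[which(bad)[1]], " of ", path,
         " has ", nfield[which(bad)[1]], " columns; expected ",
         length(cols), " for kind '", kind, "'")
  }
  m <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  for (nc in table_numeric(kind)) {
    v <- suppressWarnings(as.numeric(out[[nc]]))
    if (anyNA(v)) {
      stop("format error: unparseable numeric field '", nc, "' at line ",
           lineno[which(is.na(v))[1]], " of ", path)
    }
    out[[nc]] <- v
  }
  finalize_table(kind, out)
}

finalize_table <- function(kind, out) {
  if (kind == "location") {
    out$location <- normalize_location(out$raw_location)
    if (length(out$score) && any(out$score < 0)) {
      stop("format error: negative localization score")
    }
  } else if (kind == "signal_peptide") {
    out$method <- tolower(out$method)
    bad <- !out$method %in% sp_methods()
    if (any(bad)) {
      stop("format error: unknown signal-peptide method(s): ",
           paste(unique(out$method[bad]), collapse = ", "))
    }
    out$has_sp <- if (length(out$has_sp)) {
      parse_logical(out$has_sp, "has_sp")
    } else logical(0)
    out$sp_type <- toupper(out$sp_type)
    if (any(!out$sp_type %in% c("SEC", "TAT", "NONE"))) {
      stop("format error: sp_type must be SEC, TAT or NONE")
    }
    if (any((out$sp_type == "NONE") != (!out$has_sp))) {
      stop("integrity error: sp_type == NONE must hold exactly when ",
           "has_sp is false")
    }
    if (anyDuplicated(out[c("protein_id", "method")])) {
      stop("integrity error: more than one signal-peptide call per ",
           "(protein, method)")
    }
  } else if (kind == "annotation") {
    out$descriptor <- sub("^-$", "", out$descriptor)
    out$cog_categories <- sub("^-$", "", out$cog_categories)
    bad <- grepl("[^A-Z]", out$cog_categories)
    if (any(bad)) {
      stop("format error: COG categories must be upper-case letters: ",
           paste(unique(out$cog_categories[bad]), collapse = ", "))
    }
    if (any(!out$source %in% c("gene_caller", "og_mapper"))) {
      stop("format error: annotation source must be gene_caller or ",
           "og_mapper")
    }
  } else if (kind == "cazy") {
    out$class_label <- sub("^-$", "", out$class_label)
    if (length(out$methods)) {
      out$methods <- normalize_cazy_methods(out$methods)
    }
  } else if (kind %in% c("domain", "merops")) {
    if (any(out$evalue <= 0)) stop("format error: e-values must be > 0")
    if (kind == "domain" && any(!nzchar(out$domain_name))) {
      stop("format error: empty domain_name")
    }
  } else if (kind == "similarity") {
    if (any(out$evalue <= 0)) stop("format error: e-values must be > 0")
    int_cols <- c("alignment_length", "mismatches", "gap_opens",
                  "qstart", "qend", "sstart", "send")
    for (ic in int_cols) out[[ic]] <- as.integer(out[[ic]])
  } else if (kind == "abundance") {
    if (any(out$mean_relative_abundance < 0)) {
      stop("format error: abundance must be >= 0")
    }
  } else if (kind == "envelope") {
    out$envelope <- toupper(out$envelope)
    if (any(!out$envelope %in% c("DIDERM", "MONODERM", "ARCHAEAL"))) {
      stop("format error: envelope must be DIDERM, MONODERM or ARCHAEAL")
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a tool-output table
#'
#' Inverse of [read_table()]; a commented header line records the kind,
#' column names and the 1-based inclusive coordinate convention, and
#' numeric fields are printed so that reading the file back reproduces the
#' records exactly.
#'
#' @param kind table kind (see [read_table()]).
#' @param records data.frame of records for that kind.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(kind, records, path) {
  cols <- table_columns(kind)
  out <- records[, cols, drop = FALSE]
  for (nc in table_numeric(kind)) out[[nc]] <- format_num(records[[nc]])
  if (kind == "signal_peptide" && nrow(out)) {
    out$has_sp <- ifelse(records$has_sp, "TRUE", "FALSE")
  }
  for (tc in c("descriptor", "cog_categories", "class_label")) {
    if (tc %in% cols) out[[tc]] <- ifelse(nzchar(out[[tc]]), out[[tc]], "-")
  }
  hdr <- paste0("# kind=", kind, "; columns=", paste(cols, collapse = ","),
                "; coordinates=1-based inclusive")
  body <- if (nrow(out)) {
    do.call(paste, c(unname(as.list(out)), sep = "\t"))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the pipeline outputs
#'
#' Writes the per-protein catalog and per-MAG profile tables
#' (deterministically sorted by MAG then protein id) plus a
#' machine-readable JSON run manifest carrying the package version, seed,
#' configuration hash and per-file row counts. Byte-identical across runs
#' with identical inputs.
#'
#' @param catalog per-protein catalog data.frame (needs `protein_id`,
#'   `mag_id`).
#' @param profiles per-MAG profile data.frame (needs `mag_id`).
#' @param outdir output directory (created if missing).
#' @param config pipeline configuration (hashed into the manifest).
#' @param seed integer seed recorded in the manifest.
#' @return invisible character vector of the files written.
#' @export
write_outputs <- function(catalog, profiles, outdir,
                          config = pipeline_config(), seed = NA) {
  missing_mag <- setdiff(catalog$mag_id, profiles$mag_id)
  if (length(missing_mag)) {
    stop("integrity error: catalog references MAG(s) absent from ",
         "profiles: ", paste(missing_mag, collapse = ", "))
  }
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory ", outdir)
  }
  catalog <- catalog[order(catalog$mag_id, catalog$protein_id), ,
                     drop = FALSE]
  profiles <- profiles[order(profiles$mag_id), , drop = FALSE]
  write_flat <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    for (j in which(num)) out[[j]] <- format_num(df[[j]])
    lines <- c(
      "# magsecretome output; coordinates=1-based inclusive",
      paste(names(df), collapse = "\t"),
      if (nrow(out)) do.call(paste, c(unname(as.list(out)), sep = "\t"))
    )
    writeLines(lines, file)
  }
  f_cat <- file.path(outdir, "protein_catalog.tsv")
  f_prof <- file.path(outdir, "mag_profiles.tsv")
  write_flat(catalog, f_cat)
  write_flat(profiles, f_prof)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "magsecretome",
    version = as.character(utils::packageVersion("magsecretome")),
    seed = seed,
    config_md5 = cfg_hash,
    vocab_version = config$vocab_version,
    files = list(
      protein_catalog = list(name = "protein_catalog.tsv",
                             rows = nrow(catalog)),
      mag_profiles = list(name = "mag_profiles.tsv",
                          rows = nrow(profiles))
    )
  )
  f_man <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(f_cat, f_prof, f_man))
}
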