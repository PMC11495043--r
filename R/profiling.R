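## Per-MAG profile aggregation and cohort statistics: count vectors over
## compartments, enzyme classes and heme classes; >2 SD high-count
## flagging; abundance labelling; the UNK+SP vs extra-cytoplasmic Pearson
## correlation; cohort summary; orthogroup ranking and correlation-
## distance average-linkage clustering with Newick export.

#' Build per-MAG profiles
#'
#' Joins compartment assignments, enzyme calls, heme profiles and the
#' abundance table into one count vector per MAG: the compartment counts
#' from [partition_proteome()], one count per enzyme class, and the heme
#' metrics (multi-heme proteins in EC+OM+CW, multi-heme among UNK+SP,
#' periplasmic and cytoplasmic-membrane proteins with >= 1 motif,
#' secreted cytochromes). MAGs above the abundance cutoff (strictly) are
#' labelled abundant; a MAG missing from the abundance table is labelled
#' not abundant with a warning.
#'
#' @param assignments data.frame from [assign_compartments()].
#' @param enzyme_calls combined enzyme-call data.frame.
#' @param heme_profiles data.frame from [profile_heme_proteins()].
#' @param abundance data.frame from `read_table("abundance", ...)`.
#' @param config a [pipeline_config()].
#' @return data.frame, one row per MAG.
#' @export
build_mag_profiles <- function(assignments, enzyme_calls, heme_profiles,
                               abundance, config = pipeline_config()) {
  prof <- partition_proteome(assignments)
  mags <- prof$mag_id
  fmag <- function(x) factor(x, levels = mags)

  ec_mag <- assignments$mag_id[match(enzyme_calls$protein_id,
                                     assignments$protein_id)]
  for (cls in enzyme_classes()) {
    sel <- enzyme_calls$enzyme_class == cls
    prof[[cls]] <- as.integer(table(fmag(ec_mag[sel])))
  }

  h <- heme_profiles
  sec3 <- h$category %in% c("EXTRACELLULAR", "OUTER_MEMBRANE",
                            "CELL_WALL")
  prof$MULTIHEME_SECRETED <-
    as.integer(table(fmag(h$mag_id[h$is_multiheme & sec3])))
  prof$MULTIHEME_UNK_SP <-
    as.integer(table(fmag(h$mag_id[h$is_multiheme & h$unk_sp])))
  prof$HEME_PP <-
    as.integer(table(fmag(h$mag_id[h$category == "PERIPLASMIC"])))
  prof$HEME_CM <- as.integer(table(fmag(
    h$mag_id[h$category == "CYTOPLASMIC_MEMBRANE"])))
  prof$CYTOCHROME_SECRETED <-
    as.integer(table(fmag(h$mag_id[h$is_cytochrome])))

  ab <- abundance$mean_relative_abundance[match(mags, abundance$mag_id)]
  if (anyNA(ab)) {
    warning("MAG(s) missing from the abundance table treated as not ",
            "abundant: ",
            paste(mags[is.na(ab)], collapse = ", "))
  }
  prof$mean_relative_abundance <- ab
  prof$abundant <- !is.na(ab) & ab > config$abundance_cutoff
  prof
}

#' Flag MAGs with especially high counts
#'
#' Implements the high-count rule used throughout the cohort report: a
#' MAG is flagged for a metric when its count exceeds the cohort mean by
#' more than `flag_sd_multiplier` sample standard deviations (n-1
#' denominator). Strict inequality, so a zero-variance metric flags
#' nothing.
#'
#' @param values named numeric vector of per-MAG counts for one metric.
#' @param config a [pipeline_config()].
#' @return list with `flagged` (names of flagged MAGs), `mean`, `sd`,
#'   `threshold`.
#' @export
flag_high_counts <- function(values, config = pipeline_config()) {
  if (length(values) < 2L) {
    stop("usage error: flagging needs at least two MAGs")
  }
  m <- mean(values)
  s <- stats::sd(values)
  thr <- m + config$flag_sd_multiplier * s
  list(flagged = names(values)[values > thr], mean = m, sd = s,
       threshold = thr)
}

#' Flag every count metric of a profile table
#'
#' Applies [flag_high_counts()] to each requested metric column of the
#' per-MAG profile table.
#'
#' @param profiles data.frame from [build_mag_profiles()].
#' @param metrics character vector of count columns to flag (defaults to
#'   every compartment, enzyme and heme metric).
#' @param config a [pipeline_config()].
#' @return data.frame with one row per (metric, flagged MAG) pair plus an
#'   attribute `"stats"` holding per-metric mean/sd/threshold.
#' @export
flag_profiles <- function(profiles, metrics = NULL,
                          config = pipeline_config()) {
  if (is.null(metrics)) {
    metrics <- intersect(
      c("EC", "OM", "CW", "PP", "CM", "UNK_SP", "EXTRA_CYTOPLASMIC",
        enzyme_classes(), "MULTIHEME_SECRETED", "MULTIHEME_UNK_SP",
        "HEME_PP", "HEME_CM", "CYTOCHROME_SECRETED"),
      names(profiles))
  }
  stats_rows <- list()
  flag_rows <- list()
  for (mt in metrics) {
    v <- stats::setNames(profiles[[mt]], profiles$mag_id)
    f <- flag_high_counts(v, config)
    stats_rows[[mt]] <- data.frame(metric = mt, mean = f$mean, sd = f$sd,
                                   threshold = f$threshold,
                                   n_flagged = length(f$flagged),
                                   stringsAsFactors = FALSE)
    if (length(f$flagged)) {
      flag_rows[[mt]] <- data.frame(metric = mt, mag_id = f$flagged,
                                    flag = "HIGH",
                                    stringsAsFactors = FALSE)
    }
  }
  out <- if (length(flag_rows)) do.call(rbind, flag_rows) else
    data.frame(metric = character(0), mag_id = character(0),
               flag = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stats") <- do.call(rbind, stats_rows)
  out
}

#' Correlate UNK+SP and extra-cytoplasmic counts
#'
#' Pearson product-moment correlation between the per-MAG number of
#' UNK+SP proteins and the per-MAG extra-cytoplasmic total, with the
#' two-sided p-value from the t distribution on n-2 degrees of freedom.
#'
#' @param profiles data.frame with columns `UNK_SP` and
#'   `EXTRA_CYTOPLASMIC` (one row per MAG; >= 3 rows).
#' @return list with `r`, `p`, `n`.
#' @export
correlate_categories <- function(profiles) {
  x <- profiles$UNK_SP
  y <- profiles$EXTRA_CYTOPLASMIC
  if (length(x) < 3L) {
    stop("usage error: correlation needs at least three MAGs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in a count vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort summary table
#'
#' Totals per compartment category with the percentage of proteins
#' carrying signal-peptide support: for the extra-cytoplasmic categories
#' the share called by at least one of the three detectors, for UNKNOWN
#' the share in UNK+SP. Percentages are `NA` for empty categories.
#'
#' @param assignments data.frame from [assign_compartments()].
#' @return data.frame with columns `category`, `n`, `pct_with_sp`.
#' @export
summarize_cohort <- function(assignments) {
  cats <- c(compartment_categories(), "UNK_SP", "EXTRA_CYTOPLASMIC")
  rows <- lapply(cats, function(cat) {
    sel <- switch(cat,
      UNK_SP = assignments$unk_sp,
      EXTRA_CYTOPLASMIC = assignments$is_extra_cytoplasmic,
      assignments$category == cat)
    n <- sum(sel)
    pct <- if (n == 0L) NA_real_ else if (cat == "UNKNOWN") {
      100 * sum(assignments$unk_sp[sel]) / n
    } else {
      100 * sum(assignments$sp_support[sel] >= 1L) / n
    }
    data.frame(category = cat, n = n, pct_with_sp = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build an orthogroup count matrix
#'
#' Cross-tabulates orthogroup membership into a (orthogroup x MAG) count
#' matrix.
#'
#' @param orthogroups data.frame from `read_table("orthogroup", ...)`.
#' @param proteins data.frame with `protein_id`, `mag_id`.
#' @return integer matrix with orthogroup rownames and MAG colnames.
#' @export
og_count_matrix <- function(orthogroups, proteins) {
  mag <- proteins$mag_id[match(orthogroups$protein_id,
                               proteins$protein_id)]
  if (anyNA(mag)) {
    stop("integrity error: orthogroup member(s) not in the proteome: ",
         paste(utils::head(
           orthogroups$protein_id[is.na(mag)], 5), collapse = ", "))
  }
  tab <- table(orthogroups$og_id, mag)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Rank orthogroups by total counts
#'
#' Orders orthogroups by descending sum of counts over a MAG subset,
#' breaking ties by orthogroup id (ascending), and truncates to the top
#' `top_og_n`.
#'
#' @param og_matrix matrix from [og_count_matrix()].
#' @param mag_subset MAG columns to sum over (defaults to all).
#' @param config a [pipeline_config()].
#' @return data.frame with `og_id` and `total`, in rank order.
#' @export
rank_ogs <- function(og_matrix, mag_subset = colnames(og_matrix),
                     config = pipeline_config()) {
  if (length(mag_subset) == 0L) {
    stop("usage error: empty MAG subset")
  }
  missing <- setdiff(mag_subset, colnames(og_matrix))
  if (length(missing)) {
    stop("usage error: MAG(s) not in the matrix: ",
         paste(missing, collapse = ", "))
  }
  tot <- rowSums(og_matrix[, mag_subset, drop = FALSE])
  ord <- order(-tot, rownames(og_matrix))
  out <- data.frame(og_id = rownames(og_matrix)[ord],
                    total = unname(tot[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, config$top_og_n)
}

#' Cluster the orthogroup matrix
#'
#' Reproduces the heatmap clustering recipe: rows are centered and scaled
#' to unit variance; pairwise distances are correlation distances
#' (`1 - Pearson r`); rows and columns are clustered by agglomerative
#' average linkage (UPGMA). A constant row, or a column that is constant
#' after row scaling, has no defined correlation and is an error naming
#' the offender. Dendrograms are returned as `hclust` objects and as
#' Newick strings with merge heights as branch lengths.
#'
#' @param og_matrix numeric matrix (>= 2 rows and columns).
#' @return list with `row_hclust`, `col_hclust`, `row_newick`,
#'   `col_newick`.
#' @export
cluster_og_matrix <- function(og_matrix) {
  if (nrow(og_matrix) < 2L || ncol(og_matrix) < 2L) {
    stop("usage error: clustering needs at least a 2 x 2 matrix")
  }
  rsd <- apply(og_matrix, 1, stats::sd)
  if (any(rsd == 0)) {
    stop("zero-variance row(s): ",
         paste(rownames(og_matrix)[rsd == 0], collapse = ", "))
  }
  scaled <- t(scale(t(og_matrix)))  # center + unit variance per row
  csd <- apply(scaled, 2, stats::sd)
  if (any(csd == 0)) {
    stop("zero-variance column(s) after row scaling: ",
         paste(colnames(og_matrix)[csd == 0], collapse = ", "))
  }
  cor_dist <- function(m) stats::as.dist(1 - stats::cor(t(m)))
  row_h <- stats::hclust(cor_dist(scaled), method = "average")
  col_h <- stats::hclust(cor_dist(t(scaled)), method = "average")
  list(row_hclust = row_h, col_hclust = col_h,
       row_newick = hclust_to_newick(row_h),
       col_newick = hclust_to_newick(col_h))
}

## Newick serialization of an hclust dendrogram with merge heights as
## node heights (branch length = parent height - child height).
hclust_to_newick <- function(h) {
  phy <- ape::as.phylo(h)
  ape::write.tree(phy)
}
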