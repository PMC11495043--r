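## Integration of localization calls and signal-peptide calls into the
## compartment scheme: the seven canonical categories, the UNK+SP class
## (unknown location but a signal peptide called by the primary detector),
## and the extra-cytoplasmic union EC+OM+CW+PP.

#' Assign integrated compartments
#'
#' Combines one location call per protein with its signal-peptide calls
#' and the MAG's cell-envelope type. The category is taken verbatim from
#' the (normalized) location call; `unk_sp` is true exactly when the
#' category is `UNKNOWN` and the primary signal-peptide method calls a
#' signal peptide; `sp_support` counts how many of the (up to three)
#' detectors call one. Compartments incompatible with the envelope
#' (outer-membrane/periplasmic in a monoderm, cell-wall in a diderm) are
#' integrity errors; archaeal envelopes are treated as monoderm.
#'
#' @param locations data.frame from `read_table("location", ...)` — one
#'   row per protein.
#' @param sp_calls data.frame from `read_table("signal_peptide", ...)`.
#' @param envelopes data.frame from `read_table("envelope", ...)` — one
#'   row per MAG.
#' @param proteins data.frame with `protein_id`, `mag_id` giving MAG
#'   membership.
#' @return data.frame with columns `protein_id`, `mag_id`, `category`,
#'   `raw_location`, `unk_sp`, `sp_support`, `is_extra_cytoplasmic`.
#' @export
assign_compartments <- function(locations, sp_calls, envelopes, proteins) {
  if (anyDuplicated(locations$protein_id)) {
    stop("integrity error: more than one location call for protein(s): ",
         paste(unique(locations$protein_id[
           duplicated(locations$protein_id)]), collapse = ", "))
  }
  missing <- setdiff(proteins$protein_id, locations$protein_id)
  if (length(missing)) {
    stop("integrity error: protein(s) without a location call: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- match(proteins$protein_id, locations$protein_id)
  category <- locations$location[idx]
  raw_location <- locations$raw_location[idx]

  env <- envelopes$envelope[match(proteins$mag_id, envelopes$mag_id)]
  if (anyNA(env)) {
    stop("integrity error: MAG(s) without an envelope type: ",
         paste(unique(proteins$mag_id[is.na(env)]), collapse = ", "))
  }
  env_eff <- ifelse(env == "ARCHAEAL", "MONODERM", env)
  bad <- (env_eff == "MONODERM" &
            category %in% c("OUTER_MEMBRANE", "PERIPLASMIC")) |
         (env_eff == "DIDERM" & category == "CELL_WALL")
  if (any(bad)) {
    i <- which(bad)[1]
    stop("integrity error: location ", category[i],
         " is incompatible with envelope ", env[i], " (MAG ",
         proteins$mag_id[i], ", protein ", proteins$protein_id[i], ")")
  }

  sp <- sp_calls[sp_calls$has_sp, , drop = FALSE]
  sp_support <- as.integer(table(factor(sp$protein_id,
                                        levels = proteins$protein_id)))
  primary <- sp$protein_id[sp$method == sp_methods()[1]]
  unk_sp <- category == "UNKNOWN" & proteins$protein_id %in% primary

  data.frame(
    protein_id = proteins$protein_id,
    mag_id = proteins$mag_id,
    category = category,
    raw_location = raw_location,
    unk_sp = unk_sp,
    sp_support = sp_support,
    is_extra_cytoplasmic = category %in% extra_cytoplasmic_categories(),
    stringsAsFactors = FALSE
  )
}

#' Partition a cohort's assignments per MAG
#'
#' Counts, per MAG, the members of every compartment category plus the
#' UNK+SP set and the extra-cytoplasmic union. Category counts sum to the
#' proteome size for every MAG.
#'
#' @param assignments data.frame from [assign_compartments()].
#' @return data.frame with one row per MAG and columns `mag_id`,
#'   `n_proteins`, the seven category counts (`EC`, `OM`, `CW`, `PP`,
#'   `CM`, `CY`, `UNK`), `UNK_SP`, and `EXTRA_CYTOPLASMIC`.
#' @export
partition_proteome <- function(assignments) {
  if (anyDuplicated(assignments$protein_id)) {
    stop("integrity error: protein assigned more than once: ",
         paste(unique(assignments$protein_id[
           duplicated(assignments$protein_id)]), collapse = ", "))
  }
  mags <- sort(unique(assignments$mag_id))
  fmag <- factor(assignments$mag_id, levels = mags)
  fcat <- factor(assignments$category, levels = compartment_categories())
  tab <- table(fmag, fcat)
  out <- data.frame(
    mag_id = mags,
    n_proteins = as.integer(table(fmag)),
    EC = as.integer(tab[, "EXTRACELLULAR"]),
    OM = as.integer(tab[, "OUTER_MEMBRANE"]),
    CW = as.integer(tab[, "CELL_WALL"]),
    PP = as.integer(tab[, "PERIPLASMIC"]),
    CM = as.integer(tab[, "CYTOPLASMIC_MEMBRANE"]),
    CY = as.integer(tab[, "CYTOPLASMIC"]),
    UNK = as.integer(tab[, "UNKNOWN"]),
    UNK_SP = as.integer(tapply(assignments$unk_sp, fmag, sum,
                               default = 0L)),
    stringsAsFactors = FALSE
  )
  out$EXTRA_CYTOPLASMIC <- out$EC + out$OM + out$CW + out$PP
  rownames(out) <- NULL
  out
}
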