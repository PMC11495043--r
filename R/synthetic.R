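## Deterministic synthetic-cohort generator with planted, machine-readable
## ground truth. The generator emulates the statistical structure of a
## real MAG cohort (compartment proportions and per-category signal-
## peptide fractions of a full-scale activated-sludge data set) and the
## tabular dialects of the upstream tools, at a desk-scale default of
## 20 MAGs x 500 proteins. Background sequences are drawn from the 18
## residues excluding C and H, so CxxCH motifs occur exactly where
## planted.

BG_ALPHABET <- setdiff(c("A","D","E","F","G","I","K","L","M","N","P","Q",
                         "R","S","T","V","W","Y","C","H"), c("C", "H"))

#' Cohort generator configuration
#'
#' Defaults are the cohort conditions the generator emulates: compartment
#' fractions (extracellular 1.9%, outer-membrane 1.6%, cell-wall 0.05%,
#' periplasmic 1.6%, cytoplasmic-membrane 19.9%, unknown 36.1% of which
#' 32.3% carry a signal peptide), per-category signal-peptide fractions
#' (81/73/63/67%), and sparse planted enzyme/heme classes (a few proteins
#' per MAG, as secreted catabolic enzymes are in real genomes). Planted
#' compartments respect the envelope type: no outer-membrane/periplasmic
#' proteins in monoderm MAGs, no cell-wall proteins in diderm MAGs.
#'
#' @param n_mags number of MAGs.
#' @param proteins_per_mag proteins per MAG (single count or
#'   `c(min, max)` range).
#' @param envelope_mix fraction of diderm MAGs (the rest are monoderm).
#' @param planted_fractions named list of planted-class fractions; see
#'   defaults. `unknown_with_sp` is the fraction *of unknown-location
#'   proteins* given a primary signal peptide; decoy classes
#'   (`peptidase_housekeeping`, `peptidase_glutathione`,
#'   `peptidase_weak`, `lipase_phod`, `expansion_blocker`,
#'   `expansion_blocker_child`, `cazy_onemethod`, `cazy_gt`,
#'   `cazy_excluded`, `multiheme_plain`, `heme_low`) plant true-negative
#'   evidence the classifiers must reject.
#' @param sp_fractions per-category probability that the primary detector
#'   calls a signal peptide for a secreted protein.
#' @param homology_chain_length chain length for planted homology chains.
#' @param n_seeds seed proteins per expansion class.
#' @param n_ogs orthogroups used for the membership table.
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_mags = 20,
                          proteins_per_mag = 500,
                          envelope_mix = 0.5,
                          planted_fractions = list(),
                          sp_fractions = c(EXTRACELLULAR = 0.81,
                                           OUTER_MEMBRANE = 0.73,
                                           CELL_WALL = 0.63,
                                           PERIPLASMIC = 0.67),
                          homology_chain_length = 3,
                          n_seeds = 4,
                          n_ogs = 30,
                          seed = 1) {
  pf <- list(
    extracellular = 0.019, outer_membrane = 0.016, cell_wall = 0.0005,
    periplasmic = 0.016, cm = 0.199, unknown = 0.361,
    unknown_with_sp = 0.323,
    cazy_gh = 0.008, cazy_cbm = 0.004, cazy_ce = 0.004, cazy_pl = 0.002,
    peptidase_nutrient = 0.006, peptidase_housekeeping = 0.004,
    peptidase_glutathione = 0.001, peptidase_weak = 0,
    lipase = 0.004, lipase_phod = 0.001,
    nuclease = 0.004, rnase = 0.002, nucleotidase = 0.002,
    expansion_blocker = 0.002, expansion_blocker_child = 0.001,
    cazy_onemethod = 0.002, cazy_gt = 0.002, cazy_excluded = 0.001,
    multiheme_cytochrome = 0.004, multiheme_plain = 0.002,
    heme_low = 0.004
  )
  pf[names(planted_fractions)] <- planted_fractions
  bad <- vapply(pf, function(x) !is.numeric(x) || x < 0 || x > 1,
                logical(1))
  if (any(bad)) {
    stop("config error: planted fractions must lie in [0, 1]: ",
         paste(names(pf)[bad], collapse = ", "))
  }
  comp_sum <- pf$extracellular + pf$outer_membrane + pf$cell_wall +
    pf$periplasmic + pf$cm + pf$unknown
  if (comp_sum > 1) {
    stop("config error: compartment fractions sum to ", comp_sum,
         " (> 1)")
  }
  stopifnot(n_mags >= 1, envelope_mix >= 0, envelope_mix <= 1,
            homology_chain_length >= 1, n_seeds >= 1, n_ogs >= 2)
  n_diderm <- round(envelope_mix * n_mags)
  if (n_diderm == 0 && (pf$outer_membrane > 0 || pf$periplasmic > 0)) {
    stop("config error: outer-membrane/periplasmic fractions > 0 but ",
         "no diderm MAGs in the cohort")
  }
  if (n_diderm == n_mags && pf$cell_wall > 0) {
    stop("config error: cell-wall fraction > 0 but no monoderm MAGs in ",
         "the cohort")
  }
  structure(list(n_mags = n_mags, proteins_per_mag = proteins_per_mag,
                 envelope_mix = envelope_mix, planted_fractions = pf,
                 sp_fractions = sp_fractions,
                 homology_chain_length = homology_chain_length,
                 n_seeds = n_seeds, n_ogs = n_ogs, seed = seed),
            class = "cohort_config")
}

## sample() without the length-1 surprise: permute or subsample the
## elements of x regardless of its length.
sample_vec <- function(x, k = length(x)) x[sample.int(length(x), k)]

## Cohort-level largest-remainder allocation of round(frac * total)
## items over groups with the given sizes.
alloc_counts <- function(frac, sizes) {
  if (length(sizes) == 0L || frac == 0) return(integer(length(sizes)))
  tot <- round(frac * sum(sizes))
  base <- floor(frac * sizes)
  rem <- tot - sum(base)
  if (rem > 0) {
    ord <- order(-(frac * sizes - base), seq_along(sizes))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

## Distribute a fixed total over groups proportionally to their
## capacities (largest remainder, never exceeding a capacity).
alloc_total <- function(total, capacity) {
  if (total > sum(capacity)) {
    stop("config error: infeasible fractions (planted classes exceed ",
         "the available protein pool)")
  }
  if (total == 0L || length(capacity) == 0L) {
    return(integer(length(capacity)))
  }
  share <- total * capacity / sum(capacity)
  base <- pmin(floor(share), capacity)
  rem <- total - sum(base)
  while (rem > 0) {
    open <- which(base < capacity)
    ord <- open[order(-(share[open] - base[open]), open)]
    k <- min(rem, length(ord))
    base[ord[seq_len(k)]] <- base[ord[seq_len(k)]] + 1L
    rem <- rem - k
  }
  as.integer(base)
}

rand_seq <- function(len) {
  paste(sample(BG_ALPHABET, len, replace = TRUE), collapse = "")
}

## Insert exactly n CxxCH motifs at non-overlapping positions of a
## background sequence (slots spaced 5 apart so motifs never collide or
## arise spuriously).
plant_motifs <- function(sequence, n) {
  L <- nchar(sequence)
  slots <- seq(1L, L - 4L, by = 5L)
  if (length(slots) < n) {
    stop("config error: sequence too short for ", n, " heme motifs")
  }
  starts <- sort(sample_vec(slots, n))
  ch <- strsplit(sequence, "")[[1]]
  for (s in starts) {
    ch[s] <- "C"
    ch[s + 3L] <- "C"
    ch[s + 4L] <- "H"
  }
  list(sequence = paste(ch, collapse = ""), positions = starts)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces MAG proteomes plus every emulated tool table and the seed
#' databases, together with a per-protein truth manifest. Deterministic
#' given `config$seed`: planted heme proteins contain exactly their
#' manifest number of CxxCH motifs; planted homology chains are realized
#' as similarity rows with e-values below the class cutoffs; planted
#' CAZymes carry multi-method detection; nutrient peptidases carry
#' passing e-values and COG E; decoy classes carry evidence the
#' classifiers must reject.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory: when given, all files (FASTA, tables,
#'   truth manifest JSON, config JSON) are written there.
#' @return list with `proteins`, `tables` (named list of tool tables;
#'   `similarity` is itself a named list per expansion class), `seeds`
#'   (named list of seed-protein data.frames), `truth` (per-protein
#'   manifest data.frame) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  set.seed(config$seed)
  pf <- config$planted_fractions
  n_mags <- config$n_mags
  mags <- sprintf("MAG%04d", seq_len(n_mags))
  n_diderm <- round(config$envelope_mix * n_mags)
  envelope <- sample(c(rep("DIDERM", n_diderm),
                       rep("MONODERM", n_mags - n_diderm)))
  ppm <- config$proteins_per_mag
  n_i <- if (length(ppm) == 2L) {
    sample(ppm[1]:ppm[2], n_mags, replace = TRUE)
  } else rep(as.integer(ppm), n_mags)

  proteins <- data.frame(
    protein_id = unlist(lapply(seq_len(n_mags), function(i) {
      sprintf("%s_P%04d", mags[i], seq_len(n_i[i]))
    })),
    mag_id = rep(mags, n_i),
    stringsAsFactors = FALSE
  )
  N <- nrow(proteins)
  truth <- data.frame(protein_id = proteins$protein_id,
                      mag_id = proteins$mag_id,
                      compartment = "CYTOPLASMIC",
                      unk_sp = FALSE,
                      sp_signalp = FALSE, sp_predtat = FALSE,
                      sp_phobius = FALSE,
                      class = "background",
                      n_heme_motifs = 0L,
                      is_seed_homolog = FALSE,
                      expansion_round = NA_integer_,
                      stringsAsFactors = FALSE)

  ## -- compartments ---------------------------------------------------
  by_mag <- split(seq_len(N), proteins$mag_id)[mags]
  pool <- lapply(by_mag, sample_vec)  # shuffled per-MAG index pools
  take <- function(mag_idx, k) {
    if (k == 0L) return(integer(0))
    if (length(pool[[mag_idx]]) < k) {
      stop("config error: infeasible fractions (per-MAG pool exhausted)")
    }
    out <- pool[[mag_idx]][seq_len(k)]
    pool[[mag_idx]] <<- pool[[mag_idx]][-seq_len(k)]
    out
  }
  ## MAG-level secretion propensity: real cohorts differ strongly in how
  ## much of the proteome each genome secretes (whole phyla are enriched
  ## or depleted), and the UNK+SP share tracks the extra-cytoplasmic
  ## share. A lognormal per-MAG factor applied to the secreted categories
  ## and to the UNK+SP share emulates both the spread and the
  ## correlation; per-(MAG, category) jitter keeps them from being
  ## perfectly collinear.
  propensity <- exp(stats::rnorm(n_mags, 0, 0.8))
  comp_spec <- list(
    EXTRACELLULAR = list(frac = pf$extracellular, env = c("DIDERM",
                                                          "MONODERM")),
    OUTER_MEMBRANE = list(frac = pf$outer_membrane, env = "DIDERM"),
    CELL_WALL = list(frac = pf$cell_wall, env = "MONODERM"),
    PERIPLASMIC = list(frac = pf$periplasmic, env = "DIDERM"),
    CYTOPLASMIC_MEMBRANE = list(frac = pf$cm, env = c("DIDERM",
                                                      "MONODERM")),
    UNKNOWN = list(frac = pf$unknown, env = c("DIDERM", "MONODERM"))
  )
  secreted_cats <- extra_cytoplasmic_categories()
  for (cat in names(comp_spec)) {
    sp <- comp_spec[[cat]]
    idx_el <- which(envelope %in% sp$env)
    w <- if (cat %in% secreted_cats) {
      propensity[idx_el] * exp(stats::rnorm(length(idx_el), 0, 0.15))
    } else rep(1, length(idx_el))
    counts <- alloc_counts(sp$frac, n_i[idx_el] * w)
    counts <- pmin(counts, vapply(pool[idx_el], length, integer(1)))
    for (k in seq_along(idx_el)) {
      got <- take(idx_el[k], counts[k])
      truth$compartment[got] <- cat
    }
  }
  ## UNK+SP subset within each MAG's unknowns, scaled by the same
  ## propensity factor
  for (i in seq_len(n_mags)) {
    unk <- which(truth$compartment == "UNKNOWN" &
                   truth$mag_id == mags[i])
    k <- round(pf$unknown_with_sp * length(unk) * propensity[i] *
                 exp(stats::rnorm(1, 0, 0.15)))
    k <- min(k, length(unk))
    if (k > 0) {
      sel <- sample_vec(unk, k)
      truth$unk_sp[sel] <- TRUE
      truth$sp_signalp[sel] <- TRUE
    }
  }

  ## -- planted functional classes (from the secreted pool) -------------
  secreted <- which(truth$compartment %in% extra_cytoplasmic_categories() |
                      truth$unk_sp)
  sec_pool <- lapply(mags, function(m) {
    sample_vec(secreted[truth$mag_id[secreted] == m])
  })
  other <- setdiff(which(truth$compartment %in%
                           c("CYTOPLASMIC", "CYTOPLASMIC_MEMBRANE")),
                   secreted)
  oth_pool <- lapply(mags, function(m) {
    sample_vec(other[truth$mag_id[other] == m])
  })
  take_pool <- function(pool_list, counts) {
    got <- integer(0)
    for (k in seq_along(counts)) {
      if (counts[k] == 0L) next
      if (length(pool_list[[k]]) < counts[k]) {
        stop("config error: infeasible fractions (planted classes ",
             "exceed the available protein pool)")
      }
      got <- c(got, pool_list[[k]][seq_len(counts[k])])
      pool_list[[k]] <- pool_list[[k]][-seq_len(counts[k])]
    }
    list(got = got, pool = pool_list)
  }
  sec_classes <- c("cazy_gh", "cazy_cbm", "cazy_ce", "cazy_pl",
                   "peptidase_nutrient", "peptidase_housekeeping",
                   "peptidase_glutathione", "peptidase_weak",
                   "lipase", "lipase_phod",
                   "nuclease", "rnase", "nucleotidase",
                   "expansion_blocker",
                   "multiheme_cytochrome", "multiheme_plain", "heme_low")
  oth_classes <- c("expansion_blocker_child", "cazy_onemethod",
                   "cazy_gt", "cazy_excluded")
  ## fractions are fractions of the proteome; the proteins themselves
  ## are drawn from the secreted (or, for decoys, cytoplasmic) pool,
  ## proportionally to what each MAG's pool can host
  for (cls in sec_classes) {
    counts <- alloc_total(round(pf[[cls]] * N),
                          vapply(sec_pool, length, integer(1)))
    r <- take_pool(sec_pool, counts)
    sec_pool <- r$pool
    truth$class[r$got] <- cls
  }
  for (cls in oth_classes) {
    counts <- alloc_total(round(pf[[cls]] * N),
                          vapply(oth_pool, length, integer(1)))
    r <- take_pool(oth_pool, counts)
    oth_pool <- r$pool
    truth$class[r$got] <- cls
  }

  ## -- sequences -------------------------------------------------------
  lens <- sample(120:400, N, replace = TRUE)
  seqs <- vapply(lens, rand_seq, character(1))
  heme_n <- integer(N)
  heme_idx <- which(truth$class %in% c("multiheme_cytochrome",
                                       "multiheme_plain", "heme_low"))
  for (i in heme_idx) {
    n_m <- switch(truth$class[i],
                  multiheme_cytochrome = sample(4:9, 1),
                  multiheme_plain = sample(4:6, 1),
                  heme_low = sample(1:3, 1))
    pm <- plant_motifs(seqs[i], n_m)
    seqs[i] <- pm$sequence
    heme_n[i] <- n_m
  }
  truth$n_heme_motifs <- heme_n
  proteins$sequence <- seqs
  proteins$length <- nchar(seqs)

  ## -- location table --------------------------------------------------
  raw_label <- c(EXTRACELLULAR = "Extracellular",
                 OUTER_MEMBRANE = "OuterMembrane",
                 CELL_WALL = "CellWall",
                 PERIPLASMIC = "Periplasmic",
                 CYTOPLASMIC_MEMBRANE = "CytoplasmicMembrane",
                 CYTOPLASMIC = "Cytoplasmic",
                 UNKNOWN = "Unknown")
  location <- data.frame(
    protein_id = proteins$protein_id,
    raw_location = unname(raw_label[truth$compartment]),
    score = round(runif(N, 7.5, 10), 2),
    stringsAsFactors = FALSE)
  location$location <- normalize_location(location$raw_location)

  ## -- signal peptides --------------------------------------------------
  spf <- config$sp_fractions
  is_sec_cat <- truth$compartment %in% names(spf)
  p_primary <- ifelse(is_sec_cat, spf[truth$compartment], 0)
  primary <- runif(N) < p_primary
  primary[truth$unk_sp] <- TRUE
  truth$sp_signalp <- primary
  truth$sp_predtat <- primary & runif(N) < 0.85
  truth$sp_phobius <- primary & runif(N) < 0.80
  sp_scope <- which(is_sec_cat | truth$compartment == "UNKNOWN")
  sp_type_of <- function(has) ifelse(has,
                                     ifelse(runif(length(has)) < 0.9,
                                            "SEC", "TAT"), "NONE")
  signal_peptide <- do.call(rbind, lapply(sp_methods(), function(m) {
    has <- truth[[paste0("sp_", m)]][sp_scope]
    data.frame(protein_id = proteins$protein_id[sp_scope], method = m,
               has_sp = has, sp_type = sp_type_of(has),
               stringsAsFactors = FALSE)
  }))

  ## -- annotations / domains / cazy / merops ----------------------------
  gc_desc <- rep("hypothetical protein", N)
  og_desc <- rep("", N)
  cogs <- rep("", N)
  dom_rows <- list()
  cazy_rows <- list()
  merops_rows <- list()
  add_dom <- function(i, name) {
    dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
      protein_id = proteins$protein_id[i], domain_name = name,
      evalue = 10^-runif(1, 4, 8), stringsAsFactors = FALSE)
  }
  nuc_rules <- load_domain_rules("NUCLEASE")
  rna_rules <- load_domain_rules("RNASE")
  ntd_rules <- load_domain_rules("NUCLEOTIDASE")
  lip_rules <- load_domain_rules("LIPASE")
  cazy_fams <- list(cazy_gh = c("GH13", "GH5", "GH3", "GH16"),
                    cazy_cbm = c("CBM48", "CBM6"),
                    cazy_ce = c("CE1", "CE4"),
                    cazy_pl = c("PL9", "PL1"))
  cazy_labels <- list(cazy_gh = "Alpha-amylase",
                      cazy_cbm = "Starch-binding module",
                      cazy_ce = "Acetyl xylan esterase",
                      cazy_pl = "Pectate lyase")
  mh_rule <- 0L
  lip_route_seed <- TRUE
  for (i in seq_len(N)) {
    cls <- truth$class[i]
    if (cls == "background") next
    pid <- proteins$protein_id[i]
    if (cls %in% names(cazy_fams)) {
      fam <- sample(cazy_fams[[cls]], 1)
      meth <- paste(sort(sample(c("HMM", "HOTPEP", "DIAMOND"),
                                sample(2:3, 1))), collapse = "+")
      cazy_rows[[length(cazy_rows) + 1L]] <- data.frame(
        protein_id = pid, family = fam, methods = meth,
        class_label = cazy_labels[[cls]], stringsAsFactors = FALSE)
    } else if (cls == "cazy_onemethod") {
      cazy_rows[[length(cazy_rows) + 1L]] <- data.frame(
        protein_id = pid, family = "GH13", methods = "HMM",
        class_label = "Alpha-amylase", stringsAsFactors = FALSE)
    } else if (cls == "cazy_gt") {
      cazy_rows[[length(cazy_rows) + 1L]] <- data.frame(
        protein_id = pid, family = "GT2",
        methods = "DIAMOND+HMM+HOTPEP",
        class_label = "Glycoside transferases",
        stringsAsFactors = FALSE)
    } else if (cls == "cazy_excluded") {
      cazy_rows[[length(cazy_rows) + 1L]] <- data.frame(
        protein_id = pid, family = "CE4", methods = "HMM+HOTPEP",
        class_label = "Peptidoglycan-N-acetylmuramic_acid_deacetylase_PdaC",
        stringsAsFactors = FALSE)
    } else if (cls %in% c("peptidase_nutrient", "peptidase_housekeeping",
                          "peptidase_glutathione", "peptidase_weak")) {
      fam <- sample(c("M4", "S8", "M23"), 1)
      ev <- if (cls == "peptidase_weak") 1e-15 else 10^-runif(1, 21, 30)
      merops_rows[[length(merops_rows) + 1L]] <- data.frame(
        protein_id = pid, merops_family = fam, evalue = ev,
        stringsAsFactors = FALSE)
      gc_desc[i] <- "peptidase"
      if (cls == "peptidase_housekeeping") {
        cogs[i] <- sample(c("M", "O", "EM"), 1)
        og_desc[i] <- "cell wall biogenesis peptidase"
      } else {
        cogs[i] <- "E"
        og_desc[i] <- if (cls == "peptidase_glutathione")
          "Glutathione hydrolase" else
            paste("peptidase family", fam)
      }
    } else if (cls %in% c("lipase", "lipase_phod")) {
      add_dom(i, sample(lip_rules$accept_domains, 1))
      if (cls == "lipase_phod") {
        add_dom(i, "PhoD")
      } else if (!lip_route_seed) {
        gc_desc[i] <- sample(lip_rules$annotation_include_keywords, 1)
      }
      if (cls == "lipase") lip_route_seed <- !lip_route_seed
    } else if (cls == "nuclease") {
      add_dom(i, sample(nuc_rules$accept_domains, 1))
    } else if (cls == "rnase") {
      add_dom(i, sample(rna_rules$accept_domains, 1))
    } else if (cls == "nucleotidase") {
      add_dom(i, sample(ntd_rules$accept_domains, 1))
    } else if (cls == "expansion_blocker") {
      add_dom(i, "DUF1234")
    } else if (cls == "multiheme_cytochrome") {
      mh_rule <- mh_rule %% 4L + 1L
      if (mh_rule == 1L) {
        gc_desc[i] <- "cytochrome c peroxidase"
      } else if (mh_rule == 2L) {
        og_desc[i] <- sample(c("cytochrome b subunit",
                               "denitrification protein NirS"), 1)
      } else if (mh_rule == 3L) {
        add_dom(i, sample(c("Cytochrom_C", "decahem",
                            "nanowire_3heme"), 1))
      } else {
        og_desc[i] <- "heat shock protein"
      }
    }
  }
  annotation <- rbind(
    data.frame(protein_id = proteins$protein_id, source = "gene_caller",
               descriptor = gc_desc, cog_categories = "",
               stringsAsFactors = FALSE),
    data.frame(protein_id = proteins$protein_id, source = "og_mapper",
               descriptor = og_desc, cog_categories = cogs,
               stringsAsFactors = FALSE))
  domain <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(protein_id = character(0), domain_name = character(0),
               evalue = numeric(0), stringsAsFactors = FALSE)
  cazy <- if (length(cazy_rows)) do.call(rbind, cazy_rows) else
    data.frame(protein_id = character(0), family = character(0),
               methods = character(0), class_label = character(0),
               stringsAsFactors = FALSE)
  merops <- if (length(merops_rows)) do.call(rbind, merops_rows) else
    data.frame(protein_id = character(0), merops_family = character(0),
               evalue = numeric(0), stringsAsFactors = FALSE)

  ## -- seed databases and similarity tables ----------------------------
  seed_prefix <- c(nuclease = "NUCSEED", rnase = "RNASEED",
                   nucleotidase = "NTDSEED", lipase = "LIPSEED")
  seeds <- lapply(names(seed_prefix), function(cl) {
    data.frame(
      protein_id = sprintf("%s_%02d", seed_prefix[[cl]],
                           seq_len(config$n_seeds)),
      mag_id = NA_character_,
      sequence = vapply(sample(150:300, config$n_seeds, replace = TRUE),
                        rand_seq, character(1)),
      stringsAsFactors = FALSE)
  })
  names(seeds) <- names(seed_prefix)
  for (nm in names(seeds)) seeds[[nm]]$length <- nchar(seeds[[nm]]$sequence)

  sim_row <- function(q, s, emin, emax) {
    al <- sample(80:200, 1)
    mm <- sample(10:60, 1)
    data.frame(query_id = q, subject_id = s,
               percent_identity = round(runif(1, 30, 80), 1),
               alignment_length = al, mismatches = mm,
               gap_opens = sample(0:4, 1),
               qstart = 1L, qend = al, sstart = 1L, send = al,
               evalue = 10^-runif(1, emin, emax),
               bitscore = round(runif(1, 80, 300), 1),
               stringsAsFactors = FALSE)
  }
  similarity <- list()
  L <- config$homology_chain_length
  blockers <- which(truth$class == "expansion_blocker")
  blocker_class <- rep(c("nuclease", "rnase", "nucleotidase"),
                       length.out = length(blockers))
  blocker_children <- which(truth$class == "expansion_blocker_child")
  for (cl in c("nuclease", "rnase", "nucleotidase")) {
    rows <- list()
    members <- which(truth$class == cl)
    if (length(members)) {
      chain_id <- ceiling(seq_along(members) / L)
      pos <- (seq_along(members) - 1L) %% L + 1L
      for (k in seq_along(members)) {
        i <- members[k]
        subj <- if (pos[k] == 1L) {
          sample(seeds[[cl]]$protein_id, 1)
        } else {
          proteins$protein_id[members[k - 1L]]
        }
        rows[[length(rows) + 1L]] <-
          sim_row(proteins$protein_id[i], subj, 15, 30)
        truth$is_seed_homolog[i] <- TRUE
        truth$expansion_round[i] <- pos[k]
      }
    }
    bl <- blockers[blocker_class == cl]
    for (i in bl) {
      rows[[length(rows) + 1L]] <-
        sim_row(proteins$protein_id[i],
                sample(seeds[[cl]]$protein_id, 1), 15, 30)
    }
    ## children hit only a (never-accepted) blocker: must not propagate
    if (length(bl)) {
      kids <- blocker_children[seq_along(blocker_children) %%
                                 3L + 1L == match(cl, c("nuclease",
                                                        "rnase",
                                                        "nucleotidase"))]
      for (i in kids) {
        rows[[length(rows) + 1L]] <-
          sim_row(proteins$protein_id[i],
                  proteins$protein_id[sample_vec(bl, 1)], 15, 30)
      }
    }
    ## decoy hits far above the cutoff
    far <- sample_vec(which(truth$class == "background"),
                      min(3L, sum(truth$class == "background")))
    for (i in far) {
      rows[[length(rows) + 1L]] <-
        sim_row(proteins$protein_id[i],
                sample(seeds[[cl]]$protein_id, 1), 1, 3)
    }
    similarity[[cl]] <- if (length(rows)) do.call(rbind, rows) else
      read_table_empty("similarity")
  }
  ## lipase: single-pass hits for seed-route lipases and the PhoD decoy
  rows <- list()
  lip_members <- which(truth$class %in% c("lipase", "lipase_phod"))
  lip_seed_route <- rep(c(TRUE, FALSE),
                        length.out = sum(truth$class == "lipase"))
  li <- 0L
  for (i in lip_members) {
    hit <- if (truth$class[i] == "lipase_phod") TRUE else {
      li <- li + 1L
      lip_seed_route[li]
    }
    if (hit) {
      rows[[length(rows) + 1L]] <-
        sim_row(proteins$protein_id[i],
                sample(seeds$lipase$protein_id, 1), 6, 12)
    }
  }
  far <- sample_vec(which(truth$class == "background"),
                    min(3L, sum(truth$class == "background")))
  for (i in far) {
    rows[[length(rows) + 1L]] <-
      sim_row(proteins$protein_id[i],
              sample(seeds$lipase$protein_id, 1), 1, 3)
  }
  similarity$lipase <- if (length(rows)) do.call(rbind, rows) else
    read_table_empty("similarity")

  ## -- orthogroups (MAG-structured so clustering has signal) ------------
  og_scope <- which(truth$compartment %in%
                      extra_cytoplasmic_categories() | truth$unk_sp)
  centers <- ((match(truth$mag_id[og_scope], mags) - 1L) %% 5L) * 6L + 3L
  og_idx <- vapply(centers, function(cc) {
    w <- stats::dnorm(seq_len(config$n_ogs), cc, 4)
    sample(config$n_ogs, 1, prob = w)
  }, integer(1))
  orthogroup <- data.frame(
    og_id = sprintf("OG%04d", og_idx),
    protein_id = proteins$protein_id[og_scope],
    stringsAsFactors = FALSE)

  abundance <- data.frame(
    mag_id = mags,
    mean_relative_abundance = round(10^runif(n_mags, -2, 0.5), 4),
    stringsAsFactors = FALSE)
  envelope_tab <- data.frame(mag_id = mags, envelope = envelope,
                             stringsAsFactors = FALSE)

  cohort <- list(
    proteins = proteins,
    tables = list(location = location, signal_peptide = signal_peptide,
                  domain = domain, annotation = annotation, cazy = cazy,
                  merops = merops, similarity = similarity,
                  orthogroup = orthogroup, abundance = abundance,
                  envelope = envelope_tab),
    seeds = seeds,
    truth = truth,
    config = config
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a generated cohort to a directory
#'
#' Emits the proteome FASTA, the four seed-database FASTAs, every tool
#' table in its dialect, the truth manifest (JSON) and the generator
#' configuration (JSON).
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(cohort$proteins, file.path(dir, "proteins.fasta"))
  for (cl in names(cohort$seeds)) {
    write_fasta(cohort$seeds[[cl]],
                file.path(dir, paste0("seeds_", cl, ".fasta")))
  }
  for (kind in c("location", "signal_peptide", "domain", "annotation",
                 "cazy", "merops", "orthogroup", "abundance",
                 "envelope")) {
    write_table(kind, cohort$tables[[kind]],
                file.path(dir, paste0(kind, ".tsv")))
  }
  for (cl in names(cohort$tables$similarity)) {
    write_table("similarity", cohort$tables$similarity[[cl]],
                file.path(dir, paste0("similarity_", cl, ".tsv")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()] (the truth manifest is reloaded too, when
#' present).
#'
#' @param dir directory written by [write_cohort()].
#' @return cohort list as from [generate_cohort()] (without `config`).
#' @export
read_cohort_dir <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  seed_files <- list.files(dir, pattern = "^seeds_.*\\.fasta$")
  seeds <- lapply(seed_files, function(f) {
    read_fasta(file.path(dir, f))
  })
  names(seeds) <- sub("^seeds_(.*)\\.fasta$", "\\1", seed_files)
  tables <- lapply(stats::setNames(nm = c("location", "signal_peptide",
                                          "domain", "annotation", "cazy",
                                          "merops", "orthogroup",
                                          "abundance", "envelope")),
                   function(kind) {
                     read_table(kind, file.path(dir,
                                                paste0(kind, ".tsv")))
                   })
  sim_files <- list.files(dir, pattern = "^similarity_.*\\.tsv$")
  tables$similarity <- lapply(sim_files, function(f) {
    read_table("similarity", file.path(dir, f))
  })
  names(tables$similarity) <- sub("^similarity_(.*)\\.tsv$", "\\1",
                                  sim_files)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    as.data.frame(jsonlite::read_json(truth_path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else NULL
  list(proteins = proteins, tables = tables, seeds = seeds,
       truth = truth)
}

#' Evaluate planted-truth recovery
#'
#' Compares a pipeline catalog against the truth manifest of the cohort
#' it was computed from, reporting precision and recall per planted
#' class: every compartment category, UNK+SP, each CAZyme subtype,
#' nutrient peptidases, lipases, the three expansion classes and
#' multi-heme cytochromes. An empty class (no planted positives and no
#' calls) scores 1/1. With noise-free generator settings every class
#' reports precision = recall = 1.
#'
#' @param truth truth manifest from [generate_cohort()].
#' @param catalog catalog data.frame from [run_secretome_pipeline()].
#' @return data.frame with `class`, `n_truth`, `n_called`, `tp`,
#'   `precision`, `recall`.
#' @export
evaluate_recovery <- function(truth, catalog) {
  if (nrow(truth) == 0L && nrow(catalog) == 0L) {
    return(data.frame(class = character(0), n_truth = integer(0),
                      n_called = integer(0), tp = integer(0),
                      precision = numeric(0), recall = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!setequal(truth$protein_id, catalog$protein_id)) {
    stop("integrity error: truth manifest and catalog protein ids ",
         "differ")
  }
  cat_at <- catalog[match(truth$protein_id, catalog$protein_id), ,
                    drop = FALSE]
  sets <- list()
  for (cc in compartment_categories()) {
    sets[[paste0("compartment_", cc)]] <-
      list(truth = truth$compartment == cc, called = cat_at$category == cc)
  }
  sets$unk_sp <- list(truth = truth$unk_sp, called = cat_at$unk_sp)
  enz_map <- c(cazy_gh = "CAZY_GH", cazy_cbm = "CAZY_CBM",
               cazy_ce = "CAZY_CE", cazy_pl = "CAZY_PL",
               peptidase_nutrient = "PEPTIDASE_NUTRIENT",
               lipase = "LIPASE", nuclease = "NUCLEASE",
               rnase = "RNASE", nucleotidase = "NUCLEOTIDASE")
  for (tc in names(enz_map)) {
    col <- tolower(enz_map[[tc]])
    sets[[col]] <- list(truth = truth$class == tc,
                        called = cat_at[[col]])
  }
  sets$multiheme_cytochrome <- list(
    truth = truth$class == "multiheme_cytochrome",
    called = cat_at$is_multiheme & cat_at$is_cytochrome)
  rows <- lapply(names(sets), function(nm) {
    tr <- sets[[nm]]$truth
    ca <- sets[[nm]]$called
    tp <- sum(tr & ca)
    data.frame(class = nm, n_truth = sum(tr), n_called = sum(ca),
               tp = tp,
               precision = if (sum(ca) == 0L) 1 else tp / sum(ca),
               recall = if (sum(tr) == 0L) 1 else tp / sum(tr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
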