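cfg <- pipeline_config()

cazy_row <- function(id, family, methods, label = "Alpha-amylase") {
  data.frame(protein_id = id, family = family, methods = methods,
             class_label = label, stringsAsFactors = FALSE)
}

test_that("CAZyme filtering applies the method and exclusion rules", {
  cz <- rbind(
    cazy_row("p1", "GH13", "HMM+HOTPEP"),           # accepted
    cazy_row("p2", "GH13", "HMM"),                  # one method: dropped
    cazy_row("p3", "GT2", "DIAMOND+HMM+HOTPEP",
             "Glycoside transferases"),             # GT: dropped
    cazy_row("p4", "CE4", "HMM+HOTPEP",
             "Peptidoglycan-N-acetylmuramic_acid_deacetylase_PdaC"),
    cazy_row("p5", "CBM48", "DIAMOND+HOTPEP"),
    cazy_row("p6", "PL9", "DIAMOND+HMM"),
    cazy_row("p7", "CE1", "HMM+HOTPEP"))
  out <- filter_cazymes(cz, cfg)
  expect_setequal(out$protein_id, c("p1", "p5", "p6", "p7"))
  expect_equal(out$enzyme_class[out$protein_id == "p1"], "CAZY_GH")
  expect_equal(out$enzyme_class[out$protein_id == "p5"], "CAZY_CBM")
  expect_equal(out$enzyme_class[out$protein_id == "p6"], "CAZY_PL")
  expect_equal(out$enzyme_class[out$protein_id == "p7"], "CAZY_CE")

  expect_error(filter_cazymes(cazy_row("p8", "ZZ9", "HMM+HOTPEP"), cfg),
               "family grammar")
  # min-methods is configurable
  out1 <- filter_cazymes(cz, pipeline_config(cazy_min_methods = 1))
  expect_true("p2" %in% out1$protein_id)
})

merops_row <- function(id, e, fam = "M4") {
  data.frame(protein_id = id, merops_family = fam, evalue = e,
             stringsAsFactors = FALSE)
}
ann_row <- function(id, cogs, desc = "peptidase", src = "og_mapper") {
  data.frame(protein_id = id, source = src, descriptor = desc,
             cog_categories = cogs, stringsAsFactors = FALSE)
}

test_that("peptidase filtering enforces e-value, COG-E and exclusions", {
  hits <- rbind(merops_row("p1", 1e-25), merops_row("p2", 1e-25),
                merops_row("p3", 1e-15), merops_row("p4", 1e-25),
                merops_row("p5", 1e-25))
  ann <- rbind(ann_row("p1", "E"), ann_row("p2", "M"),
               ann_row("p3", "E"),
               ann_row("p4", "E", "Glutathione hydrolase"),
               ann_row("p5", "EM"))
  out <- classify_peptidases(hits, ann, cfg)
  expect_equal(out$protein_id, "p1")
  expect_equal(out$enzyme_class, "PEPTIDASE_NUTRIENT")
  # relaxed COG mode keeps the multi-letter assignment containing E
  out2 <- classify_peptidases(hits, ann,
                              pipeline_config(cog_mode = "contains"))
  expect_setequal(out2$protein_id, c("p1", "p5"))
  # the best (minimum) e-value per protein decides
  multi <- rbind(merops_row("p6", 1e-5), merops_row("p6", 1e-25))
  expect_equal(classify_peptidases(multi, ann_row("p6", "E"),
                                   cfg)$protein_id, "p6")
  # a hit without an annotation row is excluded, not fatal
  expect_message(
    out3 <- classify_peptidases(merops_row("p9", 1e-25), ann, cfg),
    "without an annotation")
  expect_equal(nrow(out3), 0L)
})

sim_hit <- function(q, s, e) {
  data.frame(query_id = q, subject_id = s, percent_identity = 50,
             alignment_length = 100L, mismatches = 40L, gap_opens = 1L,
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = e, bitscore = 100, stringsAsFactors = FALSE)
}
dom_hit <- function(id, name) {
  data.frame(protein_id = id, domain_name = name, evalue = 1e-6,
             stringsAsFactors = FALSE)
}

test_that("lipase classification combines routes, domains and the PhoD veto", {
  ann <- rbind(
    ann_row("p2", "", "Multifunctional_esterase", src = "gene_caller"),
    ann_row("p4", "", "hypothetical protein", src = "gene_caller"))
  doms <- rbind(dom_hit("p1", "Lipase_3"), dom_hit("p2", "Abhydrolase"),
                dom_hit("p3", "Lipase_3"), dom_hit("p3", "PhoD"))
  hits <- rbind(sim_hit("p1", "LIPSEED_01", 1e-7),
                sim_hit("p3", "LIPSEED_01", 1e-7),
                sim_hit("p4", "LIPSEED_01", 1e-7),   # no lipase domain
                sim_hit("p5", "LIPSEED_01", 1e-2))   # above cutoff
  out <- classify_lipases(hits, ann, doms, cfg)
  expect_setequal(out$protein_id, c("p1", "p2"))
  expect_equal(out$evidence[out$protein_id == "p1"], "route=seed")
  expect_equal(out$evidence[out$protein_id == "p2"], "route=keyword")
  # PhoD vetoes p3 despite seed hit + accept domain
  expect_false("p3" %in% out$protein_id)
})

test_that("iterative expansion walks chains and blocks domain-negatives", {
  rules <- load_domain_rules("NUCLEASE")
  doms <- rbind(dom_hit("A", "SNase"), dom_hit("B", "endonuclease"))
  # chain seed -> A -> B, each hit linking only to its predecessor
  hits <- rbind(sim_hit("A", "S1", 1e-20), sim_hit("B", "A", 1e-20))
  out <- iterative_expansion("S1", NULL, rules, doms, cfg, hits = hits)
  expect_equal(out$protein_id, c("A", "B"))
  expect_equal(out$iteration, c(1L, 2L))

  # A domain-negative hit blocks propagation entirely
  doms2 <- dom_hit("B", "endonuclease")  # A has no accept domain
  out2 <- iterative_expansion("S1", NULL, rules, doms2, cfg,
                              hits = hits)
  expect_equal(nrow(out2), 0L)

  # no hits at the cutoff: empty result after round 1
  far <- sim_hit("A", "S1", 1e-3)
  expect_equal(nrow(iterative_expansion("S1", NULL, rules, doms, cfg,
                                        hits = far)), 0L)
  expect_error(iterative_expansion(character(0), NULL, rules, doms,
                                   cfg, hits = hits), "empty seed")
})

test_that("expansion equals the graph-closure oracle on random graphs", {
  rules <- load_domain_rules("RNASE")
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(6:18, 1)
    prots <- paste0("p", seq_len(n))
    seeds <- c("S1", "S2")
    nodes <- c(seeds, prots)
    # random sparse hit graph, mixed e-values around the cutoff
    n_edge <- sample(5:25, 1)
    hits <- do.call(rbind, lapply(seq_len(n_edge), function(k) {
      q <- sample(prots, 1)
      s <- sample(setdiff(nodes, q), 1)
      sim_hit(q, s, 10^-sample(c(3, 8, 12, 20), 1))
    }))
    dpos <- sample(prots, sample.int(n, 1))
    doms <- do.call(rbind, lapply(dpos, dom_hit,
                                  name = "RNase_Sa"))
    got <- iterative_expansion(seeds, NULL, rules, doms, cfg,
                               hits = hits)
    want <- closure_oracle(seeds, hits, dpos,
                           cfg$nuclease_evalue_cutoff *
                             (1 + cfg$evalue_rel_tol))
    expect_setequal(got$protein_id, want$protein_id)
    if (nrow(got)) {
      expect_equal(got$iteration[order(got$protein_id)],
                   want$round[order(want$protein_id)])
      # accepted set grows monotonically with rounds
      expect_true(all(diff(got$iteration) >= 0))
    }
  }
})

test_that("e-value boundary semantics match the cutoff contract", {
  ann <- ann_row("p1", "E")
  expect_equal(nrow(classify_peptidases(merops_row("p1", 1e-20), ann,
                                        cfg)), 1L)
  expect_equal(nrow(classify_peptidases(merops_row("p1", 1.01e-20), ann,
                                        cfg)), 1L)
  expect_equal(nrow(classify_peptidases(merops_row("p1", 1e-19), ann,
                                        cfg)), 0L)
})
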