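make_env <- function(mags, env) {
  data.frame(mag_id = mags, envelope = env, stringsAsFactors = FALSE)
}

test_that("compartment assignment integrates location, SP and envelope", {
  proteins <- data.frame(protein_id = c("p1", "p2", "p3"),
                         mag_id = "m1", stringsAsFactors = FALSE)
  loc <- mini_locations(c("p1", "p2", "p3"),
                        c("Unknown", "Extracellular", "Unknown"))
  sp <- rbind(mini_sp("p1", "signalp", TRUE),
              mini_sp("p1", "predtat", TRUE),
              mini_sp("p3", "phobius", TRUE))
  a <- assign_compartments(loc, sp, make_env("m1", "DIDERM"), proteins)

  # unknown + primary SP => UNK+SP
  expect_true(a$unk_sp[a$protein_id == "p1"])
  expect_equal(a$sp_support[a$protein_id == "p1"], 2L)
  # extracellular without any SP call stays extracellular, no UNK+SP
  expect_equal(a$category[a$protein_id == "p2"], "EXTRACELLULAR")
  expect_false(a$unk_sp[a$protein_id == "p2"])
  expect_equal(a$sp_support[a$protein_id == "p2"], 0L)
  expect_true(a$is_extra_cytoplasmic[a$protein_id == "p2"])
  # unknown + only a non-primary method does NOT make UNK+SP
  expect_false(a$unk_sp[a$protein_id == "p3"])
  expect_equal(a$sp_support[a$protein_id == "p3"], 1L)
})

test_that("envelope-incompatible locations are integrity errors", {
  proteins <- data.frame(protein_id = "p1", mag_id = "m1",
                         stringsAsFactors = FALSE)
  expect_error(
    assign_compartments(mini_locations("p1", "Periplasmic"), empty_sp(),
                        make_env("m1", "MONODERM"), proteins),
    "PERIPLASMIC.*MONODERM")
  expect_error(
    assign_compartments(mini_locations("p1", "CellWall"), empty_sp(),
                        make_env("m1", "DIDERM"), proteins),
    "CELL_WALL.*DIDERM")
  # archaeal envelopes behave as monoderm
  expect_error(
    assign_compartments(mini_locations("p1", "OuterMembrane"),
                        empty_sp(), make_env("m1", "ARCHAEAL"), proteins),
    "OUTER_MEMBRANE")
  # cell wall is fine in archaea
  a <- assign_compartments(mini_locations("p1", "CellWall"), empty_sp(),
                           make_env("m1", "ARCHAEAL"), proteins)
  expect_equal(a$category, "CELL_WALL")
})

test_that("duplicate or missing location calls are integrity errors", {
  proteins <- data.frame(protein_id = c("p1", "p2"), mag_id = "m1",
                         stringsAsFactors = FALSE)
  dup <- mini_locations(c("p1", "p1"), c("Unknown", "Cytoplasmic"))
  expect_error(assign_compartments(dup, empty_sp(),
                                   make_env("m1", "DIDERM"), proteins),
               "more than one location")
  one <- mini_locations("p1", "Unknown")
  expect_error(assign_compartments(one, empty_sp(),
                                   make_env("m1", "DIDERM"), proteins),
               "without a location")
})

test_that("partitioning counts categories and conserves proteome size", {
  proteins <- data.frame(
    protein_id = paste0("p", 1:4), mag_id = "m1",
    stringsAsFactors = FALSE)
  loc <- mini_locations(paste0("p", 1:4),
                        c("Extracellular", "Extracellular", "Unknown",
                          "Cytoplasmic"))
  sp <- mini_sp("p3", "signalp", TRUE)
  a <- assign_compartments(loc, sp, make_env("m1", "DIDERM"), proteins)
  part <- partition_proteome(a)
  expect_equal(part$EC, 2L)
  expect_equal(part$UNK, 1L)
  expect_equal(part$UNK_SP, 1L)
  expect_equal(part$CY, 1L)
  expect_equal(part$EXTRA_CYTOPLASMIC, 2L)
  expect_equal(part$EC + part$OM + part$CW + part$PP + part$CM +
                 part$CY + part$UNK, part$n_proteins)

  expect_equal(nrow(partition_proteome(a[0, ])), 0L)
})

test_that("partition sizes equal an independent recount on a cohort", {
  co <- generate_cohort(cohort_config(n_mags = 4, proteins_per_mag = 80,
                                      seed = 5))
  a <- assign_compartments(co$tables$location, co$tables$signal_peptide,
                           co$tables$envelope, co$proteins)
  part <- partition_proteome(a)
  # brute-force recount from the raw location table
  for (m in part$mag_id) {
    ids <- co$proteins$protein_id[co$proteins$mag_id == m]
    raw <- co$tables$location[co$tables$location$protein_id %in% ids, ]
    expect_equal(part$EC[part$mag_id == m],
                 sum(raw$location == "EXTRACELLULAR"))
    expect_equal(part$UNK[part$mag_id == m],
                 sum(raw$location == "UNKNOWN"))
    expect_equal(part$n_proteins[part$mag_id == m], length(ids))
  }
  # conservation and subset invariants
  expect_equal(part$EC + part$OM + part$CW + part$PP + part$CM +
                 part$CY + part$UNK, part$n_proteins)
  expect_true(all(part$UNK_SP <= part$UNK))
  expect_equal(part$EXTRA_CYTOPLASMIC,
               part$EC + part$OM + part$CW + part$PP)
})
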