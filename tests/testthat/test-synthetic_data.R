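test_that("generation is deterministic given the seed", {
  cfgc <- cohort_config(n_mags = 2, proteins_per_mag = 10, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfgc, dir = d1)
  generate_cohort(cfgc, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the output
  d3 <- withr::local_tempdir()
  generate_cohort(cohort_config(n_mags = 2, proteins_per_mag = 10,
                                seed = 8), dir = d3)
  expect_false(identical(readLines(file.path(d1, "proteins.fasta")),
                         readLines(file.path(d3, "proteins.fasta"))))
})

test_that("planted heme proteins carry exactly their manifest motif count", {
  co <- generate_cohort(cohort_config(n_mags = 4, proteins_per_mag = 120,
                                      seed = 3))
  planted <- which(co$truth$n_heme_motifs > 0)
  expect_gt(length(planted), 0)
  for (i in planted) {
    found <- heme_oracle(co$proteins$sequence[i])
    expect_length(found, co$truth$n_heme_motifs[i])
  }
  # background proteins contain no motifs at all (no C/H off-motif)
  bg <- which(co$truth$n_heme_motifs == 0)
  expect_true(all(vapply(co$proteins$sequence[bg],
                         function(s) length(heme_oracle(s)) == 0L,
                         logical(1))))
})

test_that("envelope constraints are validated and respected", {
  expect_error(cohort_config(envelope_mix = 0),
               "no diderm")
  expect_error(cohort_config(envelope_mix = 1),
               "no monoderm")
  # all-monoderm is fine once OM/PP are not planted
  cfgc <- cohort_config(n_mags = 3, proteins_per_mag = 50,
                        envelope_mix = 0,
                        planted_fractions = list(outer_membrane = 0,
                                                 periplasmic = 0),
                        seed = 2)
  co <- generate_cohort(cfgc)
  expect_false(any(co$truth$compartment %in%
                     c("OUTER_MEMBRANE", "PERIPLASMIC")))
  # planted compartments respect the per-MAG envelope
  co2 <- generate_cohort(cohort_config(n_mags = 6,
                                       proteins_per_mag = 100,
                                       seed = 4))
  env <- co2$tables$envelope
  mono <- env$mag_id[env$envelope == "MONODERM"]
  expect_false(any(co2$truth$compartment[co2$truth$mag_id %in% mono]
                   %in% c("OUTER_MEMBRANE", "PERIPLASMIC")))
  did <- env$mag_id[env$envelope == "DIDERM"]
  expect_false(any(co2$truth$compartment[co2$truth$mag_id %in% did]
                   == "CELL_WALL"))
})

test_that("infeasible fractions are config errors", {
  expect_error(cohort_config(planted_fractions = list(unknown = 0.9,
                                                      cm = 0.2)),
               "sum to")
  expect_error(cohort_config(planted_fractions = list(cazy_gh = -0.1)),
               "\\[0, 1\\]")
  expect_error(
    generate_cohort(cohort_config(
      n_mags = 2, proteins_per_mag = 20, seed = 1,
      planted_fractions = list(extracellular = 0.1, nuclease = 0.5))),
    "config error")
})

test_that("manifest counts equal recomputed counts from generated files", {
  d <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_mags = 3, proteins_per_mag = 80,
                                      seed = 9), dir = d)
  back <- read_cohort_dir(d)
  expect_equal(back$proteins$sequence, co$proteins$sequence)
  # compartment labels in the location table equal the manifest
  loc <- back$tables$location
  expect_equal(loc$location[match(co$truth$protein_id, loc$protein_id)],
               co$truth$compartment)
  # primary SP calls equal the manifest truth
  sp <- back$tables$signal_peptide
  primary <- sp[sp$method == "signalp", ]
  has <- co$truth$protein_id %in% primary$protein_id[primary$has_sp]
  expect_equal(has, co$truth$sp_signalp)
  # planted CAZymes all appear in the cazy table
  cz_truth <- co$truth$protein_id[grepl("^cazy_(gh|cbm|ce|pl)$",
                                        co$truth$class)]
  expect_true(all(cz_truth %in% back$tables$cazy$protein_id))
})

test_that("noise-free recovery is perfect and planned misses are missed", {
  co <- generate_cohort(cohort_config(n_mags = 4, proteins_per_mag = 150,
                                      seed = 21))
  res <- run_secretome_pipeline(co)
  rec <- evaluate_recovery(co$truth, res$catalog)
  expect_true(all(rec$precision == 1))
  expect_true(all(rec$recall == 1))

  # a peptidase planted with a deliberately failing e-value is missed
  co2 <- generate_cohort(cohort_config(
    n_mags = 4, proteins_per_mag = 150, seed = 21,
    planted_fractions = list(peptidase_weak = 0.005)))
  res2 <- run_secretome_pipeline(co2)
  weak <- co2$truth$protein_id[co2$truth$class == "peptidase_weak"]
  expect_gt(length(weak), 0)
  expect_false(any(weak %in%
                     res2$catalog$protein_id[res2$catalog$peptidase_nutrient]))

  # id mismatch between manifest and catalog is an integrity error
  expect_error(evaluate_recovery(co$truth[-1, ], res$catalog),
               "integrity error")
  # empty cohort handling
  expect_equal(nrow(evaluate_recovery(co$truth[0, ],
                                      res$catalog[0, ])), 0L)
})
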