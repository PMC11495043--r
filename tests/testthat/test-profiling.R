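cfg <- pipeline_config()

test_that("high-count flagging reproduces hand-computed thresholds", {
  v <- stats::setNames(c(rep(0, 9), 10), paste0("m", 1:10))
  f <- flag_high_counts(v, cfg)
  expect_equal(f$mean, 1)
  expect_equal(f$sd, sqrt(10), tolerance = 1e-12)
  expect_equal(f$threshold, 1 + 2 * sqrt(10), tolerance = 1e-12)
  expect_equal(f$flagged, "m10")

  v2 <- stats::setNames(c(1, 1, 1, 1, 10), paste0("m", 1:5))
  f2 <- flag_high_counts(v2, cfg)
  expect_equal(f2$threshold, 2.8 + 2 * sd(c(1, 1, 1, 1, 10)),
               tolerance = 1e-12)
  expect_length(f2$flagged, 0L)  # 10 < 10.85

  # all-equal counts: SD 0 and the strict inequality flags nothing
  expect_length(flag_high_counts(stats::setNames(rep(3, 6),
                                                 paste0("m", 1:6)),
                                 cfg)$flagged, 0L)
  expect_error(flag_high_counts(c(m1 = 1), cfg), "at least two")
})

test_that("category correlation matches the closed form", {
  p <- data.frame(UNK_SP = c(1, 2, 3, 4, 5),
                  EXTRA_CYTOPLASMIC = c(2, 4, 6, 8, 10))
  expect_equal(correlate_categories(p)$r, 1, tolerance = 1e-12)
  p$EXTRA_CYTOPLASMIC <- -p$UNK_SP + 7
  expect_equal(correlate_categories(p)$r, -1, tolerance = 1e-12)

  set.seed(31)
  x <- rnorm(25)
  y <- 0.6 * x + rnorm(25)
  p <- data.frame(UNK_SP = x, EXTRA_CYTOPLASMIC = y)
  got <- correlate_categories(p)
  want <- pearson_oracle(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  expect_error(correlate_categories(p[1:2, ]), "at least three")
  p$UNK_SP <- 1
  expect_error(correlate_categories(p), "zero variance")
})

test_that("orthogroup ranking sorts by subset sums with lexicographic ties", {
  m <- matrix(c(3, 1, 1, 1, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("og1", "og2", "og3"), c("mA", "mB")))
  r <- rank_ogs(m, config = cfg)
  expect_equal(r$og_id, c("og1", "og3", "og2"))
  # tied sums break by orthogroup id
  m2 <- matrix(c(1, 1, 1, 1), nrow = 2,
               dimnames = list(c("ogB", "ogA"), c("mA", "mB")))
  expect_equal(rank_ogs(m2, config = cfg)$og_id, c("ogA", "ogB"))
  # subset restriction and truncation
  expect_equal(rank_ogs(m, "mA", pipeline_config(top_og_n = 1))$og_id,
               "og1")
  expect_error(rank_ogs(m, character(0)), "empty MAG subset")
  expect_error(rank_ogs(m, "nope"), "not in the matrix")
  # random matrices agree with a brute-force sort oracle
  set.seed(5)
  for (k in 1:20) {
    mm <- matrix(rpois(24, 2), nrow = 6,
                 dimnames = list(sprintf("og%02d", sample(6)),
                                 paste0("m", 1:4)))
    got <- rank_ogs(mm, config = cfg)$og_id
    sums <- rowSums(mm)
    want <- names(sums)[order(-sums, names(sums))]
    expect_equal(got, want)
  }
})

test_that("correlation-distance clustering matches the linkage oracle", {
  # self-distance 0 and r = -1 distance 2
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                1, 3, 2, 5,
                2, 2, 4, 1,
                5, 1, 1, 2), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("og", 1:5), paste0("m", 1:4)))
  scaled <- t(scale(t(m)))
  D <- 1 - cor(t(scaled))
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(D["og1", "og2"], 2, tolerance = 1e-12)  # affine negation

  cl <- cluster_og_matrix(m)
  expect_equal(sort(cl$row_hclust$height),
               sort(avg_linkage_oracle(as.dist(D))), tolerance = 1e-12)
  # ultrametric: merge heights are non-decreasing
  expect_true(all(diff(cl$row_hclust$height) >= -1e-12))
  # Newick export parses back with matching tip count
  tr <- ape::read.tree(text = cl$row_newick)
  expect_setequal(tr$tip.label, rownames(m))

  # random matrices against the brute-force oracle
  set.seed(13)
  for (k in 1:20) {
    mm <- matrix(rnorm(20), nrow = 5,
                 dimnames = list(paste0("og", 1:5), paste0("m", 1:4)))
    cl <- cluster_og_matrix(mm)
    sc <- t(scale(t(mm)))
    expect_equal(sort(cl$row_hclust$height),
                 sort(avg_linkage_oracle(as.dist(1 - cor(t(sc))))),
                 tolerance = 1e-12)
    expect_equal(sort(cl$col_hclust$height),
                 sort(avg_linkage_oracle(as.dist(1 - cor(sc)))),
                 tolerance = 1e-12)
  }

  # degenerate inputs are named errors
  bad <- m
  bad["og3", ] <- 7
  expect_error(cluster_og_matrix(bad), "og3")
  expect_error(cluster_og_matrix(m[1, , drop = FALSE]), "at least")
})

test_that("profiles count metrics and label abundance strictly", {
  a <- data.frame(
    protein_id = paste0("p", 1:5),
    mag_id = c("m1", "m1", "m1", "m2", "m2"),
    category = c("EXTRACELLULAR", "EXTRACELLULAR", "UNKNOWN",
                 "CYTOPLASMIC", "UNKNOWN"),
    unk_sp = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    sp_support = c(1L, 0L, 1L, 0L, 0L),
    is_extra_cytoplasmic = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  calls <- data.frame(protein_id = "p1", enzyme_class = "CAZY_GH",
                      evidence = "", iteration = NA_integer_,
                      stringsAsFactors = FALSE)
  heme <- data.frame(protein_id = "p2", mag_id = "m1", n_motifs = 5L,
                     motif_positions = "1;7;13;19;25",
                     is_multiheme = TRUE, in_secreted_scope = TRUE,
                     is_cytochrome = TRUE, rule_fired = "PROKKA_NAME",
                     category = "EXTRACELLULAR", unk_sp = FALSE,
                     stringsAsFactors = FALSE)
  ab <- data.frame(mag_id = c("m1", "m2"),
                   mean_relative_abundance = c(0.25, 0.1),
                   stringsAsFactors = FALSE)
  prof <- build_mag_profiles(a, calls, heme, ab, cfg)
  expect_equal(prof$EC, c(2L, 0L))
  expect_equal(prof$UNK_SP, c(1L, 0L))
  expect_equal(prof$CAZY_GH, c(1L, 0L))
  expect_equal(prof$MULTIHEME_SECRETED, c(1L, 0L))
  expect_equal(prof$CYTOCHROME_SECRETED, c(1L, 0L))
  # abundance 0.25 > 0.1 abundant; exactly 0.1 is NOT (strict >)
  expect_equal(prof$abundant, c(TRUE, FALSE))
  # a MAG missing from the abundance table warns and is not abundant
  expect_warning(p2 <- build_mag_profiles(a, calls, heme, ab[1, ], cfg),
                 "not.*abundant|abundant")
  expect_false(p2$abundant[2])
})

test_that("cohort summary reports totals and SP percentages", {
  a <- data.frame(
    protein_id = paste0("p", 1:10),
    mag_id = "m1",
    category = c(rep("EXTRACELLULAR", 5), rep("UNKNOWN", 4),
                 "CYTOPLASMIC"),
    unk_sp = c(rep(FALSE, 5), TRUE, TRUE, FALSE, FALSE, FALSE),
    sp_support = c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L),
    is_extra_cytoplasmic = c(rep(TRUE, 5), rep(FALSE, 5)),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(a)
  expect_equal(s$n[s$category == "EXTRACELLULAR"], 5L)
  expect_equal(s$pct_with_sp[s$category == "EXTRACELLULAR"], 80)
  expect_equal(s$pct_with_sp[s$category == "UNKNOWN"], 50)
  expect_true(is.na(s$pct_with_sp[s$category == "CELL_WALL"]))
  # totals conserve: category rows sum to the proteome size
  cat_rows <- s$category %in% compartment_categories()
  expect_equal(sum(s$n[cat_rows]), nrow(a))
  # empty cohort: zero totals, undefined percentages
  s0 <- summarize_cohort(a[0, ])
  expect_true(all(s0$n == 0L))
  expect_true(all(is.na(s0$pct_with_sp)))
})
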