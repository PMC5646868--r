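make_test_msa <- function(strings, ids = NULL, labels = NULL,
                          query = NULL) {
  seqs <- do.call(rbind, strsplit(strings, ""))
  ids <- ids %||% sprintf("seq%02d", seq_along(strings))
  msa(seqs, ids, labels = labels, query = query %||% ids[1])
}

test_that("aligned FASTA round-trips and ragged input is rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  x <- make_test_msa(c("AC-DE", "AYWDE"))
  write_msa(x, f)
  y <- read_msa(f)
  expect_equal(y$seqs, x$seqs)
  expect_equal(y$ids, x$ids)

  writeLines(c(">a", "ACDE", ">b", "ACD"), f)
  expect_error(read_msa(f), "'b'")

  # '.' gaps and lower case are normalised
  writeLines(c(">a", "ac.de", ">b", "ACDDE"), f)
  z <- read_msa(f)
  expect_equal(paste(z$seqs[1, ], collapse = ""), "AC-DE")
})

test_that("covalent-anchor filtering keeps the query and matching records", {
  x <- make_test_msa(c("AHC", "AHC", "ADC", "AYC", "AHC"))
  # all-His at the anchor: unchanged
  all_h <- filter_covalent_anchor(make_test_msa(c("AHC", "AHC")), 2, "H")
  expect_equal(nrow(all_h$seqs), 2)
  # 2 of 5 lack His -> 3 retained
  got <- filter_covalent_anchor(x, 2, "H")
  expect_equal(nrow(got$seqs), 3)
  # query retained even when it fails the filter
  y <- make_test_msa(c("ADC", "AHC", "AHC"))
  got2 <- filter_covalent_anchor(y, 2, "H")
  expect_true("seq01" %in% got2$ids)
  expect_equal(nrow(got2$seqs), 3)
  # tyrosine anchor for PCMH-like alignments
  got3 <- filter_covalent_anchor(x, 2, c("Y"))
  expect_equal(nrow(got3$seqs), 2)  # query + the one Tyr record
})

test_that("column-to-query mapping skips query-gap columns", {
  gapless <- make_test_msa(c("ACDE", "AAAA"))
  m1 <- map_columns_to_query(gapless)
  expect_equal(m1$col_for_pos, 1:4)

  gapped <- make_test_msa(c("A-CD", "AACD"))
  m2 <- map_columns_to_query(gapped)
  expect_equal(m2$col_for_pos, c(1, 3, 4))
  expect_equal(m2$n_positions, 3)
})

test_that("column similarity scores the dominant group with the gap policy", {
  g <- similarity_groups()
  # pure column
  cs <- column_similarity(rep("F", 100), g)
  expect_equal(cs$group, "aromatic")
  expect_equal(cs$fraction, 1)
  # mixed column: 60 L + 40 D
  cs2 <- column_similarity(c(rep("L", 60), rep("D", 40)), g)
  expect_equal(cs2$group, "aliphatic")
  expect_equal(cs2$fraction, 0.6)
  # tie with gaps counted in the denominator
  cs3 <- column_similarity(c(rep("H", 45), rep("D", 45), rep("-", 10)), g)
  expect_equal(cs3$fraction, 0.45)
  expect_true(cs3$tie)
  expect_equal(cs3$group, "acidic_amide")  # alphabetically first
  # excluding gaps changes the denominator
  cs4 <- column_similarity(c(rep("H", 45), rep("-", 10)), g,
                           gap_policy = "exclude")
  expect_equal(cs4$fraction, 1)
  # non-standard residues belong to no group
  cs5 <- column_similarity(c("X", "B", "Z"), g)
  expect_equal(cs5$fraction, 0)
})

test_that("position categories follow the 50%/90% rules in both modes", {
  # single mode boundaries: 0.90 is similar (strict conserved), 0.50 similar
  expect_equal(categorise_position(list(fraction = 0.90))$category,
               "similar")
  expect_equal(categorise_position(list(fraction = 0.901))$category,
               "conserved")
  expect_equal(categorise_position(list(fraction = 0.50))$category,
               "similar")
  expect_equal(categorise_position(list(fraction = 0.499))$category,
               "dissimilar")

  st <- function(g, f) list(group = g, fraction = f)
  # all three subfamilies 100% basic -> conserved
  all_h <- list(VAO = st("basic", 1), EUGO = st("basic", 1),
                PCMH = st("basic", 1))
  expect_equal(categorise_position(all_h, mode = "merged")$category,
               "conserved")
  # VAO H, EUGO K (same group), PCMH D -> dissimilar + PCMH-unlike
  pu <- list(VAO = st("basic", 1), EUGO = st("basic", 1),
             PCMH = st("acidic_amide", 1))
  got <- categorise_position(pu, mode = "merged")
  expect_equal(got$category, "dissimilar")
  expect_true(got$pcmh_unlike)
  # VAO H, EUGO D, PCMH D -> dissimilar, not PCMH-unlike
  no <- list(VAO = st("basic", 1), EUGO = st("acidic_amide", 1),
             PCMH = st("acidic_amide", 1))
  got2 <- categorise_position(no, mode = "merged")
  expect_equal(got2$category, "dissimilar")
  expect_false(got2$pcmh_unlike)
  # shared group but one subfamily below 90 -> similar, not conserved
  sim <- list(VAO = st("small", 0.95), EUGO = st("small", 0.85),
              PCMH = st("small", 0.95))
  expect_equal(categorise_position(sim, mode = "merged")$category,
               "similar")
  expect_error(categorise_position(list(VAO = st("basic", 1)),
                                   mode = "merged"), "EUGO")
})

test_that("group summaries report category percentages per residue group", {
  sm <- make_synthetic_msa(n_positions = 60,
                           counts = c(VAO = 8, EUGO = 8, PCMH = 8),
                           gap_rate = 0, seed = 51)
  prof <- conservation_profile(sm$msa)
  grp <- group_summary(prof, list(all = 1:60, first10 = 1:10))
  expect_equal(grp$n, c(60, 10))
  want <- 100 * mean(sm$truth$category[1:10] == "conserved")
  expect_equal(grp$pct_conserved[grp$group == "first10"], want)
  expect_error(group_summary(prof, list(bad = 55:70)), "outside")
  expect_error(group_summary(prof, list(none = integer(0))), "empty")
})

test_that("category calls are invariant to record order and monotone in the cutoff", {
  sm <- make_synthetic_msa(n_positions = 40,
                           counts = c(VAO = 10, EUGO = 10, PCMH = 6),
                           gap_rate = 0.05, seed = 52)
  prof <- conservation_profile(sm$msa)

  set.seed(53)
  perm <- sample(nrow(sm$msa$seqs))
  qpos <- which(sm$msa$ids[perm] == sm$msa$query)
  shuffled <- msa(sm$msa$seqs[perm, ], sm$msa$ids[perm],
                  sm$msa$labels[perm], query = sm$msa$query)
  prof2 <- conservation_profile(shuffled)
  expect_equal(prof$category, prof2$category)
  expect_equal(prof$pcmh_unlike, prof2$pcmh_unlike)

  # raising the similar cutoff can only move positions toward dissimilar
  lo <- conservation_profile(sm$msa, similar_cutoff = 0.4)
  hi <- conservation_profile(sm$msa, similar_cutoff = 0.6)
  was_sim <- lo$category %in% c("similar", "conserved")
  now_sim <- hi$category %in% c("similar", "conserved")
  expect_true(all(!now_sim | was_sim))
})

test_that("planted alignment categories are recovered", {
  # noise-free plan: recovery is exact, fractions match the plan exactly
  nf <- make_synthetic_msa(n_positions = 100,
                           counts = c(VAO = 30, EUGO = 30, PCMH = 30),
                           fractions = c(conserved = 0.29, similar = 0.25,
                                         dissimilar = 0.21,
                                         pcmh_unlike = 0.25),
                           gap_rate = 0, seed = 54)
  prof <- conservation_profile(nf$msa)
  called <- ifelse(prof$pcmh_unlike, "pcmh_unlike",
                   as.character(prof$category))
  expect_equal(called, nf$truth$category)
  expect_equal(mean(prof$category == "conserved"), 0.29)
  expect_equal(mean(prof$pcmh_unlike), 0.25)

  # noisy plan (gaps, >= 30 records/subfamily): >= 95% recovery
  nz <- make_synthetic_msa(n_positions = 200,
                           counts = c(VAO = 40, EUGO = 40, PCMH = 30),
                           gap_rate = 0.03, seed = 55)
  profz <- conservation_profile(nz$msa)
  calledz <- ifelse(profz$pcmh_unlike, "pcmh_unlike",
                    as.character(profz$category))
  expect_gte(mean(calledz == nz$truth$category), 0.95)
})

test_that("categories partition positions and PCMH-unlike implies dissimilar", {
  sm <- make_synthetic_msa(n_positions = 80,
                           counts = c(VAO = 12, EUGO = 12, PCMH = 6),
                           gap_rate = 0.04, seed = 56)
  prof <- conservation_profile(sm$msa)
  expect_true(all(prof$category %in%
                    c("conserved", "similar", "dissimilar")))
  expect_true(all(prof$category[prof$pcmh_unlike] == "dissimilar"))
  # pooled merged rule also yields a valid partition
  pooled <- conservation_profile(sm$msa, merged_rule = "pooled")
  expect_true(all(pooled$category[pooled$pcmh_unlike] == "dissimilar"))
})
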