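panel <- mini_panel()
samples <- mini_samples()

test_that("mode consistency follows inheritance, zygosity and sex", {
  cases <- list(
    # male hemizygous LoF in an X-linked known gene qualifies
    list(mini_variant(gene = "XL1", chrom_class = "X", zygosity = "hemi"),
         TRUE),
    # het in a biallelic gene with no second allele does not
    list(mini_variant(gene = "REC1"), FALSE),
    # hom in a biallelic gene does
    list(mini_variant(gene = "REC1", zygosity = "hom"), TRUE),
    # het or hom in a monoallelic gene does
    list(mini_variant(gene = "DOM1"), TRUE),
    list(mini_variant(gene = "DOM1", zygosity = "hom"), TRUE),
    # female het on an X-linked gene does not, by default
    list(mini_variant(sample_id = "S2", gene = "XL1", chrom_class = "X"),
         FALSE)
  )
  for (cs in cases) {
    v <- triage_ready(cs[[1L]])
    expect_identical(mode_consistent(v, panel, samples), cs[[2L]],
                     info = paste(cs[[1L]]$gene, cs[[1L]]$zygosity))
  }
  # per-gene override accepts female het carriers (female-manifesting gene)
  v <- triage_ready(mini_variant(sample_id = "S2", gene = "XL1",
                                 chrom_class = "X"))
  expect_true(mode_consistent(v, panel, samples,
                              female_manifesting_override = "XL1"))
  # comp-het pair satisfies a biallelic gene
  v <- triage_ready(mini_variants(
    mini_variant(gene = "REC1", pos = 1L),
    mini_variant(gene = "REC1", pos = 2L)))
  expect_true(all(mode_consistent(v, panel, samples)))
  expect_error(mode_consistent(triage_ready(mini_variant(gene = "NOPE")),
                               panel, samples), "NOPE")
})

test_that("LoF triage verdicts and reason codes follow the rules", {
  lp <- triage_lof(triage_ready(mini_variant()), panel, samples)
  expect_equal(lp$verdict, "likely_pathogenic")
  expect_equal(lp$pathway, "lof_known_gene")
  expect_equal(lp$reason_codes, "")

  cand <- triage_lof(triage_ready(mini_variant(gene = "CAND1")),
                     panel, samples)
  expect_equal(cand$verdict, "uncertain")
  expect_match(cand$reason_codes, "R_CANDIDATE_GENE")

  single_rec <- triage_lof(triage_ready(mini_variant(gene = "REC1")),
                           panel, samples)
  expect_equal(single_rec$verdict, "uncertain")
  expect_match(single_rec$reason_codes, "R_RECESSIVE_SINGLE_ALLELE")

  shared <- triage_lof(triage_ready(mini_variant(carriers_internal = 2L)),
                       panel, samples)
  expect_equal(shared$verdict, "uncertain")
  expect_match(shared$reason_codes, "R_IN_CONTROLS")

  # control presence is tolerated for biallelic genes
  rec_shared <- triage_lof(
    triage_ready(mini_variant(gene = "REC1", zygosity = "hom",
                              freq_kgp = 0.0001)),
    panel, samples)
  expect_equal(rec_shared$verdict, "likely_pathogenic")

  # non-canonical transcript is flagged
  offtx <- triage_lof(triage_ready(mini_variant(transcript = "TX_ALT")),
                      panel, samples)
  expect_equal(offtx$verdict, "uncertain")
  expect_match(offtx$reason_codes, "R_NOT_CANONICAL_TRANSCRIPT")
})

test_that("missense curation applies its rules in order, first failure only", {
  mk <- function(...) triage_ready(mini_variant(
    consequence = "missense_variant", known_pathogenic = TRUE, ...))

  ok <- triage_missense(mk(), panel, samples)
  expect_equal(ok$verdict, "likely_pathogenic")
  expect_equal(ok$pathway, "missense_known_pathogenic")

  not_kp <- triage_missense(
    triage_ready(mini_variant(consequence = "missense_variant")),
    panel, samples)
  expect_equal(not_kp$verdict, "excluded")
  expect_equal(not_kp$reason_codes, "R_NOT_KNOWN_PATHOGENIC")

  # a record failing rule (i) reports only that rule even when later
  # rules would also fail
  multi_fail <- triage_missense(
    mk(gene = "CAND1", freq_kgp = 0.001, literature_excluded = TRUE),
    panel, samples)
  expect_equal(multi_fail$reason_codes, "R_CANDIDATE_GENE")

  in_controls <- triage_missense(mk(freq_kgp = 0.001), panel, samples)
  expect_equal(in_controls$reason_codes, "R_IN_CONTROLS")

  # control presence tolerated for a biallelic gene with two alleles
  rec_ok <- triage_missense(
    triage_ready(mini_variants(
      mini_variant(gene = "REC1", pos = 1L,
                   consequence = "missense_variant",
                   known_pathogenic = TRUE, freq_kgp = 1e-4),
      mini_variant(gene = "REC1", pos = 2L,
                   consequence = "missense_variant",
                   known_pathogenic = TRUE))),
    panel, samples)
  expect_true(all(rec_ok$verdict == "likely_pathogenic"))

  single_rec <- triage_missense(mk(gene = "REC1"), panel, samples)
  expect_equal(single_rec$reason_codes, "R_RECESSIVE_SINGLE_ALLELE")

  lit <- triage_missense(mk(literature_excluded = TRUE), panel, samples)
  expect_equal(lit$reason_codes, "R_LITERATURE_EXCLUDED")

  mode <- triage_missense(mk(mode_mismatch = TRUE), panel, samples)
  expect_equal(mode$reason_codes, "R_MODE_MISMATCH")

  # male hemizygous known-pathogenic missense on a known X gene qualifies
  xm <- triage_missense(mk(gene = "XL1", chrom_class = "X",
                           zygosity = "hemi"), panel, samples)
  expect_equal(xm$verdict, "likely_pathogenic")
})

test_that("a likely-pathogenic LoF in another gene excludes the missense,
           but a comp-het partner in the same gene does not", {
  # LoF in DOM1 + reported missense in XL1: missense excluded by rule (v)
  v <- triage_ready(mini_variants(
    mini_variant(gene = "DOM1", pos = 1L),
    mini_variant(gene = "XL1", chrom_class = "X", pos = 2L,
                 zygosity = "hemi", consequence = "missense_variant",
                 known_pathogenic = TRUE)))
  cls <- triage_cohort(v, panel, samples)
  mis <- cls[cls$consequence_class == "functional", ]
  expect_equal(mis$verdict, "excluded")
  expect_equal(mis$reason_codes, "R_BETTER_LOF_EXPLANATION")

  # comp-het LoF + missense in one biallelic gene: both diagnostic
  v2 <- triage_ready(mini_variants(
    mini_variant(gene = "REC1", pos = 1L),
    mini_variant(gene = "REC1", pos = 2L,
                 consequence = "missense_variant",
                 known_pathogenic = TRUE)))
  cls2 <- triage_cohort(v2, panel, samples)
  expect_true(all(cls2$verdict == "likely_pathogenic"))
  expect_setequal(cls2$pathway,
                  c("lof_known_gene", "missense_known_pathogenic"))
})

test_that("triage verdicts are independent of record order", {
  sim <- simulate_cohorts(sim_config(n_case = 60L, n_comparison = 60L,
                                     seed = 5L))
  prep <- prepare_cohort(sim$variants, sim$samples, quiet = TRUE)
  cls1 <- triage_cohort(prep$variants, sim$panel, prep$samples)
  set.seed(9)
  shuffled <- prep$variants[sample.int(nrow(prep$variants)), ]
  cls2 <- triage_cohort(shuffled, sim$panel, prep$samples)
  key <- function(d) d[order(d$sample_id, d$pos, d$alt), ]
  expect_equal(key(cls1), key(cls2), ignore_attr = TRUE)
})

test_that("external-presence annotation attaches counts, never verdicts", {
  cls <- triage_cohort(triage_ready(mini_variant()), panel, samples)
  sec <- data.frame(gene = "DOM1", pos = 100L, ref = "C", alt = "T",
                    count = 4L, stringsAsFactors = FALSE)
  ann <- annotate_external_presence(cls, sec)
  expect_equal(ann$external_presence, 4L)
  expect_equal(ann$verdict, cls$verdict)
  # absent from the secondary panel -> 0
  ann2 <- annotate_external_presence(cls, sec[0L, ])
  expect_equal(ann2$external_presence, 0L)
  # empty classification set stays empty
  expect_equal(nrow(annotate_external_presence(cls[0L, ], sec)), 0L)
})

test_that("diagnostic yield satisfies the inclusion-exclusion identity", {
  fx <- yield_fixture(n_samples = 986L, n_lof = 77L, n_mis = 33L, n_both = 3L)
  y <- diagnostic_yield(fx$classifications, fx$samples)
  expect_equal(y$n_lof_diagnosed, 77L)
  expect_equal(y$n_missense_diagnosed, 33L)
  expect_equal(y$n_both, 3L)
  expect_equal(y$n_diagnosed_union, 107L)
  expect_equal(y$n_diagnosed_union,
               y$n_lof_diagnosed + y$n_missense_diagnosed - y$n_both)
  expect_equal(y$yield_fraction, 107 / 986)
  # no diagnoses -> zero yield
  y0 <- diagnostic_yield(fx$classifications[0L, ], fx$samples)
  expect_equal(y0$n_diagnosed_union, 0L)
  expect_equal(y0$yield_fraction, 0)
})
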