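test_that("cast_test equals the brute-force hypergeometric oracle", {
  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(1:30, 1L); n2 <- sample(1:30, 1L)
    a <- sample(0:n1, 1L); c_ <- sample(0:n2, 1L)
    expect_equal(cast_test(a, n1, c_, n2, "greater"),
                 oracle_tail(a, n1, c_, n2, "greater"), tolerance = 1e-12)
    expect_equal(cast_test(a, n1, c_, n2, "less"),
                 oracle_tail(a, n1, c_, n2, "less"), tolerance = 1e-12)
  }
  # small exhaustive case with a zero cell: 3/10 vs 0/10
  expect_equal(cast_test(3, 10, 0, 10, "greater"),
               oracle_tail(3, 10, 0, 10, "greater"), tolerance = 1e-12)
})

test_that("cast_test agrees with fisher.test across random tables", {
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(1:400, 1L); n2 <- sample(1:400, 1L)
    a <- sample(0:n1, 1L); c_ <- sample(0:n2, 1L)
    m <- matrix(c(a, n1 - a, c_, n2 - c_), 2L)
    expect_equal(cast_test(a, n1, c_, n2, "greater"),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(cast_test(a, n1, c_, n2, "two_sided"),
                 fisher.test(m)$p.value, tolerance = 1e-10)
  }
})

test_that("cast_test tail-direction properties hold", {
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(5:200, 1L); n2 <- sample(5:200, 1L)
    a <- sample(0:n1, 1L); c_ <- sample(0:n2, 1L)
    pg <- cast_test(a, n1, c_, n2, "greater")
    pl <- cast_test(a, n1, c_, n2, "less")
    # the boundary table is shared between the two tails
    expect_gte(pg + pl, 1 - 1e-12)
    # two-sided never undercuts the enriched one-sided tail
    expect_gte(cast_test(a, n1, c_, n2, "two_sided") + 1e-12, min(pg, pl))
    # label-swap antisymmetry
    expect_equal(pg, cast_test(c_, n2, a, n1, "less"), tolerance = 1e-12)
  }
  # identical proportions cannot look enriched
  expect_gte(cast_test(10, 100, 10, 100, "greater"), 0.5)
  expect_equal(cast_test(0, 50, 0, 50, "greater"), 1)
  expect_error(cast_test(11, 10, 0, 10), "inconsistent")
  expect_error(cast_test(-1, 10, 0, 10), "inconsistent")
})

test_that("null CAST p-values are calibrated, never anti-conservative", {
  set.seed(33)
  p_carrier <- 0.12
  ps <- replicate(2000, {
    a <- rbinom(1L, 500L, p_carrier)
    c_ <- rbinom(1L, 500L, p_carrier)
    cast_test(a, 500L, c_, 500L, "greater")
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps < alpha),
               alpha + 2 * sqrt(alpha * (1 - alpha) / length(ps)))
  }
  # close to uniform overall, allowing the exact test's discreteness
  d <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(unname(d), 0.08)
})

test_that("stratum_spec rejects invalid stratum combinations", {
  expect_error(stratum_spec("X_males_only", "known_monoallelic", "lof_snv"),
               "autosome_or_PAR")
  expect_error(stratum_spec("autosome_or_PAR", "known_x", "lof_snv"),
               "X_males_only")
  s <- stratum_spec("X_males_only", "candidate", "lof_indel")
  expect_s3_class(s, "idpanel_stratum")
})

test_that("carrier counting is per-sample and sex-restricted on X", {
  panel <- mini_panel()
  samples <- mini_samples()
  # one sample with three qualifying LoF contributes one carrier
  v <- triage_ready(mini_variants(
    mini_variant(pos = 1L), mini_variant(pos = 2L), mini_variant(pos = 3L)))
  cc <- carrier_counts(v, samples, panel,
                       stratum_spec("autosome_or_PAR", "known_monoallelic",
                                    "lof_snv"))
  expect_equal(cc$carriers_case, 1L)
  expect_equal(cc$n_case, 2L)
  # male-only stratum ignores female carriers in numerator and denominator
  vx <- triage_ready(mini_variant(sample_id = "S2", gene = "XL1",
                                  chrom_class = "X", pos = 9L))
  ccx <- carrier_counts(vx, samples, panel,
                        stratum_spec("X_males_only", "known_x", "lof_snv"))
  expect_equal(ccx$carriers_case, 0L)
  expect_equal(ccx$n_case, 1L)   # only the male case sample
  # empty stratum warns and returns zero carriers
  no_x_panel <- panel[panel$chrom_class != "X", ]
  expect_warning(
    cc0 <- carrier_counts(vx, samples, no_x_panel,
                          stratum_spec("X_males_only", "known_x", "lof_snv")),
    "empty stratum")
  expect_equal(cc0$carriers_case, 0L)
})

test_that("damaging-missense mask needs all four scores and absence from
           references, with strict inequalities", {
  mk <- function(pp2 = 0.95, sift = 0.03, condel = 0.6, cadd = 25,
                 freq_kgp = NA_real_) {
    mini_variant(consequence = "missense_variant", polyphen2 = pp2,
                 sift = sift, condel = condel, cadd = cadd,
                 freq_kgp = freq_kgp)
  }
  expect_true(damaging_missense_mask(mk()))
  expect_false(damaging_missense_mask(mk(pp2 = 0.9)))      # strict >
  expect_false(damaging_missense_mask(mk(sift = 0.06)))    # strict <
  expect_false(damaging_missense_mask(mk(condel = 0.47)))
  expect_false(damaging_missense_mask(mk(cadd = 20)))
  expect_false(damaging_missense_mask(mk(cadd = NA)))      # missing fails
  expect_false(damaging_missense_mask(mk(freq_kgp = 1e-4)))
  expect_false(damaging_missense_mask(mini_variant()))     # not missense
})

test_that("stratified table has the published category structure", {
  fx <- fixture_tables()$enrichment
  panel <- simulate_panel(sim_config())
  tab <- stratified_table(fx$variants, fx$samples, panel)
  # 3 autosomal + 2 X gene categories, each with SNV/indel/synonymous rows
  expect_equal(nrow(tab), 15L)
  expect_equal(sum(tab$chrom_stratum == "autosome_or_PAR"), 9L)
  expect_equal(sum(tab$chrom_stratum == "X_males_only"), 6L)
  expect_equal(tab$n_genes[tab$gene_category == "known_monoallelic" &
                             tab$variant_type == "lof_snv"], 78L)
  # synonymous control rows are never flagged significant
  syn <- tab[tab$variant_type == "synonymous", ]
  expect_false(any(syn$significant))
  # significance flag is exactly p < adjusted alpha on LoF rows
  lof <- tab[tab$variant_type != "synonymous", ]
  expect_equal(lof$significant, lof$p_value < 0.05 / 10)
  # empty panel -> empty table
  expect_equal(nrow(stratified_table(fx$variants, fx$samples, panel[0L, ])),
               0L)
})

test_that("threshold sweep carrier counts are monotone in the threshold", {
  sim <- simulate_cohorts(sim_config(n_case = 120L, n_comparison = 120L,
                                     seed = 13L))
  prep <- prepare_cohort(sim$variants, sim$samples, quiet = TRUE)
  sw <- threshold_sweep(prep$variants, prep$samples, sim$panel)
  expect_true(all(diff(sw$carriers_case) <= 0))
  expect_true(all(diff(sw$carriers_comparison) <= 0))
  # threshold 1.0 is a no-op relative to the filtered input
  sw1 <- threshold_sweep(prep$variants, prep$samples, sim$panel,
                         thresholds = 1.0)
  lof_ids <- unique(prep$variants$sample_id[
    prep$variants$consequence_class == "lof"])
  expect_equal(sw1$carriers_case + sw1$carriers_comparison, length(lof_ids))
})

test_that("damaging-missense CAST excludes LoF-diagnosed case samples and
           reports the implied denominator", {
  fx <- fixture_tables()$damaging_missense
  panel <- simulate_panel(sim_config())
  res <- damaging_missense_cast(fx$variants, fx$samples, panel,
                                fx$lof_diagnosed)
  expect_equal(res$n_case, 900L)
  expect_equal(res$carriers_case, 284L)
  expect_equal(res$carriers_comparison, 245L)
  # no damaging missense anywhere -> p = 1
  none <- damaging_missense_cast(fx$variants[0L, ], fx$samples, panel,
                                 character(0))
  expect_equal(none$p_value, 1)
})
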