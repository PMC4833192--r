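# shared builders for small in-code cohorts

mini_panel <- function() {
  data.frame(
    gene = c("DOM1", "REC1", "XL1", "CAND1", "CANDX1"),
    status = c("known", "known", "known", "candidate", "candidate"),
    chrom_class = c("autosome", "autosome", "X", "autosome", "X"),
    inheritance = c("monoallelic", "biallelic", "x_linked", "monoallelic",
                    "x_linked"),
    transcript = c("TX_DOM1", "TX_REC1", "TX_XL1", "TX_CAND1", "TX_CANDX1"),
    stringsAsFactors = FALSE
  )
}

mini_samples <- function() {
  data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    sex = c("male", "female", "male", "female"),
    cohort = c("case", "case", "comparison", "comparison"),
    qc_pass = TRUE, variant_count = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# one variant row with overridable fields
mini_variant <- function(sample_id = "S1", gene = "DOM1",
                         chrom_class = "autosome", pos = 100L,
                         ref = "C", alt = "T",
                         consequence = "stop_gained",
                         variant_class = "SNV", zygosity = "het",
                         freq_kgp = NA_real_, freq_evs = NA_real_,
                         carriers_internal = 1L,
                         polyphen2 = NA_real_, sift = NA_real_,
                         condel = NA_real_, cadd = NA_real_,
                         known_pathogenic = FALSE,
                         literature_excluded = FALSE,
                         mode_mismatch = FALSE,
                         transcript = paste0("TX_", gene)) {
  data.frame(sample_id = sample_id, gene = gene, chrom_class = chrom_class,
             pos = pos, ref = ref, alt = alt, consequence = consequence,
             variant_class = variant_class, zygosity = zygosity,
             freq_kgp = freq_kgp, freq_evs = freq_evs,
             carriers_internal = carriers_internal, polyphen2 = polyphen2,
             sift = sift, condel = condel, cadd = cadd,
             known_pathogenic = known_pathogenic,
             literature_excluded = literature_excluded,
             mode_mismatch = mode_mismatch, transcript = transcript,
             stringsAsFactors = FALSE)
}

mini_variants <- function(...) {
  do.call(rbind, list(...))
}

# annotate + flag, skipping frequency filtering
triage_ready <- function(variants) {
  flag_compound_het(annotate_consequence(variants))
}

# independent exact-test oracle: enumerate every 2x2 table with the
# observed margins and sum binomial-coefficient probabilities directly
oracle_tail <- function(a, n1, c_, n2, alternative = "greater") {
  k <- a + c_
  n_tot <- n1 + n2
  support <- max(0L, k - n2):min(k, n1)
  logp <- lchoose(n1, support) + lchoose(n2, k - support) - lchoose(n_tot, k)
  p <- exp(logp)
  switch(alternative,
         greater = sum(p[support >= a]),
         less = sum(p[support <= a]))
}

# deterministic classification fixture: n_lof samples diagnosed through
# the LoF pathway, n_mis through the missense pathway, n_both through both
yield_fixture <- function(n_samples = 986L, n_lof = 77L, n_mis = 33L,
                          n_both = 3L) {
  ids <- sprintf("CASE%04d", seq_len(n_samples))
  lof_ids <- ids[seq_len(n_lof)]
  mis_ids <- ids[c(seq_len(n_both), n_lof + seq_len(n_mis - n_both))]
  cls <- rbind(
    data.frame(sample_id = lof_ids, verdict = "likely_pathogenic",
               pathway = "lof_known_gene", stringsAsFactors = FALSE),
    data.frame(sample_id = mis_ids, verdict = "likely_pathogenic",
               pathway = "missense_known_pathogenic", stringsAsFactors = FALSE)
  )
  samples <- data.frame(sample_id = ids, sex = "male", cohort = "case",
                        qc_pass = TRUE, variant_count = NA_integer_,
                        stringsAsFactors = FALSE)
  list(classifications = cls, samples = samples)
}
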