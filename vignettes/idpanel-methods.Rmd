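---
title: "Methods: proband-only panel triage and carrier-burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proband-only panel triage and carrier-burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large cohorts of unrelated probands with intellectual disability (ID) are
often sequenced on targeted gene panels without parental DNA, so de novo
inference is unavailable. The diagnostic question becomes: which rare
variants can be called likely pathogenic from the proband's data alone,
and how much true signal does the cohort carry beyond what triage can
confidently assign? `idpanel` implements both halves: a rule-based,
inheritance-aware triage of individual variants, and a cohort-level
carrier-burden comparison against a phenotypically unrelated comparison
cohort sequenced on the same panel.

## Filtering model

Variants enter as per-sample records annotated with a consequence term, a
zygosity, allele frequencies in external reference sets, and an internal
carrier count over the full multi-phenotype dataset of which the two
cohorts are subsets (2,812 individuals by default, configurable).
Filtering applies, in order:

1. **Frequency filter.** A record is dropped if any reference-set
   frequency, or the internal carrier frequency
   (`carriers_internal / internal_cohort_size`), reaches the MAF
   threshold (default 1%). "MAF < 1%" is read strictly: a frequency
   exactly at the threshold is dropped. The internal denominator is
   individuals, not chromosomes, because internal filtering is
   carrier-based; an allele-based denominator can be configured.
2. **Outlier exclusion.** Samples with strictly more than 30 filtered
   variants (configurable) are removed as technical outliers; a sample
   with exactly 30 stays. Exclusion runs after frequency filtering and
   before triage and burden testing, and is idempotent.
3. **Consequence classification.** The controlled vocabulary maps
   nonsense, frameshift and the two canonical splice-site terms to LoF;
   missense, inframe indels and stop loss to the functional class;
   `synonymous_variant` to the synonymous control class. Essential splice
   sites are the two canonical intronic bases only -- extended
   splice-region terms are rejected unless explicitly configured as
   `other`, and `other` never participates in triage or burden testing.
   Unknown terms are an error rather than a silent bucket, because every
   downstream rule keys on this classification.
4. **Compound-heterozygote flagging.** A (sample, gene) pair is flagged
   when it carries two or more *distinct* heterozygous records;
   homozygous and hemizygous records follow their own pathways and do
   not contribute.

The internal-frequency ladder (1%, 0.5%, 0.1%, 0.05%) drives the
uniqueness filter: at the lowest rung with the default denominator, only
variants carried by a single individual ("unique" variants) survive.

## Triage rules

**LoF pathway.** A filtered LoF variant is likely pathogenic iff the gene
is a known disease gene, the genotype fits the gene's inheritance mode
(het or hom for monoallelic; hom or flagged comp-het for biallelic; male
hemizygous for X-linked), the variant is absent from control sets
(tolerated for biallelic genes, where healthy het carriers are expected),
and the call is on the canonical transcript. Everything else is
*uncertain*, with reason codes for each failing condition.

**Missense pathway.** Only variants previously reported as
disease-causing (a user-supplied lookup standing in for licensed clinical
databases) are considered; the rest are excluded outright. Reported
variants pass an ordered checklist, and the first failing rule is the one
recorded: (i) candidate gene; (ii) presence in control sets, unless the
gene is biallelic; (iii) biallelic gene with a single abnormal allele;
(iv) literature exclusion; (v) a likely-pathogenic LoF that better
explains the phenotype; (vi/vii) pedigree/phenotype mode mismatch. Rules
(iv) and (vi/vii) are inherently manual judgments, so the engine consumes
them as input flag columns -- the checklist stays complete without
pretending to automate literature review.

Two design points in this checklist were genuinely open:

* **Rule (v) scope.** Taken literally ("any likely-pathogenic LoF in the
  sample"), rule (v) would make it impossible for one individual to carry
  both a LoF and a missense diagnosis -- yet recessive diagnoses
  routinely arrive as a comp-het LoF + missense pair in one gene. The
  engine therefore excludes a missense only when the explanatory LoF sits
  in a *different* gene; a comp-het partner in the same gene is part of
  the same diagnosis.
* **X-linked female carriers.** Female het carriers of X-linked genes are
  non-diagnostic by default, since most X-linked ID is male-limited, but
  penetrance is gene-dependent (several X-linked genes manifest in
  females), so a per-gene override list is supported and empty by
  default.

The diagnostic yield is the per-sample union of the two pathways;
individuals diagnosed through both count once, so
`union = lof + missense - both` holds exactly on every run.

## The carrier-burden test

The cohort allelic sums test (CAST) reduces each cohort to the number of
samples carrying at least one qualifying variant and compares the two
proportions with an exact conditional test: with both margins of the 2x2
table fixed, the case-carrier count is hypergeometric, and the p-value is
the tail probability of a table at least as extreme. The implementation
sums the hypergeometric density directly; `stats::fisher.test` and a
brute-force enumeration over all tables with the observed margins serve
as independent oracles in the test suite. The default alternative is
one-tailed case enrichment, used uniformly across all strata, and no
mid-p correction is applied -- the plain exact test reproduces the
reference contingency tables at their printed precision. Two-sided
p-values use the standard minimum-likelihood convention with the
`1 + 1e-7` tie tolerance, matching `fisher.test`.

Stratification crosses three autosomal gene categories (known
monoallelic, known biallelic, candidate) with two X categories (known
X-linked, candidate), each over LoF SNVs, LoF indels and synonymous
controls -- 15 cells. X strata restrict both numerator and denominator to
male samples; genotype is otherwise ignored because carriers are counted
at the sample level. Synonymous rows are negative controls and are never
flagged significant. The Bonferroni family counts the 10 LoF tests
(5 gene-category strata x 2 LoF types), giving the adjusted threshold
0.05 / 10 = 0.005; the family size is exposed as a configuration override
because reasonable analysts could include the synonymous rows.

The damaging-missense variant of the test keeps only missense records
passing all four in-silico thresholds -- PolyPhen2 > 0.9, SIFT < 0.06,
Condel > 0.47, CADD (Phred) > 20, strict inequalities, a missing score
failing -- and absent from all reference sets. Samples already explained
by a LoF diagnosis are removed from the case cohort first; the operation
reports whatever denominator the supplied exclusion list implies rather
than hard-coding one, since published summaries of this design are not
internally consistent about it.

## The synthetic cohort generator

The generator exists so that every stage -- parsing, filtering, triage,
burden testing -- can be exercised with fully known ground truth. Its
defaults emulate the reference study conditions: 986 cases (93.8% male)
vs 899 comparison samples (male fraction 466/899, inferred from male-only
stratum denominators rather than quoted); a 565-gene panel of 253 known
(78 monoallelic, 86 biallelic, 89 X-linked) and 312 candidate genes (162
autosomal, 150 X); post-filter background means of 0.46 LoF and 8
missense variants per person; and planted diagnostic fractions of 8%
(LoF) and 3% (missense) with 3 dual-pathway individuals realised as
comp-het LoF + missense pairs in one biallelic gene.

Choices where only summary statistics were available:

* **Count model.** Per-sample background counts are Poisson at the stated
  means -- the minimal assumption given only means -- with a negative
  binomial option for overdispersion.
* **Synonymous and common classes.** Synonymous background (mean 4 per
  person) feeds the control rows; a common class (mean 1 per person,
  reference frequencies >= 1%) exists purely to give the MAF filter work
  to do, so the post-filter means remain the configured ones.
* **Uniqueness and reference presence.** Each background variant is
  unique in the internal dataset with probability 0.5 and present in an
  external reference set with probability 0.45. These two defaults were
  calibrated once against the published comparison-cohort attrition
  (roughly 45% of MAF-filtered LoF carriers remain at the unique-only
  rung) and then fixed.
* **Background LoF gene weights.** Uniform gene choice would place far
  too many background LoF variants in known monoallelic and known
  X-linked genes relative to the published category structure, which
  shows strong LoF depletion in those genes (purifying selection, most
  visible as zero male X carriers in the comparison cohort). Background
  LoF gene choice is therefore weighted per category
  (0.8 / 2.2 / 1.4 / 0.05 / 0.2 for known-mono / known-bi /
  candidate-autosomal / known-X / candidate-X); missense and synonymous
  classes stay uniform. The weights are a config hook.
* **Known-pathogenic decoys.** 5% of background missense records carry
  the reported-pathogenic flag (matching the observed proportion of
  panel missense with prior disease reports), and 90% of those carry the
  literature-exclusion flag, matching the published curation attrition
  in which ~9 in 10 reported variants failed manual review. This keeps
  background missense false positives at the few-per-cohort level the
  checklist achieves in practice.
* **Internal carrier counts.** A background variant's internal carrier
  count refers to the full multi-phenotype internal dataset, most of
  which lies outside the generated tables, so shared counts are drawn
  (2 + Poisson(2)) rather than realised as duplicate rows. The
  deterministic fixtures, by contrast, realise sharing as actual
  within-cohort duplicate alleles, which is what the bit-exact carrier
  regressions need.
* **Planting.** Planted variants are always unique, absent from
  references, canonical, and mode-consistent; X-linked plants go to male
  samples only, matching the triage default. PAR genes are not emitted by
  default (panel composition by PAR is unstated in the reference
  material; wherever a PAR record appears it is treated as autosomal).

What the generator does **not** emulate: per-gene variant-rate
heterogeneity beyond the LoF category weights (no gene-length model),
population structure and relatedness, genotype error and coverage
artifacts (the outlier rule is exercised by fixtures instead), and any
correlation between in-silico scores beyond a single latent
damaging/benign indicator. Passing tests on synthetic data therefore
validate the pipeline's logic and calibration, not the biological realism
of any particular gene's variant load.

## Validation problem sizes

The suite checks the exact test against brute-force enumeration on all
2x2 tables with margins up to 30; calibrates the null rejection rate on
500 replicate null cohorts of 500 samples per side (the rejection rate
must sit inside the 95% binomial window around 0.05 -- note the exact
test is conservative, so rates near the lower edge are expected);
and measures ground-truth recovery on 10 replicates at the full default
study size, requiring >= 95% recall of planted diagnoses and a mean
measured yield within three binomial standard errors of the planted union
fraction. The measured yield sits slightly above the planted fraction by
construction, because the generator's background legitimately produces a
small rate of triage-passing LoF carriers (about 1.5% of samples, matching
the residual unexplained carriers seen in real comparison cohorts), and
the triage engine cannot -- and should not -- distinguish those from
planted signal.

## Known limitations

* Rules (iv) and (vi/vii) of the missense checklist are only as good as
  the supplied flags; the engine executes the checklist, it does not
  perform literature review.
* The CAST is a carrier-level test: it ignores allele counts within a
  sample and is underpowered for per-gene association at these cohort
  sizes. No allele-count burden tests (CMC, SKAT) are provided.
* The triage has no phenotype model (no HPO matching, no ACMG scoring)
  and no de novo inference -- by design, since the setting is
  proband-only.
* Exact-test conservatism means the type-I rate at nominal 5% is
  typically 3.5-4.5% at these cohort sizes; power statements should use
  the adjusted threshold actually applied (0.005), not the nominal 5%.
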