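#' Cohort allelic sums test (CAST)
#'
#' Carrier-level burden test between two cohorts: given the number of
#' samples in each cohort carrying at least one qualifying variant, the
#' test computes the exact conditional (hypergeometric) tail probability of
#' a 2x2 table at least as extreme in the stated direction, conditioning on
#' both margins. The default alternative \code{"greater"} asks for carrier
#' enrichment in the case cohort (one-tailed); \code{"two_sided"} sums the
#' probabilities of all tables no more likely than the observed one.
#' No mid-p correction is applied.
#'
#' @param carriers_case,n_case carriers and cohort size, case cohort.
#' @param carriers_comparison,n_comparison carriers and cohort size,
#'   comparison cohort.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two_sided"}.
#' @return the p-value, a number in (0, 1].
#' @examples
#' cast_test(341, 986, 222, 899)  # ~1.7e-6
#' @export
cast_test <- function(carriers_case, n_case, carriers_comparison,
                      n_comparison,
                      alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- carriers_case; c_ <- carriers_comparison
  stopifnot(length(a) == 1L, length(c_) == 1L)
  if (any(c(a, n_case, c_, n_comparison) < 0) || a > n_case ||
      c_ > n_comparison) {
    stop("inconsistent carrier counts: carriers must lie within [0, n]",
         call. = FALSE)
  }
  k <- a + c_                     # total carriers (fixed margin)
  n_tot <- n_case + n_comparison
  lo <- max(0L, k - n_comparison) # support of the case-carrier count
  hi <- min(k, n_case)
  dens <- stats::dhyper(lo:hi, k, n_tot - k, n_case)
  obs <- a - lo + 1L
  p <- switch(alternative,
    greater = sum(dens[obs:length(dens)]),
    less = sum(dens[1:obs]),
    two_sided = sum(dens[dens <= dens[obs] * (1 + 1e-7)])
  )
  min(1, p)
}

.gene_categories <- c("known_monoallelic", "known_biallelic", "known_x",
                      "candidate")
.variant_types <- c("lof_snv", "lof_indel", "synonymous",
                    "damaging_missense")

#' Define a stratification cell for burden testing
#'
#' @param chrom_stratum \code{"autosome_or_PAR"} (all samples; autosomal
#'   and pseudo-autosomal genes) or \code{"X_males_only"} (male samples
#'   only, X-linked genes only).
#' @param gene_category \code{"known_monoallelic"}, \code{"known_biallelic"}
#'   (only valid with the autosomal stratum), \code{"known_x"} (only with
#'   the X stratum), or \code{"candidate"} (valid in both; restricted to
#'   the stratum's chromosome class).
#' @param variant_type \code{"lof_snv"}, \code{"lof_indel"},
#'   \code{"synonymous"} or \code{"damaging_missense"}.
#' @return a validated list of class \code{"idpanel_stratum"}.
#' @export
stratum_spec <- function(chrom_stratum = c("autosome_or_PAR", "X_males_only"),
                         gene_category = .gene_categories,
                         variant_type = .variant_types) {
  chrom_stratum <- match.arg(chrom_stratum)
  gene_category <- match.arg(gene_category)
  variant_type <- match.arg(variant_type)
  if (gene_category %in% c("known_monoallelic", "known_biallelic") &&
      chrom_stratum != "autosome_or_PAR") {
    stop("gene_category ", gene_category,
         " is only valid with the autosome_or_PAR stratum", call. = FALSE)
  }
  if (gene_category == "known_x" && chrom_stratum != "X_males_only") {
    stop("gene_category known_x is only valid with the X_males_only stratum",
         call. = FALSE)
  }
  structure(list(chrom_stratum = chrom_stratum,
                 gene_category = gene_category,
                 variant_type = variant_type),
            class = "idpanel_stratum")
}

stratum_genes <- function(panel, stratum) {
  on_x <- panel$chrom_class == "X"
  in_chrom <- if (stratum$chrom_stratum == "X_males_only") on_x else !on_x
  in_cat <- switch(stratum$gene_category,
    known_monoallelic = panel$status == "known" &
      panel$inheritance == "monoallelic",
    known_biallelic = panel$status == "known" &
      panel$inheritance == "biallelic",
    known_x = panel$status == "known" & panel$inheritance == "x_linked",
    candidate = panel$status == "candidate"
  )
  panel$gene[in_chrom & in_cat]
}

variant_type_mask <- function(variants, variant_type) {
  if (!"consequence_class" %in% names(variants)) {
    variants <- annotate_consequence(variants)
  }
  switch(variant_type,
    lof_snv = variants$consequence_class == "lof" &
      variants$variant_class == "SNV",
    lof_indel = variants$consequence_class == "lof" &
      variants$variant_class == "indel",
    synonymous = variants$consequence_class == "synonymous",
    damaging_missense = damaging_missense_mask(variants)
  )
}

#' Carrier counts for one stratification cell
#'
#' A sample is a carrier iff it has at least one variant matching the
#' stratum after the internal-frequency (uniqueness) filter; each sample
#' counts at most once. The \code{X_males_only} stratum drops female
#' samples from both numerator and denominator; genotype (het, hom, hemi)
#' is otherwise ignored, as carriers are counted at the sample level.
#'
#' @param variants filtered variant table.
#' @param samples sample table with a \code{cohort} column.
#' @param panel gene panel.
#' @param stratum a \code{\link{stratum_spec}}.
#' @param uniqueness internal-frequency threshold (default keeps unique
#'   variants only).
#' @param cfg a \code{\link{filter_config}}.
#' @param case_label,comparison_label values of \code{samples$cohort}
#'   naming the two cohorts.
#' @return list \code{(carriers_case, n_case, carriers_comparison,
#'   n_comparison)}.
#' @export
carrier_counts <- function(variants, samples, panel, stratum,
                           uniqueness = 0.0005, cfg = filter_config(),
                           case_label = "case",
                           comparison_label = "comparison") {
  genes <- stratum_genes(panel, stratum)
  if (length(genes) == 0L) {
    warning("empty stratum: no panel genes match ",
            stratum$gene_category, " / ", stratum$chrom_stratum)
  }
  pool <- samples
  if (stratum$chrom_stratum == "X_males_only") {
    pool <- pool[pool$sex == "male", , drop = FALSE]
  }
  v <- uniqueness_filter(variants, uniqueness, cfg)
  v <- v[v$gene %in% genes & variant_type_mask(v, stratum$variant_type), ,
         drop = FALSE]
  carriers <- unique(v$sample_id)
  case_ids <- pool$sample_id[pool$cohort == case_label]
  comp_ids <- pool$sample_id[pool$cohort == comparison_label]
  list(
    carriers_case = sum(case_ids %in% carriers),
    n_case = length(case_ids),
    carriers_comparison = sum(comp_ids %in% carriers),
    n_comparison = length(comp_ids)
  )
}

#' Stratified carrier-enrichment table
#'
#' One row per valid combination of chromosome stratum, gene category and
#' variant type: three autosomal gene categories (known monoallelic, known
#' biallelic, candidate) and two X categories (known X-linked, candidate)
#' crossed with LoF SNVs, LoF indels and synonymous controls -- 15 rows.
#' Synonymous rows are negative controls: they are never flagged
#' significant. A Bonferroni-adjusted alpha of
#' \code{alpha / bonferroni_m} is applied to the LoF rows; the default
#' family counts the 10 LoF tests (5 gene-category strata x 2 LoF variant
#' types), excluding the synonymous controls.
#'
#' @inheritParams carrier_counts
#' @param alpha nominal significance level before adjustment.
#' @param bonferroni_m multiple-testing family size for the LoF rows.
#' @return data.frame with one row per stratification cell: counts, the
#'   one-tailed CAST p-value, adjusted alpha and significance flag.
#' @export
stratified_table <- function(variants, samples, panel, uniqueness = 0.0005,
                             cfg = filter_config(), alpha = 0.05,
                             bonferroni_m = 10,
                             case_label = "case",
                             comparison_label = "comparison") {
  if (nrow(panel) == 0L) {
    return(data.frame())
  }
  cells <- expand.grid(
    gene_category = c("known_monoallelic", "known_biallelic", "candidate",
                      "known_x", "candidate_x"),
    variant_type = c("lof_snv", "lof_indel", "synonymous"),
    stringsAsFactors = FALSE
  )
  cells <- cells[order(match(cells$gene_category,
                             c("known_monoallelic", "known_biallelic",
                               "candidate", "known_x", "candidate_x"))), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cat_i <- cells$gene_category[i]
    stratum <- if (cat_i %in% c("known_x", "candidate_x")) {
      stratum_spec("X_males_only",
                   if (cat_i == "known_x") "known_x" else "candidate",
                   cells$variant_type[i])
    } else {
      stratum_spec("autosome_or_PAR", cat_i, cells$variant_type[i])
    }
    cc <- carrier_counts(variants, samples, panel, stratum, uniqueness, cfg,
                         case_label, comparison_label)
    p <- cast_test(cc$carriers_case, cc$n_case, cc$carriers_comparison,
                   cc$n_comparison, alternative = "greater")
    is_lof <- cells$variant_type[i] != "synonymous"
    alpha_adj <- if (is_lof) alpha / bonferroni_m else 0
    data.frame(
      chrom_stratum = stratum$chrom_stratum,
      gene_category = stratum$gene_category,
      n_genes = length(stratum_genes(panel, stratum)),
      variant_type = stratum$variant_type,
      carriers_case = cc$carriers_case, n_case = cc$n_case,
      carriers_comparison = cc$carriers_comparison,
      n_comparison = cc$n_comparison,
      p_value = p,
      alpha_adjusted = alpha_adj,
      significant = p < alpha_adj,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Carrier frequencies and p-values across the internal-frequency ladder
#'
#' For each threshold, counts samples in each cohort carrying at least one
#' LoF variant in any panel gene after the internal-frequency filter, and
#' computes the one-tailed CAST p-value. Carrier counts are non-increasing
#' as the threshold tightens.
#'
#' @inheritParams carrier_counts
#' @param thresholds internal-frequency thresholds to sweep (defaults to
#'   the configured ladder).
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(variants, samples, panel,
                            thresholds = NULL, cfg = filter_config(),
                            case_label = "case",
                            comparison_label = "comparison") {
  if (is.null(thresholds)) thresholds <- cfg$internal_freq_thresholds
  if (!"consequence_class" %in% names(variants)) {
    variants <- annotate_consequence(variants, cfg)
  }
  lof <- variants[variants$consequence_class == "lof" &
                    variants$gene %in% panel$gene, , drop = FALSE]
  case_ids <- samples$sample_id[samples$cohort == case_label]
  comp_ids <- samples$sample_id[samples$cohort == comparison_label]
  rows <- lapply(thresholds, function(t) {
    v <- suppressWarnings(uniqueness_filter(lof, t, cfg))
    carriers <- unique(v$sample_id)
    a <- sum(case_ids %in% carriers)
    c_ <- sum(comp_ids %in% carriers)
    data.frame(
      threshold = t,
      carriers_case = a, n_case = length(case_ids),
      carriers_comparison = c_, n_comparison = length(comp_ids),
      frac_case = a / length(case_ids),
      frac_comparison = c_ / length(comp_ids),
      p_value = cast_test(a, length(case_ids), c_, length(comp_ids)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Four-score consensus mask for damaging missense variants
#'
#' TRUE iff the record is a missense variant with PolyPhen2 > 0.9,
#' SIFT < 0.06, Condel > 0.47 and CADD (Phred) > 20 -- all strict
#' inequalities -- and the variant is absent from every reference set. A
#' missing score fails the mask.
#'
#' @param variants variant table.
#' @return logical vector along \code{variants}.
#' @export
damaging_missense_mask <- function(variants) {
  fc <- freq_columns(variants)
  absent_refs <- if (length(fc) > 0L) {
    fmat <- as.matrix(variants[fc])
    rowSums(!is.na(fmat) & fmat > 0) == 0L
  } else {
    rep(TRUE, nrow(variants))
  }
  pass <- function(x, ok) !is.na(x) & ok
  variants$consequence == "missense_variant" &
    pass(variants$polyphen2, variants$polyphen2 > 0.9) &
    pass(variants$sift, variants$sift < 0.06) &
    pass(variants$condel, variants$condel > 0.47) &
    pass(variants$cadd, variants$cadd > 20) &
    absent_refs
}

#' CAST on unique damaging missense carriers
#'
#' Removes the samples already explained by a likely-pathogenic LoF from
#' the case cohort, counts carriers of at least one unique damaging
#' missense variant (four-score consensus) in any panel gene, and runs the
#' one-tailed CAST. The case denominator follows the supplied exclusion
#' list and is reported, not hard-coded.
#'
#' @inheritParams carrier_counts
#' @param lof_diagnosed_sample_ids case samples to exclude.
#' @return one-row data.frame with counts and the p-value.
#' @export
damaging_missense_cast <- function(variants, samples, panel,
                                   lof_diagnosed_sample_ids = character(),
                                   uniqueness = 0.0005,
                                   cfg = filter_config(),
                                   case_label = "case",
                                   comparison_label = "comparison") {
  samples <- samples[!(samples$cohort == case_label &
                         samples$sample_id %in% lof_diagnosed_sample_ids), ,
                     drop = FALSE]
  v <- uniqueness_filter(variants, uniqueness, cfg)
  v <- v[v$gene %in% panel$gene & damaging_missense_mask(v), , drop = FALSE]
  carriers <- unique(v$sample_id)
  case_ids <- samples$sample_id[samples$cohort == case_label]
  comp_ids <- samples$sample_id[samples$cohort == comparison_label]
  a <- sum(case_ids %in% carriers)
  c_ <- sum(comp_ids %in% carriers)
  data.frame(
    carriers_case = a, n_case = length(case_ids),
    carriers_comparison = c_, n_comparison = length(comp_ids),
    p_value = cast_test(a, length(case_ids), c_, length(comp_ids)),
    stringsAsFactors = FALSE
  )
}
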