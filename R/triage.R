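#' @name triage
#' @title Inheritance-aware triage of filtered variants
#'
#' @description The triage engine classifies each filtered LoF or
#' functional (missense-class) variant as \code{likely_pathogenic},
#' \code{uncertain} or \code{excluded}, attaching machine-readable reason
#' codes. LoF variants in known genes are diagnostic when mode-consistent,
#' absent from control sets (presence tolerated for recessive genes) and on
#' the canonical transcript. Missense variants are considered only when
#' previously reported pathogenic, then pass through an ordered curation
#' checklist mirroring manual review; the inherently manual steps
#' (literature exclusion, pedigree/phenotype mode) are consumed as input
#' flag columns so the checklist stays complete without pretending to
#' automate literature review.
NULL

.reason_codes <- c(
  "R_CANDIDATE_GENE", "R_IN_CONTROLS", "R_RECESSIVE_SINGLE_ALLELE",
  "R_LITERATURE_EXCLUDED", "R_BETTER_LOF_EXPLANATION", "R_MODE_MISMATCH",
  "R_NOT_CANONICAL_TRANSCRIPT", "R_NOT_KNOWN_PATHOGENIC"
)

# presence in any configured control set: nonzero external reference
# frequency, or sharing with another individual in the internal dataset
in_controls <- function(variants) {
  fc <- freq_columns(variants)
  ref_present <- if (length(fc) > 0L) {
    fmat <- as.matrix(variants[fc])
    rowSums(!is.na(fmat) & fmat > 0) > 0
  } else {
    rep(FALSE, nrow(variants))
  }
  ref_present | variants$carriers_internal > 1L
}

on_canonical <- function(variants, panel) {
  if (!"transcript" %in% names(variants)) {
    return(rep(TRUE, nrow(variants)))
  }
  canon <- panel$transcript[match(variants$gene, panel$gene)]
  is.na(variants$transcript) | variants$transcript == canon
}

#' Check consistency with a gene's expected mode of inheritance
#'
#' Monoallelic genes qualify with het or hom genotypes. Biallelic genes
#' require a homozygous genotype or a flagged potential compound
#' heterozygote. X-linked genes qualify for male hemizygous (or homozygous)
#' calls; female het calls do not qualify by default, with a per-gene
#' override list for genes with established female-manifesting disease.
#'
#' @param variants variant table with \code{comp_het_flag}.
#' @param panel gene panel table.
#' @param samples sample table (for sex).
#' @param female_manifesting_override character vector of X-linked genes
#'   where female het carriers are accepted as diagnostic.
#' @return logical vector along \code{variants}.
#' @export
mode_consistent <- function(variants, panel, samples,
                            female_manifesting_override = character()) {
  idx <- match(variants$gene, panel$gene)
  if (anyNA(idx)) {
    stop("gene(s) absent from panel: ",
         paste(unique(variants$gene[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  inheritance <- panel$inheritance[idx]
  sex <- samples$sex[match(variants$sample_id, samples$sample_id)]
  comp_het <- if ("comp_het_flag" %in% names(variants)) {
    variants$comp_het_flag
  } else {
    rep(FALSE, nrow(variants))
  }
  zyg <- variants$zygosity

  ok <- rep(FALSE, nrow(variants))
  mono <- inheritance == "monoallelic"
  ok[mono] <- zyg[mono] %in% c("het", "hom")
  bi <- inheritance == "biallelic"
  ok[bi] <- zyg[bi] == "hom" | comp_het[bi]
  xl <- inheritance == "x_linked"
  male <- sex == "male"
  ok[xl & male] <- zyg[xl & male] %in% c("hemi", "hom")
  xf <- xl & !male
  ok[xf] <- zyg[xf] == "hom" | comp_het[xf] |
    variants$gene[xf] %in% female_manifesting_override
  ok
}

join_codes <- function(mat) {
  apply(mat, 1L, function(r) paste(colnames(mat)[r], collapse = ","))
}

classification_frame <- function(variants, verdict, pathway, codes) {
  data.frame(
    sample_id = variants$sample_id,
    gene = variants$gene,
    chrom_class = variants$chrom_class,
    pos = variants$pos,
    ref = variants$ref,
    alt = variants$alt,
    consequence = variants$consequence,
    consequence_class = variants$consequence_class,
    zygosity = variants$zygosity,
    verdict = verdict,
    pathway = pathway,
    reason_codes = codes,
    external_presence = rep(NA_integer_, nrow(variants)),
    stringsAsFactors = FALSE
  )
}

#' Triage loss-of-function variants
#'
#' A LoF variant is \code{likely_pathogenic} iff its gene is a known
#' disease gene, the genotype is consistent with the gene's inheritance
#' mode, the variant is absent from control sets (presence tolerated when
#' the gene is biallelic/recessive) and the call is on the canonical
#' transcript. All other LoF variants are \code{uncertain}, with reason
#' codes for every failing condition.
#'
#' @param variants filtered variant table with \code{consequence_class} and
#'   \code{comp_het_flag}; only rows with class \code{"lof"} are used.
#' @inheritParams mode_consistent
#' @return classification data.frame (one row per LoF record).
#' @export
triage_lof <- function(variants, panel, samples,
                       female_manifesting_override = character()) {
  lof <- variants[variants$consequence_class == "lof", , drop = FALSE]
  if (nrow(lof) == 0L) {
    return(classification_frame(lof, character(0), character(0), character(0)))
  }
  idx <- match(lof$gene, panel$gene)
  if (anyNA(idx)) {
    stop("gene(s) absent from panel: ",
         paste(unique(lof$gene[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  known <- panel$status[idx] == "known"
  biallelic <- panel$inheritance[idx] == "biallelic"
  mode_ok <- mode_consistent(lof, panel, samples, female_manifesting_override)
  controls_ok <- !in_controls(lof) | biallelic
  canon_ok <- on_canonical(lof, panel)

  lp <- known & mode_ok & controls_ok & canon_ok
  codes <- matrix(FALSE, nrow(lof), 4L,
                  dimnames = list(NULL, c(
                    "R_CANDIDATE_GENE", "R_IN_CONTROLS",
                    "R_RECESSIVE_SINGLE_ALLELE", "R_MODE_MISMATCH")))
  codes[, "R_CANDIDATE_GENE"] <- !known
  codes[, "R_IN_CONTROLS"] <- !controls_ok
  codes[, "R_RECESSIVE_SINGLE_ALLELE"] <- biallelic & !mode_ok
  codes[, "R_MODE_MISMATCH"] <- !biallelic & !mode_ok
  code_str <- join_codes(codes)
  if (any(!canon_ok)) {
    code_str[!canon_ok] <- paste0(
      ifelse(nzchar(code_str[!canon_ok]),
             paste0(code_str[!canon_ok], ","), ""),
      "R_NOT_CANONICAL_TRANSCRIPT")
  }
  classification_frame(
    lof,
    verdict = ifelse(lp, "likely_pathogenic", "uncertain"),
    pathway = ifelse(lp, "lof_known_gene", "none"),
    codes = ifelse(lp, "", code_str)
  )
}

#' Triage missense-class variants through the curation checklist
#'
#' Variants of the functional class are \code{excluded} with
#' \code{R_NOT_KNOWN_PATHOGENIC} unless previously reported pathogenic.
#' Reported variants then pass through ordered rules, stopping at the
#' first failure: (i) candidate gene; (ii) present in control sets, unless
#' the gene is biallelic; (iii) biallelic gene with only a single abnormal
#' allele; (iv) literature-excluded (input flag); (v) a likely-pathogenic
#' LoF in a different gene of the same sample better explains the disease
#' (a comp-het LoF partner in the same gene does not, so compound
#' LoF+missense diagnoses survive); (vi/vii) pedigree/phenotype mode
#' mismatch (input flag), which also covers genotypes inconsistent with the
#' gene's inheritance mode. Survivors are \code{likely_pathogenic}.
#'
#' @param variants filtered variant table with \code{consequence_class} and
#'   \code{comp_het_flag}; only rows with class \code{"functional"} are
#'   used. Optional logical columns \code{literature_excluded} and
#'   \code{mode_mismatch} feed rules (iv) and (vi/vii).
#' @param lof_classifications result of \code{\link{triage_lof}} on the
#'   same cohort, used by rule (v).
#' @inheritParams mode_consistent
#' @return classification data.frame (one row per functional record).
#' @export
triage_missense <- function(variants, panel, samples,
                            lof_classifications = NULL,
                            female_manifesting_override = character()) {
  mis <- variants[variants$consequence_class == "functional", , drop = FALSE]
  if (nrow(mis) == 0L) {
    return(classification_frame(mis, character(0), character(0), character(0)))
  }
  idx <- match(mis$gene, panel$gene)
  if (anyNA(idx)) {
    stop("gene(s) absent from panel: ",
         paste(unique(mis$gene[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  known <- panel$status[idx] == "known"
  biallelic <- panel$inheritance[idx] == "biallelic"
  comp_het <- mis$comp_het_flag
  mode_ok <- mode_consistent(mis, panel, samples, female_manifesting_override)
  lit_excl <- if ("literature_excluded" %in% names(mis)) {
    mis$literature_excluded %in% TRUE
  } else {
    rep(FALSE, nrow(mis))
  }
  mode_flag <- if ("mode_mismatch" %in% names(mis)) {
    mis$mode_mismatch %in% TRUE
  } else {
    rep(FALSE, nrow(mis))
  }

  # rule (v): the sample has a likely-pathogenic LoF in a *different* gene
  better_lof <- rep(FALSE, nrow(mis))
  if (!is.null(lof_classifications) && nrow(lof_classifications) > 0L) {
    lp <- lof_classifications[
      lof_classifications$verdict == "likely_pathogenic", , drop = FALSE]
    pair <- paste(mis$sample_id, mis$gene, sep = "\r")
    lp_pair <- paste(lp$sample_id, lp$gene, sep = "\r")
    better_lof <- mis$sample_id %in% lp$sample_id & !(pair %in% lp_pair)
  }

  # ordered checklist; first failing rule wins
  rule_codes <- rbind(
    R_NOT_KNOWN_PATHOGENIC = !(mis$known_pathogenic %in% TRUE),
    R_CANDIDATE_GENE = !known,
    R_IN_CONTROLS = in_controls(mis) & !biallelic,
    R_RECESSIVE_SINGLE_ALLELE = biallelic & !(mis$zygosity == "hom" | comp_het),
    R_LITERATURE_EXCLUDED = lit_excl,
    R_BETTER_LOF_EXPLANATION = better_lof,
    R_MODE_MISMATCH = mode_flag | !mode_ok
  )
  first_fail <- apply(rule_codes, 2L, function(col) {
    hit <- which(col)
    if (length(hit) > 0L) rownames(rule_codes)[hit[1L]] else ""
  })
  lp <- first_fail == ""
  classification_frame(
    mis,
    verdict = ifelse(lp, "likely_pathogenic", "excluded"),
    pathway = ifelse(lp, "missense_known_pathogenic", "none"),
    codes = first_fail
  )
}

#' Run the complete triage over a filtered cohort
#'
#' Applies \code{\link{triage_lof}} then \code{\link{triage_missense}}
#' (which needs the LoF verdicts for its better-LoF-explanation rule) and
#' returns the combined classification table. Verdicts are independent of
#' record order.
#'
#' @param variants filtered variant table (from \code{\link{prepare_cohort}}
#'   or equivalent) with \code{consequence_class} and \code{comp_het_flag}.
#' @inheritParams mode_consistent
#' @return classification data.frame covering all LoF and functional
#'   records.
#' @export
triage_cohort <- function(variants, panel, samples,
                          female_manifesting_override = character()) {
  if (!"consequence_class" %in% names(variants)) {
    variants <- annotate_consequence(variants)
  }
  if (!"comp_het_flag" %in% names(variants)) {
    variants <- flag_compound_het(variants)
  }
  lof_cls <- triage_lof(variants, panel, samples,
                        female_manifesting_override)
  mis_cls <- triage_missense(variants, panel, samples, lof_cls,
                             female_manifesting_override)
  out <- rbind(lof_cls, mis_cls)
  rownames(out) <- NULL
  out
}

#' Attach allele counts from a secondary reference panel
#'
#' Adds, for reporting only, the number of times each classified variant is
#' seen in a large secondary reference panel (e.g. aggregated exomes);
#' verdicts are never changed, mirroring the practice of retaining such
#' variants as likely pathogenic while recording the observation.
#'
#' @param classifications classification table.
#' @param secondary_panel data.frame with columns \code{gene, pos, ref,
#'   alt, count}.
#' @return \code{classifications} with \code{external_presence} filled in
#'   (0 for variants absent from the secondary panel).
#' @export
annotate_external_presence <- function(classifications, secondary_panel) {
  if (nrow(classifications) == 0L) return(classifications)
  key <- paste(classifications$gene, classifications$pos,
               classifications$ref, classifications$alt)
  ext <- paste(secondary_panel$gene, secondary_panel$pos,
               secondary_panel$ref, secondary_panel$alt)
  hit <- match(key, ext)
  classifications$external_presence <-
    ifelse(is.na(hit), 0L, as.integer(secondary_panel$count[hit]))
  classifications
}

#' Cohort diagnostic yield
#'
#' Per-sample union of the LoF and missense diagnostic pathways:
#' individuals diagnosed through both pathways are counted once, so
#' \code{n_diagnosed_union = n_lof + n_missense - n_both} holds exactly.
#' The yield fraction is taken over QC-passing samples.
#'
#' @param classifications classification table.
#' @param samples sample table; only rows with \code{qc_pass} contribute to
#'   the denominator.
#' @return list with \code{n_samples, n_lof_diagnosed,
#'   n_missense_diagnosed, n_both, n_diagnosed_union, yield_fraction}.
#' @export
diagnostic_yield <- function(classifications, samples) {
  qc <- samples$sample_id[samples$qc_pass %in% TRUE]
  lp <- classifications[
    classifications$verdict == "likely_pathogenic" &
      classifications$sample_id %in% qc, , drop = FALSE]
  lof_ids <- unique(lp$sample_id[lp$pathway == "lof_known_gene"])
  mis_ids <- unique(lp$sample_id[lp$pathway == "missense_known_pathogenic"])
  both <- intersect(lof_ids, mis_ids)
  union_ids <- union(lof_ids, mis_ids)
  list(
    n_samples = length(qc),
    n_lof_diagnosed = length(lof_ids),
    n_missense_diagnosed = length(mis_ids),
    n_both = length(both),
    n_diagnosed_union = length(union_ids),
    yield_fraction = length(union_ids) / length(qc)
  )
}
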