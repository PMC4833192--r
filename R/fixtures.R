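#' Deterministic regression fixtures reproducing published carrier counts
#'
#' Builds, in code and without randomness, small cohorts whose carrier
#' counts match the published contingency tables cell for cell, so the
#' enrichment module can be regressed bit-exactly:
#'
#' \describe{
#'   \item{\code{enrichment}}{986 case / 899 comparison samples (925 and
#'   466 male). Unique carriers realise every stratified-table cell --
#'   e.g. 42/986 vs 6/899 known-monoallelic LoF SNVs -- and additional
#'   samples carry a within-cohort shared LoF (internal carrier count 2)
#'   so that at the MAF<1\% rung the overall LoF carrier counts are
#'   341/986 vs 222/899 while the unique-only rung sees the stratified
#'   cells alone.}
#'   \item{\code{damaging_missense}}{case cohort with an 86-sample
#'   LoF-diagnosed exclusion list (case denominator 900) and unique
#'   damaging missense carriers 284/900 vs 245/899.}
#'   \item{\code{outliers}}{996 case samples of which 10 carry more than 30
#'   filtered variants (31..40) and one carries exactly 30, leaving 986
#'   retained after outlier exclusion.}
#' }
#'
#' Each fixture carries a \code{manifest} of its expected counts.
#'
#' @return named list of fixtures; each has \code{variants},
#'   \code{samples} and \code{manifest} (plus \code{lof_diagnosed} for the
#'   damaging-missense fixture).
#' @export
fixture_tables <- function() {
  panel <- simulate_panel(sim_config())
  list(
    enrichment = fixture_enrichment(panel),
    damaging_missense = fixture_damaging_missense(panel),
    outliers = fixture_outliers(panel)
  )
}

fixture_samples <- function(n, n_male, cohort, prefix) {
  data.frame(
    sample_id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = rep(c("male", "female"), c(n_male, n - n_male)),
    cohort = cohort, qc_pass = TRUE, variant_count = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# rows of variants of one type in one gene category, one per carrier sample
fixture_block <- function(sample_ids, sexes, genes, variant_type, pos0,
                          carriers_internal = 1L, share_pairs = FALSE) {
  n <- length(sample_ids)
  if (n == 0L) return(NULL)
  gene_idx <- rep_len(seq_len(nrow(genes)), n)
  csq <- switch(variant_type,
                lof_snv = "stop_gained",
                lof_indel = "frameshift_variant",
                synonymous = "synonymous_variant")
  vclass <- if (variant_type == "lof_indel") "indel" else "SNV"
  if (share_pairs) {
    # consecutive samples share one allele: same gene, position, alleles
    stopifnot(n %% 2L == 0L)
    pair <- rep(seq_len(n / 2L), each = 2L)
    gene_idx <- rep_len(seq_len(nrow(genes)), n / 2L)[pair]
    pos <- pos0 + pair
  } else {
    pos <- pos0 + seq_len(n)
  }
  g <- genes[gene_idx, , drop = FALSE]
  data.frame(
    sample_id = sample_ids, gene = g$gene, chrom_class = g$chrom_class,
    pos = as.integer(pos),
    ref = if (vclass == "indel") "CA" else "C",
    alt = if (vclass == "indel") "C" else "T",
    consequence = csq, variant_class = vclass,
    zygosity = ifelse(g$chrom_class == "X" & sexes == "male", "hemi", "het"),
    freq_kgp = NA_real_, freq_evs = NA_real_,
    carriers_internal = as.integer(carriers_internal),
    polyphen2 = NA_real_, sift = NA_real_, condel = NA_real_,
    cadd = NA_real_, known_pathogenic = FALSE, literature_excluded = FALSE,
    mode_mismatch = FALSE, transcript = g$transcript, planted = FALSE,
    stringsAsFactors = FALSE
  )
}

fixture_enrichment <- function(panel) {
  case <- fixture_samples(986L, 925L, "case", "CASE")
  comp <- fixture_samples(899L, 466L, "comparison", "COMP")
  samples <- rbind(case, comp)

  cat_genes <- list(
    known_monoallelic = panel[panel$status == "known" &
                                panel$inheritance == "monoallelic", ],
    known_biallelic = panel[panel$status == "known" &
                              panel$inheritance == "biallelic", ],
    candidate = panel[panel$status == "candidate" &
                        panel$chrom_class != "X", ],
    known_x = panel[panel$status == "known" & panel$inheritance == "x_linked", ],
    candidate_x = panel[panel$status == "candidate" &
                          panel$chrom_class == "X", ]
  )

  # published unique-level carrier counts per (category, type, cohort)
  manifest <- data.frame(
    gene_category = rep(c("known_monoallelic", "known_biallelic",
                          "candidate", "known_x", "candidate_x"), each = 3L),
    variant_type = rep(c("lof_snv", "lof_indel", "synonymous"), 5L),
    carriers_case = c(42L, 13L, 394L, 43L, 23L, 294L, 52L, 26L, 450L,
                      17L, 14L, 121L, 11L, 4L, 179L),
    carriers_comparison = c(6L, 7L, 357L, 26L, 13L, 258L, 22L, 23L, 400L,
                            0L, 0L, 41L, 2L, 1L, 92L),
    stringsAsFactors = FALSE
  )

  blocks <- list()
  pos0 <- 0L
  # unique carriers: within each cohort, LoF carriers of the five
  # categories occupy disjoint leading sample ranges (all male, satisfying
  # the X strata); synonymous carriers restart from the first sample since
  # variant types never compete within a row
  lof_offset_case <- 0L
  lof_offset_comp <- 0L
  for (i in seq_len(nrow(manifest))) {
    cat_i <- manifest$gene_category[i]
    vt <- manifest$variant_type[i]
    genes <- cat_genes[[cat_i]]
    for (side in c("case", "comp")) {
      cohort <- if (side == "case") case else comp
      k <- if (side == "case") manifest$carriers_case[i] else
        manifest$carriers_comparison[i]
      if (k == 0L) next
      if (vt == "synonymous") {
        ids <- cohort$sample_id[seq_len(k)]
        sexes <- cohort$sex[seq_len(k)]
      } else {
        offs <- if (side == "case") lof_offset_case else lof_offset_comp
        ids <- cohort$sample_id[offs + seq_len(k)]
        sexes <- cohort$sex[offs + seq_len(k)]
        if (side == "case") lof_offset_case <- offs + k else
          lof_offset_comp <- offs + k
      }
      blocks[[length(blocks) + 1L]] <- fixture_block(ids, sexes, genes, vt,
                                                     pos0)
      pos0 <- pos0 + k + 10L
    }
  }

  # shared (internal carrier count 2) LoF carriers lift the MAF<1% totals
  # to 341/986 and 222/899 without touching the unique-only rung
  shared_case <- 341L - lof_offset_case   # 96
  shared_comp <- 222L - lof_offset_comp   # 122
  auto_known <- cat_genes$known_monoallelic
  for (side in c("case", "comp")) {
    cohort <- if (side == "case") case else comp
    offs <- if (side == "case") lof_offset_case else lof_offset_comp
    k <- if (side == "case") shared_case else shared_comp
    ids <- cohort$sample_id[offs + seq_len(k)]
    sexes <- cohort$sex[offs + seq_len(k)]
    blocks[[length(blocks) + 1L]] <- fixture_block(
      ids, sexes, auto_known, "lof_snv", pos0, carriers_internal = 2L,
      share_pairs = TRUE)
    pos0 <- pos0 + k + 10L
  }

  variants <- do.call(rbind, blocks)
  rownames(variants) <- NULL
  manifest_total <- data.frame(
    name = "fig1_maf1pct", carriers_case = 341L, n_case = 986L,
    carriers_comparison = 222L, n_comparison = 899L,
    stringsAsFactors = FALSE
  )
  list(variants = variants, samples = samples, manifest = manifest,
       manifest_total = manifest_total)
}

fixture_damaging_missense <- function(panel) {
  case <- fixture_samples(986L, 925L, "case", "CASE")
  comp <- fixture_samples(899L, 466L, "comparison", "COMP")
  lof_diagnosed <- case$sample_id[seq_len(86L)]
  autosomal <- panel[panel$chrom_class != "X", , drop = FALSE]

  dm_block <- function(cohort, ids_idx, pos0) {
    ids <- cohort$sample_id[ids_idx]
    g <- autosomal[rep_len(seq_len(nrow(autosomal)), length(ids)), ]
    data.frame(
      sample_id = ids, gene = g$gene, chrom_class = g$chrom_class,
      pos = pos0 + seq_along(ids), ref = "C", alt = "T",
      consequence = "missense_variant", variant_class = "SNV",
      zygosity = "het", freq_kgp = NA_real_, freq_evs = NA_real_,
      carriers_internal = 1L, polyphen2 = 0.95, sift = 0.03, condel = 0.6,
      cadd = 25, known_pathogenic = FALSE, literature_excluded = FALSE,
      mode_mismatch = FALSE, transcript = g$transcript, planted = FALSE,
      stringsAsFactors = FALSE
    )
  }
  variants <- rbind(
    dm_block(case, 86L + seq_len(284L), 0L),       # carriers outside the
    dm_block(comp, seq_len(245L), 1000L)           # exclusion list
  )
  rownames(variants) <- NULL
  list(
    variants = variants, samples = rbind(case, comp),
    lof_diagnosed = lof_diagnosed,
    manifest = data.frame(carriers_case = 284L, n_case = 900L,
                          carriers_comparison = 245L, n_comparison = 899L,
                          p_value_printed = 0.025, stringsAsFactors = FALSE)
  )
}

fixture_outliers <- function(panel) {
  samples <- fixture_samples(996L, 934L, "case", "CASE")
  g <- panel[1L, , drop = FALSE]
  counts <- c(rep(1L, 985L), 30L, 31:40)  # sample 986 sits on the boundary
  sid <- rep(samples$sample_id, counts)
  n <- length(sid)
  variants <- data.frame(
    sample_id = sid, gene = g$gene, chrom_class = g$chrom_class,
    pos = seq_len(n), ref = "C", alt = "T",
    consequence = "synonymous_variant", variant_class = "SNV",
    zygosity = "het", freq_kgp = NA_real_, freq_evs = NA_real_,
    carriers_internal = 1L, polyphen2 = NA_real_, sift = NA_real_,
    condel = NA_real_, cadd = NA_real_, known_pathogenic = FALSE,
    literature_excluded = FALSE, mode_mismatch = FALSE,
    transcript = g$transcript, planted = FALSE, stringsAsFactors = FALSE
  )
  list(variants = variants, samples = samples,
       manifest = data.frame(n_samples = 996L, n_retained = 986L,
                             n_excluded = 10L, stringsAsFactors = FALSE))
}
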