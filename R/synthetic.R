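#' Simulation configuration for synthetic case/comparison cohorts
#'
#' Defaults reproduce the structure of a large proband-only intellectual
#' disability panel study: 986 cases (93.8\% male) against 899 comparison
#' samples sequenced on the same 565-gene panel (253 known + 312 candidate
#' genes), a mean of 0.46 rare LoF and 8 rare missense variants per person
#' after frequency filtering, and planted diagnostic fractions of 8\% (LoF)
#' and 3\% (missense) with 3 dual-pathway individuals.
#'
#' @param n_case,n_comparison cohort sizes.
#' @param male_fraction_case,male_fraction_comparison male fractions; the
#'   comparison default 466/899 is inferred from male-only stratum
#'   denominators, not a quoted value.
#' @param panel_size,n_known,n_candidate panel composition.
#' @param mean_lof_per_person,mean_missense_per_person,mean_synonymous_per_person,mean_common_per_person
#'   per-person background variant count means (post-filter classes plus a
#'   common class that the MAF filter removes).
#' @param planted_lof_diagnostic_fraction,planted_missense_diagnostic_fraction
#'   fractions of case samples given a planted diagnostic variant.
#' @param dual_pathway_overlap number of case samples planted with both a
#'   LoF and a missense diagnosis (as a comp-het pair in one biallelic
#'   gene, so both survive triage).
#' @param unique_prob probability a background variant is carried by a
#'   single individual in the internal multi-phenotype dataset.
#' @param background_reference_presence_prob probability a background
#'   variant is present (below the MAF threshold) in an external reference
#'   set.
#' @param known_pathogenic_background_prob fraction of background missense
#'   records flagged as previously reported pathogenic, feeding the
#'   curation checklist with realistic decoys.
#' @param literature_excluded_prob fraction of those decoys carrying the
#'   literature-exclusion flag; the default matches the published curation
#'   attrition in which ~91\% of previously reported missense variants
#'   were removed by manual review.
#' @param lof_gene_weights named per-category relative weights for the
#'   gene choice of background LoF variants (categories
#'   \code{known_monoallelic, known_biallelic, candidate_autosome,
#'   known_x, candidate_x}). The defaults are calibrated to the comparison
#'   cohort's published unique-carrier structure, which shows strong LoF
#'   depletion in known monoallelic and especially known X-linked genes
#'   (purifying selection) and relative tolerance in biallelic genes. Set
#'   all weights to 1 for uniform gene choice.
#' @param damaging_score_prob fraction of background missense variants
#'   whose four in-silico scores all clear the damaging consensus.
#' @param count_model \code{"poisson"} (default, minimal assumption given
#'   only published means) or \code{"nbinom"} for overdispersed counts.
#' @param nbinom_size negative-binomial size when
#'   \code{count_model = "nbinom"}.
#' @param seed RNG seed; with the seed fixed the simulation is
#'   byte-identical across runs.
#' @return list of class \code{"idpanel_sim_config"}.
#' @export
sim_config <- function(n_case = 986L, n_comparison = 899L,
                       male_fraction_case = 0.938,
                       male_fraction_comparison = 466 / 899,
                       panel_size = 565L, n_known = 253L, n_candidate = 312L,
                       mean_lof_per_person = 0.46,
                       mean_missense_per_person = 8,
                       mean_synonymous_per_person = 4,
                       mean_common_per_person = 1,
                       planted_lof_diagnostic_fraction = 0.08,
                       planted_missense_diagnostic_fraction = 0.03,
                       dual_pathway_overlap = 3L,
                       unique_prob = 0.5,
                       background_reference_presence_prob = 0.45,
                       known_pathogenic_background_prob = 0.05,
                       literature_excluded_prob = 0.9,
                       lof_gene_weights = c(known_monoallelic = 0.8,
                                            known_biallelic = 2.2,
                                            candidate_autosome = 1.4,
                                            known_x = 0.05,
                                            candidate_x = 0.2),
                       damaging_score_prob = 0.05,
                       count_model = c("poisson", "nbinom"),
                       nbinom_size = 2,
                       seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(
    n_case = as.integer(n_case), n_comparison = as.integer(n_comparison),
    male_fraction_case = male_fraction_case,
    male_fraction_comparison = male_fraction_comparison,
    panel_size = as.integer(panel_size), n_known = as.integer(n_known),
    n_candidate = as.integer(n_candidate),
    mean_lof_per_person = mean_lof_per_person,
    mean_missense_per_person = mean_missense_per_person,
    mean_synonymous_per_person = mean_synonymous_per_person,
    mean_common_per_person = mean_common_per_person,
    planted_lof_diagnostic_fraction = planted_lof_diagnostic_fraction,
    planted_missense_diagnostic_fraction = planted_missense_diagnostic_fraction,
    dual_pathway_overlap = as.integer(dual_pathway_overlap),
    unique_prob = unique_prob,
    background_reference_presence_prob = background_reference_presence_prob,
    known_pathogenic_background_prob = known_pathogenic_background_prob,
    literature_excluded_prob = literature_excluded_prob,
    lof_gene_weights = lof_gene_weights,
    damaging_score_prob = damaging_score_prob,
    count_model = count_model, nbinom_size = nbinom_size,
    seed = as.integer(seed)
  )
  with(cfg, stopifnot(
    n_case >= 0, n_comparison >= 0,
    male_fraction_case >= 0, male_fraction_case <= 1,
    male_fraction_comparison >= 0, male_fraction_comparison <= 1,
    n_known + n_candidate == panel_size,
    mean_lof_per_person > 0, mean_missense_per_person > 0,
    planted_lof_diagnostic_fraction >= 0,
    planted_missense_diagnostic_fraction >= 0,
    planted_lof_diagnostic_fraction +
      planted_missense_diagnostic_fraction <= 1
  ))
  structure(cfg, class = "idpanel_sim_config")
}

# default category proportions: known mono 78, known biallelic 86,
# known X 89 (= 253); candidate autosomal 162, candidate X 150 (= 312)
.known_props <- c(monoallelic = 78, biallelic = 86, x_linked = 89) / 253
.candidate_props <- c(autosome = 162, X = 150) / 312

# largest-remainder apportionment of n into proportions p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

#' Generate a deterministic synthetic gene panel
#'
#' Known genes are split into monoallelic, biallelic-autosomal and
#' X-linked groups and candidates into autosomal and X groups, in the
#' default proportions 78/86/89 and 162/150; overriding \code{n_known},
#' \code{n_candidate} or \code{panel_size} re-apportions by
#' largest-remainder so the sums always match. The construction uses no
#' randomness.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return panel data.frame (\code{gene, status, chrom_class, inheritance,
#'   transcript}).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  if (cfg$n_known + cfg$n_candidate != cfg$panel_size) {
    stop("n_known + n_candidate must equal panel_size", call. = FALSE)
  }
  k <- apportion(cfg$n_known, .known_props)
  cn <- apportion(cfg$n_candidate, .candidate_props)
  mk <- function(prefix, n, status, chrom, inh) {
    if (n == 0L) return(NULL)
    gene <- sprintf("%s%03d", prefix, seq_len(n))
    data.frame(gene = gene, status = status, chrom_class = chrom,
               inheritance = inh, transcript = paste0("TX_", gene),
               stringsAsFactors = FALSE)
  }
  panel <- rbind(
    mk("KNM", k[1L], "known", "autosome", "monoallelic"),
    mk("KNB", k[2L], "known", "autosome", "biallelic"),
    mk("KNX", k[3L], "known", "X", "x_linked"),
    mk("CAA", cn[1L], "candidate", "autosome", "monoallelic"),
    mk("CAX", cn[2L], "candidate", "X", "x_linked")
  )
  rownames(panel) <- NULL
  panel
}

.empty_variants <- function() {
  data.frame(
    sample_id = character(0), gene = character(0),
    chrom_class = character(0), pos = integer(0), ref = character(0),
    alt = character(0), consequence = character(0),
    variant_class = character(0), zygosity = character(0),
    freq_kgp = numeric(0), freq_evs = numeric(0),
    carriers_internal = integer(0), polyphen2 = numeric(0),
    sift = numeric(0), condel = numeric(0), cadd = numeric(0),
    known_pathogenic = logical(0), literature_excluded = logical(0),
    mode_mismatch = logical(0), transcript = character(0),
    planted = logical(0), stringsAsFactors = FALSE
  )
}

.bases <- c("A", "C", "G", "T")

# per-gene sampling weight from the per-category weight vector
panel_gene_weights <- function(panel, w) {
  cat_of <- ifelse(
    panel$status == "known",
    ifelse(panel$inheritance == "monoallelic", "known_monoallelic",
           ifelse(panel$inheritance == "biallelic", "known_biallelic",
                  "known_x")),
    ifelse(panel$chrom_class == "X", "candidate_x", "candidate_autosome")
  )
  unname(w[cat_of])
}

# draw per-sample counts under the configured count model
draw_counts <- function(n, mean, cfg) {
  if (n == 0L || mean <= 0) return(integer(n))
  if (cfg$count_model == "poisson") {
    stats::rpois(n, mean)
  } else {
    stats::rnbinom(n, size = cfg$nbinom_size, mu = mean)
  }
}

# one block of background variants of a given class for a sample vector
gen_background <- function(sample_ids, sex, class, mean, cfg, panel,
                           pos_offset) {
  counts <- draw_counts(length(sample_ids), mean, cfg)
  tot <- sum(counts)
  if (tot == 0L) return(.empty_variants())
  sid <- rep(sample_ids, counts)
  sx <- rep(sex, counts)
  gw <- if (class == "lof") panel_gene_weights(panel, cfg$lof_gene_weights)
        else NULL
  gi <- sample.int(nrow(panel), tot, replace = TRUE, prob = gw)

  consequence <- switch(class,
    lof = sample(c("stop_gained", "frameshift_variant",
                   "splice_donor_variant", "splice_acceptor_variant"),
                 tot, replace = TRUE, prob = c(184, 161, 66, 44)),
    missense = sample(c("missense_variant", "inframe_insertion",
                        "inframe_deletion", "stop_lost"),
                      tot, replace = TRUE, prob = c(0.94, 0.02, 0.03, 0.01)),
    synonymous = rep("synonymous_variant", tot),
    common = sample(c("missense_variant", "synonymous_variant"), tot,
                    replace = TRUE)
  )
  is_indel <- consequence %in% c("frameshift_variant", "inframe_insertion",
                                 "inframe_deletion")
  ref <- sample(.bases, tot, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.bases, b), 1L),
                character(1))
  alt[consequence == "frameshift_variant"] <-
    paste0(ref[consequence == "frameshift_variant"], "A")
  alt[consequence == "inframe_insertion"] <-
    paste0(ref[consequence == "inframe_insertion"], "AGT")
  del <- consequence == "inframe_deletion"
  ref[del] <- paste0(ref[del], "AGT")
  alt[del] <- substr(ref[del], 1L, 1L)

  chrom_class <- panel$chrom_class[gi]
  zygosity <- ifelse(chrom_class == "X" & sx == "male", "hemi", "het")

  if (class == "common") {
    carriers <- pmax(29L, stats::rpois(tot, 200))
    freq_kgp <- stats::runif(tot, 0.01, 0.5)
    freq_evs <- stats::runif(tot, 0.01, 0.5)
  } else {
    is_unique <- stats::runif(tot) < cfg$unique_prob
    carriers <- ifelse(is_unique, 1L, 2L + stats::rpois(tot, 2))
    in_ref <- stats::runif(tot) < cfg$background_reference_presence_prob
    freq_kgp <- ifelse(in_ref, stats::runif(tot, 1e-5, 0.0099), NA_real_)
    freq_evs <- ifelse(in_ref & stats::runif(tot) < 0.5,
                       stats::runif(tot, 1e-5, 0.0099), NA_real_)
  }

  pp2 <- sift <- condel <- cadd <- rep(NA_real_, tot)
  kp <- lit <- rep(FALSE, tot)
  if (class %in% c("missense", "common")) {
    mis <- consequence == "missense_variant"
    nm <- sum(mis)
    dmg <- stats::runif(nm) < cfg$damaging_score_prob
    pp2[mis] <- ifelse(dmg, stats::runif(nm, 0.901, 1), stats::runif(nm))
    sift[mis] <- ifelse(dmg, stats::runif(nm, 0, 0.059), stats::runif(nm))
    condel[mis] <- ifelse(dmg, stats::runif(nm, 0.475, 1), stats::runif(nm))
    cadd[mis] <- ifelse(dmg, stats::runif(nm, 20.5, 45),
                        stats::runif(nm, 0, 40))
    cadd[mis][stats::runif(nm) < 0.05] <- NA_real_  # occasional missing score
  }
  if (class == "missense") {
    kp <- stats::runif(tot) < cfg$known_pathogenic_background_prob
    lit <- kp & stats::runif(tot) < cfg$literature_excluded_prob
  }

  data.frame(
    sample_id = sid, gene = panel$gene[gi], chrom_class = chrom_class,
    pos = pos_offset + seq_len(tot), ref = ref, alt = alt,
    consequence = consequence,
    variant_class = ifelse(is_indel, "indel", "SNV"),
    zygosity = zygosity, freq_kgp = freq_kgp, freq_evs = freq_evs,
    carriers_internal = as.integer(carriers), polyphen2 = pp2, sift = sift,
    condel = condel, cadd = cadd, known_pathogenic = kp,
    literature_excluded = lit, mode_mismatch = FALSE,
    transcript = panel$transcript[gi], planted = FALSE,
    stringsAsFactors = FALSE
  )
}

# a single planted record, unique and absent from all reference sets
planted_record <- function(sample_id, gene_row, consequence, variant_class,
                           zygosity, pos, damaging = FALSE, kp = FALSE) {
  data.frame(
    sample_id = sample_id, gene = gene_row$gene,
    chrom_class = gene_row$chrom_class, pos = pos,
    ref = "C", alt = if (variant_class == "indel") "CA" else "T",
    consequence = consequence, variant_class = variant_class,
    zygosity = zygosity, freq_kgp = NA_real_, freq_evs = NA_real_,
    carriers_internal = 1L,
    polyphen2 = if (damaging) 0.98 else NA_real_,
    sift = if (damaging) 0.01 else NA_real_,
    condel = if (damaging) 0.8 else NA_real_,
    cadd = if (damaging) 28 else NA_real_,
    known_pathogenic = kp, literature_excluded = FALSE,
    mode_mismatch = FALSE, transcript = gene_row$transcript,
    planted = TRUE, stringsAsFactors = FALSE
  )
}

#' Simulate case and comparison cohorts with known ground truth
#'
#' Background variants (LoF, missense, synonymous, plus a common class the
#' MAF filter removes) are drawn identically in both cohorts; planted
#' diagnostic variants -- unique, absent from reference sets,
#' mode-consistent, on the canonical transcript -- go into the case cohort
#' only. Planted LoF diagnoses are heterozygous in monoallelic genes,
#' homozygous or compound-heterozygous in biallelic genes, and hemizygous
#' in X-linked genes (male samples only by default). Planted missense
#' diagnoses carry the known-pathogenic flag and damaging scores.
#' Dual-pathway samples receive a comp-het LoF + known-pathogenic missense
#' pair in one biallelic gene. Internal carrier counts of background
#' variants refer to the full multi-phenotype internal dataset, of which
#' the two generated cohorts are a subset, so shared counts need not be
#' realised inside the generated tables.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param panel gene panel (default \code{simulate_panel(cfg)}).
#' @return list with \code{variants}, \code{samples}, \code{truth} (one
#'   row per planted diagnosis: sample, pathway, gene, site) and
#'   \code{panel}.
#' @export
simulate_cohorts <- function(cfg = sim_config(), panel = simulate_panel(cfg)) {
  set.seed(cfg$seed)

  mk_samples <- function(n, male_frac, cohort, prefix) {
    n_male <- round(n * male_frac)
    data.frame(
      sample_id = sprintf("%s%04d", prefix, seq_len(n)),
      sex = rep(c("male", "female"), c(n_male, n - n_male)),
      cohort = cohort, qc_pass = TRUE, variant_count = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  case <- mk_samples(cfg$n_case, cfg$male_fraction_case, "case", "CASE")
  comp <- mk_samples(cfg$n_comparison, cfg$male_fraction_comparison,
                     "comparison", "COMP")
  samples <- rbind(case, comp)

  # background: identical generative process in both cohorts
  blocks <- list()
  off <- 0L
  for (cohort_df in list(case, comp)) {
    for (spec in list(list("lof", cfg$mean_lof_per_person),
                      list("missense", cfg$mean_missense_per_person),
                      list("synonymous", cfg$mean_synonymous_per_person),
                      list("common", cfg$mean_common_per_person))) {
      b <- gen_background(cohort_df$sample_id, cohort_df$sex, spec[[1L]],
                          spec[[2L]], cfg, panel, off)
      off <- off + 2000000L
      blocks[[length(blocks) + 1L]] <- b
    }
  }

  # planted diagnoses in the case cohort
  truth <- data.frame(sample_id = character(0), pathway = character(0),
                      gene = character(0), pos = integer(0),
                      stringsAsFactors = FALSE)
  known <- panel[panel$status == "known", , drop = FALSE]
  known_bi <- known[known$inheritance == "biallelic", , drop = FALSE]
  n_lof <- round(cfg$n_case * cfg$planted_lof_diagnostic_fraction)
  n_mis <- round(cfg$n_case * cfg$planted_missense_diagnostic_fraction)
  n_dual <- min(cfg$dual_pathway_overlap, n_lof, n_mis)
  plant_pos <- 900000000L

  if (n_lof + n_mis - n_dual > 0L && nrow(known) > 0L) {
    chosen <- sample(case$sample_id, n_lof + n_mis - n_dual)
    dual_ids <- if (n_dual > 0L) chosen[seq_len(n_dual)] else character(0)
    lof_ids <- chosen[seq_len(n_lof)]          # includes dual ids
    mis_only <- setdiff(chosen, lof_ids)
    sex_of <- function(id) case$sex[match(id, case$sample_id)]

    pick_gene <- function(pool, sex) {
      if (sex == "female") pool <- pool[pool$chrom_class != "X", , drop = FALSE]
      pool[sample.int(nrow(pool), 1L), , drop = FALSE]
    }
    for (id in setdiff(lof_ids, dual_ids)) {
      g <- pick_gene(known, sex_of(id))
      lof_csq <- sample(c("stop_gained", "frameshift_variant",
                          "splice_donor_variant", "splice_acceptor_variant"),
                        1L, prob = c(184, 161, 66, 44))
      vclass <- if (lof_csq == "frameshift_variant") "indel" else "SNV"
      if (g$inheritance == "biallelic" && stats::runif(1) < 0.5) {
        # compound heterozygote: two distinct het LoF alleles
        rec <- rbind(
          planted_record(id, g, lof_csq, vclass, "het", plant_pos),
          planted_record(id, g, "stop_gained", "SNV", "het", plant_pos + 1L))
        plant_pos <- plant_pos + 2L
      } else {
        zyg <- switch(g$inheritance, monoallelic = "het", biallelic = "hom",
                      x_linked = "hemi")
        rec <- planted_record(id, g, lof_csq, vclass, zyg, plant_pos)
        plant_pos <- plant_pos + 1L
      }
      blocks[[length(blocks) + 1L]] <- rec
      truth <- rbind(truth, data.frame(
        sample_id = id, pathway = "lof", gene = g$gene, pos = rec$pos[1L],
        stringsAsFactors = FALSE))
    }
    for (id in mis_only) {
      g <- pick_gene(known, sex_of(id))
      if (g$inheritance == "biallelic") {
        rec <- rbind(
          planted_record(id, g, "missense_variant", "SNV", "het", plant_pos,
                         damaging = TRUE, kp = TRUE),
          planted_record(id, g, "missense_variant", "SNV", "het",
                         plant_pos + 1L, damaging = TRUE, kp = TRUE))
        plant_pos <- plant_pos + 2L
      } else {
        zyg <- if (g$inheritance == "x_linked") "hemi" else "het"
        rec <- planted_record(id, g, "missense_variant", "SNV", zyg,
                              plant_pos, damaging = TRUE, kp = TRUE)
        plant_pos <- plant_pos + 1L
      }
      blocks[[length(blocks) + 1L]] <- rec
      truth <- rbind(truth, data.frame(
        sample_id = id, pathway = "missense", gene = g$gene,
        pos = rec$pos[1L], stringsAsFactors = FALSE))
    }
    for (id in dual_ids) {
      # comp-het LoF + known-pathogenic missense in one biallelic gene
      g <- known_bi[sample.int(nrow(known_bi), 1L), , drop = FALSE]
      lof_rec <- planted_record(id, g, "stop_gained", "SNV", "het", plant_pos)
      mis_rec <- planted_record(id, g, "missense_variant", "SNV", "het",
                                plant_pos + 1L, damaging = TRUE, kp = TRUE)
      plant_pos <- plant_pos + 2L
      blocks[[length(blocks) + 1L]] <- rbind(lof_rec, mis_rec)
      truth <- rbind(truth, data.frame(
        sample_id = c(id, id), pathway = c("lof", "missense"),
        gene = g$gene, pos = c(lof_rec$pos, mis_rec$pos),
        stringsAsFactors = FALSE))
    }
  }

  variants <- do.call(rbind, blocks)
  rownames(variants) <- NULL
  list(variants = variants, samples = samples, truth = truth, panel = panel)
}
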