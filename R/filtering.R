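#' Filtering configuration
#'
#' Parameters of the rare-variant filtering stage.
#'
#' @param maf_threshold minor-allele-frequency cut-off applied to every
#'   reference set and to the internal cohort frequency. The wording
#'   "MAF < 1\%" is read strictly: a frequency exactly equal to the
#'   threshold is dropped.
#' @param internal_freq_thresholds descending ladder of internal-frequency
#'   thresholds used by \code{\link{uniqueness_filter}} and
#'   \code{\link{threshold_sweep}}. At the default lowest rung (0.05\%) with
#'   an internal cohort of 2,812 individuals only variants carried by a
#'   single individual survive.
#' @param outlier_variant_cutoff samples with strictly more than this many
#'   variants after frequency filtering are excluded as technical outliers.
#' @param internal_cohort_size number of individuals in the full
#'   multi-phenotype dataset used as the denominator for internal carrier
#'   frequencies. The denominator is individuals, not chromosomes, because
#'   internal filtering is carrier-based.
#' @param extra_terms consequence terms to accept beyond the built-in
#'   vocabulary; they classify as \code{"other"}.
#' @return a list of class \code{"idpanel_filter_config"}.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          internal_freq_thresholds = c(0.01, 0.005, 0.001, 0.0005),
                          outlier_variant_cutoff = 30L,
                          internal_cohort_size = 2812L,
                          extra_terms = character()) {
  stopifnot(
    is.numeric(maf_threshold), length(maf_threshold) == 1L,
    maf_threshold > 0, maf_threshold <= 1,
    is.numeric(internal_freq_thresholds),
    all(diff(internal_freq_thresholds) < 0),
    outlier_variant_cutoff > 0,
    internal_cohort_size >= 1
  )
  structure(
    list(maf_threshold = maf_threshold,
         internal_freq_thresholds = internal_freq_thresholds,
         outlier_variant_cutoff = as.integer(outlier_variant_cutoff),
         internal_cohort_size = as.integer(internal_cohort_size),
         extra_terms = extra_terms),
    class = "idpanel_filter_config"
  )
}

# names of the reference-set frequency columns in a variant table
freq_columns <- function(variants) {
  grep("^freq_", names(variants), value = TRUE)
}

#' Frequency filter against reference sets and the internal cohort
#'
#' A record is dropped iff its allele frequency in any reference set
#' (columns \code{freq_*}; \code{NA} means unobserved) is at or above
#' \code{maf_threshold}, or its internal carrier frequency
#' (\code{carriers_internal / internal_cohort_size}) is at or above the
#' threshold. A variant never observed anywhere is kept.
#'
#' @param variants variant table.
#' @param cfg a \code{\link{filter_config}}.
#' @return \code{variants} with logical \code{keep_flag} and character
#'   \code{drop_reason} (\code{NA} for kept records) columns added. Subset
#'   on \code{keep_flag} to obtain the filtered table.
#' @export
frequency_filter <- function(variants, cfg = filter_config()) {
  fc <- freq_columns(variants)
  fmat <- as.matrix(variants[fc])
  if (length(fc) > 0L) {
    bad <- !is.na(fmat) & (fmat < 0 | fmat > 1)
    if (any(bad)) {
      stop("reference frequency outside [0,1] at row(s): ",
           paste(utils::head(which(rowSums(bad) > 0), 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  ref_hit <- rep(NA_character_, nrow(variants))
  if (length(fc) > 0L && nrow(variants) > 0L) {
    exceed <- !is.na(fmat) & fmat >= cfg$maf_threshold
    any_hit <- rowSums(exceed) > 0L
    first <- max.col(exceed, ties.method = "first")
    ref_hit[any_hit] <- fc[first[any_hit]]
  }
  internal_freq <- variants$carriers_internal / cfg$internal_cohort_size
  internal_hit <- internal_freq >= cfg$maf_threshold

  variants$keep_flag <- is.na(ref_hit) & !internal_hit
  variants$drop_reason <- ifelse(
    !is.na(ref_hit), paste0("ref_freq:", ref_hit),
    ifelse(internal_hit, "internal_freq", NA_character_)
  )
  variants
}

#' Exclude samples with outlying variant counts
#'
#' Samples carrying strictly more than \code{outlier_variant_cutoff}
#' variants after frequency filtering are excluded as likely technical
#' artifacts; a sample with exactly the cutoff count is retained.
#'
#' @param samples sample table.
#' @param variants frequency-filtered variant table (only rows with
#'   \code{keep_flag} are counted; if the column is absent, all rows count).
#' @param cfg a \code{\link{filter_config}}.
#' @return list with elements \code{retained} and \code{excluded}, both
#'   sample tables with \code{variant_count} filled in and \code{qc_pass}
#'   set accordingly.
#' @export
exclude_outlier_samples <- function(samples, variants, cfg = filter_config()) {
  kept <- if ("keep_flag" %in% names(variants)) {
    variants[variants$keep_flag, , drop = FALSE]
  } else {
    variants
  }
  counts <- table(factor(kept$sample_id, levels = samples$sample_id))
  samples$variant_count <- as.integer(counts[samples$sample_id])
  out <- samples$variant_count > cfg$outlier_variant_cutoff
  samples$qc_pass <- !out
  list(retained = samples[!out, , drop = FALSE],
       excluded = samples[out, , drop = FALSE])
}

#' Internal-frequency (uniqueness) filter
#'
#' Retains records whose internal carrier frequency
#' (\code{carriers_internal / internal_cohort_size}) is strictly below
#' \code{threshold}. At the default 0.05\% rung with 2,812 internal
#' individuals this keeps exactly the variants carried by one individual
#' ("unique" variants).
#'
#' @param variants variant table.
#' @param threshold internal frequency threshold; if not one of the
#'   configured ladder rungs a warning is emitted and the value is still
#'   honoured.
#' @param cfg a \code{\link{filter_config}}.
#' @return the retained subset of \code{variants}.
#' @export
uniqueness_filter <- function(variants, threshold = 0.0005,
                              cfg = filter_config()) {
  if (!isTRUE(any(abs(threshold - cfg$internal_freq_thresholds) < 1e-12))) {
    warning("threshold ", threshold,
            " is not in the configured ladder; honouring it anyway")
  }
  keep <- variants$carriers_internal / cfg$internal_cohort_size < threshold
  variants[keep, , drop = FALSE]
}

# variant identity key: one allele at one site on one transcript
variant_key <- function(variants) {
  tx <- if ("transcript" %in% names(variants)) variants$transcript else ""
  paste(variants$chrom_class, variants$pos, variants$ref, variants$alt, tx,
        sep = ":")
}

#' Flag potential compound heterozygotes
#'
#' A (sample, gene) pair is flagged when the sample carries two or more
#' distinct heterozygous records in that gene; homozygous and hemizygous
#' records do not contribute (they follow their own inheritance pathway).
#'
#' @param variants variant table.
#' @return \code{variants} with a logical \code{comp_het_flag} column: TRUE
#'   on every record (het or not) of a flagged (sample, gene) pair.
#' @export
flag_compound_het <- function(variants) {
  if (nrow(variants) == 0L) {
    variants$comp_het_flag <- logical(0)
    return(variants)
  }
  grp <- paste(variants$sample_id, variants$gene, sep = "\r")
  het <- variants$zygosity == "het"
  key <- variant_key(variants)
  nhet <- tapply(ifelse(het, key, NA_character_), grp,
                 function(k) length(unique(k[!is.na(k)])))
  variants$comp_het_flag <- unname(nhet[grp] >= 2L)
  variants
}

#' Run the full pre-triage filtering pipeline
#'
#' Convenience wrapper: consequence annotation, frequency filter, outlier
#' sample exclusion, compound-heterozygote flagging. Emits one structured
#' log line per stage with input/output record counts.
#'
#' @param variants raw variant table.
#' @param samples sample table.
#' @param cfg a \code{\link{filter_config}}.
#' @param quiet suppress log messages.
#' @return list with \code{variants} (filtered, annotated, flagged),
#'   \code{samples} (retained), \code{excluded_samples}, and
#'   \code{dropped_variants}.
#' @export
prepare_cohort <- function(variants, samples, cfg = filter_config(),
                           quiet = FALSE) {
  log_stage <- function(stage, n_in, n_out) {
    if (!quiet) {
      message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
    }
  }
  n0 <- nrow(variants)
  variants <- annotate_consequence(variants, cfg)
  variants <- frequency_filter(variants, cfg)
  kept <- variants[variants$keep_flag, , drop = FALSE]
  dropped <- variants[!variants$keep_flag, , drop = FALSE]
  log_stage("frequency_filter", n0, nrow(kept))

  split_samples <- exclude_outlier_samples(samples, kept, cfg)
  log_stage("exclude_outliers", nrow(samples), nrow(split_samples$retained))

  n1 <- nrow(kept)
  kept <- kept[kept$sample_id %in% split_samples$retained$sample_id, ,
               drop = FALSE]
  log_stage("drop_outlier_variants", n1, nrow(kept))

  kept <- flag_compound_het(kept)
  list(variants = kept,
       samples = split_samples$retained,
       excluded_samples = split_samples$excluded,
       dropped_variants = dropped)
}
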