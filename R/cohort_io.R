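#' @importFrom utils read.delim write.table head
NULL

.required_variant_cols <- c(
  "sample_id", "gene", "chrom_class", "pos", "ref", "alt", "consequence",
  "variant_class", "zygosity", "carriers_internal", "polyphen2", "sift",
  "condel", "cadd", "known_pathogenic"
)

.chrom_classes <- c("autosome", "PAR", "X")

#' Validate a variant table
#'
#' Checks required columns and per-row invariants: positive 1-based
#' positions, controlled zygosity and chromosome-class vocabularies,
#' reference frequencies in [0,1], internal carrier counts of at least one,
#' and (when a sample table is supplied) that hemizygous calls occur only on
#' the X chromosome in male samples. Failing rows are reported with their
#' row numbers.
#'
#' @param variants variant table.
#' @param samples optional sample table used for the sex-aware hemizygosity
#'   check and to verify every sample_id is known.
#' @param extra_terms extra consequence terms to accept.
#' @return \code{variants}, invisibly, if valid; otherwise an error.
#' @export
validate_variants <- function(variants, samples = NULL,
                              extra_terms = character()) {
  missing_cols <- setdiff(.required_variant_cols, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail <- function(rows, why) {
    if (length(rows) > 0L) {
      stop("invalid variant row(s) [", why, "]: ",
           paste(head(rows, 10L), collapse = ", "), call. = FALSE)
    }
  }
  fail(which(!(variants$pos >= 1)), "pos must be >= 1")
  fail(which(!variants$chrom_class %in% .chrom_classes),
       "chrom_class not in {autosome, PAR, X}")
  fail(which(!variants$zygosity %in% c("het", "hom", "hemi")),
       "zygosity not in {het, hom, hemi}")
  fail(which(!variants$variant_class %in% c("SNV", "indel")),
       "variant_class not in {SNV, indel}")
  fail(which(!(variants$carriers_internal >= 1)),
       "carriers_internal must be >= 1 for an observed variant")
  classify_consequence(variants$consequence, extra_terms)  # errors if unknown
  for (fc in freq_columns(variants)) {
    f <- variants[[fc]]
    fail(which(!is.na(f) & (f < 0 | f > 1)), paste0(fc, " outside [0,1]"))
  }
  hemi <- variants$zygosity == "hemi"
  fail(which(hemi & variants$chrom_class != "X"),
       "hemizygous call off the X chromosome")
  if (!is.null(samples)) {
    fail(which(!variants$sample_id %in% samples$sample_id),
         "sample_id absent from sample table")
    sex <- samples$sex[match(variants$sample_id, samples$sample_id)]
    fail(which(hemi & sex != "male"), "hemizygous call in a female sample")
  }
  invisible(variants)
}

#' Read a per-sample variant table
#'
#' Two dialects are supported. The TSV dialect has one row per observed
#' variant call per sample with columns \code{sample_id, gene, chrom_class,
#' pos, ref, alt, consequence, variant_class, zygosity, freq_<set>...,
#' carriers_internal, polyphen2, sift, condel, cadd, known_pathogenic} and
#' optionally \code{transcript, literature_excluded, mode_mismatch}.
#' Coordinates are 1-based inclusive in both dialects.
#'
#' The VCF dialect reads a minimal VCF 4.2 through \pkg{vcfR}: per-sample
#' genotypes (GT \code{0/1} -> het, \code{1/1} -> hom, haploid \code{1} ->
#' hemi) and annotations from INFO keys \code{GENE, CSQCLASS, PP2, SIFT,
#' CONDEL, CADD, KP}, plus optional \code{KGP, EVS} (reference-set allele
#' frequencies, mapped to \code{freq_kgp}/\code{freq_evs}) and
#' \code{CARRIERS} (internal carrier count; defaults to the number of
#' carrier samples in the file). \code{chrom_class} is X for chromosome
#' "X"/"chrX" and autosome otherwise.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @param samples optional sample table for sex-aware validation.
#' @param extra_terms extra consequence terms to accept.
#' @return validated variant data.frame.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               samples = NULL, extra_terms = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  variants <- if (dialect == "tsv") {
    read_variant_tsv(path)
  } else {
    read_variant_vcf(path)
  }
  validate_variants(variants, samples, extra_terms)
  variants
}

read_variant_tsv <- function(path) {
  # allele strings like "T" must never be coerced to logicals
  char_cols <- c(sample_id = "character", gene = "character",
                 chrom_class = "character", ref = "character",
                 alt = "character", consequence = "character",
                 variant_class = "character", zygosity = "character",
                 transcript = "character")
  hdr <- names(read.delim(path, nrows = 1L, check.names = FALSE))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = char_cols[names(char_cols) %in% hdr])
  missing_cols <- setdiff(.required_variant_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant TSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  df$carriers_internal <- as.integer(df$carriers_internal)
  df$known_pathogenic <- as.logical(df$known_pathogenic)
  for (col in c("literature_excluded", "mode_mismatch")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  for (col in c(freq_columns(df), "polyphen2", "sift", "condel", "cadd")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF carries no per-sample GT field", call. = FALSE)
  n_var <- nrow(fix)
  sample_ids <- colnames(gt)

  zyg_of <- function(g) {
    g <- gsub("\\|", "/", g)
    if (is.na(g) || g %in% c(".", "./.", "0/0", "0")) return(NA_character_)
    alleles <- strsplit(g, "/", fixed = TRUE)[[1L]]
    if (length(alleles) == 1L) return("hemi")
    if (all(alleles == "1")) return("hom")
    "het"
  }

  num_info <- function(key) suppressWarnings(as.numeric(info_get(key)))
  gene <- info_get("GENE")
  csq <- info_get("CSQCLASS")
  kp <- grepl("(^|;)KP(;|$)", fix$INFO)  # Flag-type INFO key
  carriers <- suppressWarnings(as.integer(info_get("CARRIERS")))
  pp2 <- num_info("PP2"); sift <- num_info("SIFT")
  condel <- num_info("CONDEL"); cadd <- num_info("CADD")
  kgp <- num_info("KGP"); evs <- num_info("EVS")

  rows <- list()
  for (i in seq_len(n_var)) {
    zyg <- vapply(gt[i, , drop = TRUE], zyg_of, character(1))
    car_idx <- which(!is.na(zyg))
    if (length(car_idx) == 0L) next
    chrom <- fix$CHROM[i]
    chrom_class <- if (sub("^chr", "", chrom) == "X") "X" else "autosome"
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_ids[car_idx],
      gene = gene[i],
      chrom_class = chrom_class,
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = fix$ALT[i],
      consequence = csq[i],
      variant_class = if (nchar(fix$REF[i]) != nchar(fix$ALT[i])) "indel" else "SNV",
      zygosity = unname(zyg[car_idx]),
      freq_kgp = kgp[i],
      freq_evs = evs[i],
      carriers_internal = if (!is.na(carriers[i])) carriers[i] else length(car_idx),
      polyphen2 = pp2[i], sift = sift[i], condel = condel[i], cadd = cadd[i],
      known_pathogenic = kp[i],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    stop("VCF contains no carrier genotypes", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a variant table in the TSV dialect
#'
#' @param variants variant table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as a minimal VCF 4.2
#'
#' One VCF record per distinct variant (site/allele), with per-sample GT
#' columns over all samples in \code{samples} and annotations in the INFO
#' keys documented in \code{\link{read_variant_table}}.
#'
#' @param variants variant table.
#' @param samples sample table supplying the column order of genotypes.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_vcf <- function(variants, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=CARRIERS,Number=1,Type=Integer,Description=\"Internal carrier count\">",
    "##INFO=<ID=PP2,Number=1,Type=Float,Description=\"PolyPhen2 score\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=CONDEL,Number=1,Type=Float,Description=\"Condel score\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD Phred score\">",
    "##INFO=<ID=KGP,Number=1,Type=Float,Description=\"Reference AF, set kgp\">",
    "##INFO=<ID=EVS,Number=1,Type=Float,Description=\"Reference AF, set evs\">",
    "##INFO=<ID=KP,Number=0,Type=Flag,Description=\"Known pathogenic\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t")
  ), con)
  key <- variant_key(variants)
  for (k in unique(key)) {
    rows <- variants[key == k, , drop = FALSE]
    v <- rows[1L, ]
    chrom <- if (v$chrom_class == "X") "X" else "1"
    info <- c(
      paste0("GENE=", v$gene),
      paste0("CSQCLASS=", v$consequence),
      paste0("CARRIERS=", v$carriers_internal)
    )
    for (spec in list(c("PP2", "polyphen2"), c("SIFT", "sift"),
                      c("CONDEL", "condel"), c("CADD", "cadd"),
                      c("KGP", "freq_kgp"), c("EVS", "freq_evs"))) {
      if (spec[2L] %in% names(v) && !is.na(v[[spec[2L]]])) {
        info <- c(info, paste0(spec[1L], "=", v[[spec[2L]]]))
      }
    }
    if (isTRUE(v$known_pathogenic)) info <- c(info, "KP")
    gts <- rep("0/0", nrow(samples))
    idx <- match(rows$sample_id, samples$sample_id)
    gts[idx] <- c(het = "0/1", hom = "1/1", hemi = "1")[rows$zygosity]
    writeLines(paste(c(chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                       paste(info, collapse = ";"), "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a gene-panel definition table
#'
#' TSV with columns \code{gene, status (known|candidate), chrom_class
#' (autosome|PAR|X), inheritance (monoallelic|biallelic|x_linked),
#' transcript}. Every gene must appear exactly once and X-linked
#' inheritance must coincide with the X chromosome class. Counts by status
#' are reported via \code{message()}.
#'
#' @param path file path.
#' @return panel data.frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  panel <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(panel) == 0L) {
    warning("panel file ", path, " is empty")
    return(panel)
  }
  dup <- unique(panel$gene[duplicated(panel$gene)])
  if (length(dup) > 0L) {
    stop("duplicate gene symbol(s) in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(panel$status %in% c("known", "candidate")),
            all(panel$chrom_class %in% .chrom_classes),
            all(panel$inheritance %in% c("monoallelic", "biallelic", "x_linked")))
  bad <- xor(panel$inheritance == "x_linked", panel$chrom_class == "X")
  if (any(bad)) {
    stop("x_linked inheritance must coincide with chrom_class X: ",
         paste(head(panel$gene[bad], 10L), collapse = ", "), call. = FALSE)
  }
  message(sprintf("[read_panel] genes=%d known=%d candidate=%d",
                  nrow(panel), sum(panel$status == "known"),
                  sum(panel$status == "candidate")))
  panel
}

#' Read a sample metadata table
#'
#' TSV with columns \code{sample_id, sex (male|female), cohort} and
#' optionally \code{qc_pass, variant_count}.
#'
#' @param path file path.
#' @return sample data.frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  samples <- read.delim(path, stringsAsFactors = FALSE)
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(samples$sex %in% c("male", "female")))
  if (!"qc_pass" %in% names(samples)) samples$qc_pass <- TRUE
  if (!"variant_count" %in% names(samples)) samples$variant_count <- NA_integer_
  samples
}

#' Read a known-pathogenic variant lookup
#'
#' Four-column TSV (\code{gene, pos, ref, alt}) listing previously reported
#' disease variants. Membership in this list stands in for a licensed
#' clinical database: the triage only needs the membership bit.
#'
#' @param path file path.
#' @return data.frame with the four key columns.
#' @export
read_known_pathogenic <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  kp <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(gene = "character", ref = "character",
                                  alt = "character"))
  stopifnot(all(c("gene", "pos", "ref", "alt") %in% names(kp)))
  kp
}

#' Apply a known-pathogenic lookup to a variant table
#'
#' Sets \code{known_pathogenic} from membership in the lookup, replacing
#' any prior value.
#'
#' @param variants variant table.
#' @param kp lookup from \code{\link{read_known_pathogenic}}.
#' @return \code{variants} with \code{known_pathogenic} recomputed.
#' @export
apply_known_pathogenic <- function(variants, kp) {
  key <- paste(variants$gene, variants$pos, variants$ref, variants$alt)
  variants$known_pathogenic <- key %in% paste(kp$gene, kp$pos, kp$ref, kp$alt)
  variants
}

#' Write classification and enrichment reports
#'
#' Writes three TSVs into \code{out_dir}: \code{classifications.tsv} (one
#' row per triaged variant with verdict and reason codes),
#' \code{sample_summary.tsv} (per-sample diagnostic summary), and
#' \code{enrichment.tsv} (one row per stratified burden-test cell). Empty
#' inputs produce headers-only files; all numeric cells round-trip when
#' re-read with \code{read.delim}.
#'
#' @param classifications classification table from
#'   \code{\link{triage_cohort}} (possibly empty).
#' @param enrichments enrichment table from \code{\link{stratified_table}}
#'   (possibly empty).
#' @param out_dir output directory, created if needed.
#' @param samples optional sample table for the per-sample summary; when
#'   omitted the summary covers only samples present in
#'   \code{classifications}.
#' @return character vector of the three file paths, invisibly.
#' @export
write_reports <- function(classifications, enrichments, out_dir,
                          samples = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- file.path(out_dir,
                     c("classifications.tsv", "sample_summary.tsv",
                       "enrichment.tsv"))
  write.table(classifications, paths[1L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary_df <- sample_summary(classifications, samples)
  write.table(summary_df, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(enrichments, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# per-sample rollup of triage verdicts
sample_summary <- function(classifications, samples = NULL) {
  ids <- if (!is.null(samples)) samples$sample_id else
    unique(classifications$sample_id)
  lp <- classifications[classifications$verdict == "likely_pathogenic", ,
                        drop = FALSE]
  has_path <- function(p) {
    ids %in% lp$sample_id[lp$pathway == p]
  }
  data.frame(
    sample_id = ids,
    lof_diagnosed = has_path("lof_known_gene"),
    missense_diagnosed = has_path("missense_known_pathogenic"),
    diagnosed = ids %in% lp$sample_id,
    n_likely_pathogenic = as.integer(table(
      factor(lp$sample_id, levels = ids))),
    stringsAsFactors = FALSE
  )
}
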