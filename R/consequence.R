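#' Controlled consequence vocabulary
#'
#' Consequence terms accepted by the pipeline, grouped by the functional
#' class they imply. Loss-of-function (LoF) covers nonsense, frameshift and
#' the two canonical (essential) splice-site classes; extended splice-region
#' terms are deliberately not LoF. "Functional" covers missense, inframe
#' indels and stop loss.
#'
#' @name consequence-vocabulary
#' @keywords internal
NULL

.lof_terms <- c(
  "stop_gained",
  "frameshift_variant",
  "splice_donor_variant",
  "splice_acceptor_variant"
)

.functional_terms <- c(
  "missense_variant",
  "inframe_insertion",
  "inframe_deletion",
  "stop_lost"
)

.synonymous_terms <- "synonymous_variant"

.known_terms <- function(extra_terms = character()) {
  c(.lof_terms, .functional_terms, .synonymous_terms, extra_terms)
}

#' Classify a consequence term into a functional class
#'
#' Deterministically maps controlled-vocabulary consequence terms to one of
#' four classes: \code{"lof"} (stop_gained, frameshift_variant,
#' splice_donor_variant, splice_acceptor_variant), \code{"functional"}
#' (missense_variant, inframe_insertion, inframe_deletion, stop_lost),
#' \code{"synonymous"} (synonymous_variant), or \code{"other"} for terms the
#' caller has explicitly allowed via \code{extra_terms}. Unknown terms are an
#' error, never silently mapped: triage correctness depends on the
#' vocabulary.
#'
#' @param term character vector of consequence terms.
#' @param extra_terms additional terms to accept; they classify as
#'   \code{"other"} and take no part in triage or burden testing.
#' @return character vector, same length as \code{term}, with values in
#'   \code{c("lof", "functional", "synonymous", "other")}.
#' @examples
#' classify_consequence(c("stop_gained", "missense_variant"))
#' @export
classify_consequence <- function(term, extra_terms = character()) {
  stopifnot(is.character(term))
  unknown <- setdiff(unique(term), .known_terms(extra_terms))
  if (length(unknown) > 0L) {
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- rep("other", length(term))
  out[term %in% .lof_terms] <- "lof"
  out[term %in% .functional_terms] <- "functional"
  out[term %in% .synonymous_terms] <- "synonymous"
  out
}

#' Annotate a variant table with its consequence class
#'
#' Adds a \code{consequence_class} column (see
#' \code{\link{classify_consequence}}).
#'
#' @param variants variant table (see \code{\link{read_variant_table}}).
#' @param cfg a \code{\link{filter_config}}; its \code{extra_terms} extend
#'   the accepted vocabulary.
#' @return \code{variants} with a \code{consequence_class} column.
#' @export
annotate_consequence <- function(variants, cfg = filter_config()) {
  variants$consequence_class <-
    classify_consequence(variants$consequence, cfg$extra_terms)
  variants
}
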