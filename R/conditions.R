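#' Typed error conditions
#'
#' All user-facing failures raised by this package are classed conditions so
#' callers (and the command-line tool) can react to the specific failure mode
#' rather than pattern-matching messages. Every class below also inherits from
#' `"seqnr_error"`.
#'
#' @section Condition classes:
#' \describe{
#'   \item{seqnr_malformed_id}{a string that is not a 32-character hex MD5}
#'   \item{seqnr_empty_sequence}{a sequence that is empty after normalization}
#'   \item{seqnr_illegal_character}{a non `A-Z` residue after normalization}
#'   \item{seqnr_malformed_fasta}{structurally invalid FASTA input}
#'   \item{seqnr_malformed_row}{a table row with the wrong column count}
#'   \item{seqnr_bad_taxid}{a taxid cell that is not a positive integer}
#'   \item{seqnr_empty_hierarchy}{a hierarchy row with no level cells}
#'   \item{seqnr_source_empty}{a source bundle with zero usable sequences}
#'   \item{seqnr_mixed_moltype}{merging protein and nucleotide data}
#'   \item{seqnr_duplicate_source}{two bundles sharing a namespace name}
#'   \item{seqnr_residue_mismatch}{one MD5 mapped to two residue strings}
#'   \item{seqnr_unknown_source}{a namespace name absent from the store}
#'   \item{seqnr_empty_store}{refusing to write a store with no sequences}
#'   \item{seqnr_missing_file}{a required store file is absent}
#'   \item{seqnr_integrity_error}{a dump table references an unknown MD5}
#'   \item{seqnr_malformed_sim_line}{an unparseable similarity line}
#'   \item{seqnr_not_best_hit_reduced}{duplicate query ids where one-per-query
#'     input is required}
#'   \item{seqnr_validation_error}{any other violated type invariant}
#' }
#'
#' @name seqnr-conditions
#' @keywords internal
NULL

nrStop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "seqnr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# stopifnot-style guard raising a typed validation error
nrAssert <- function(ok, message, class = "seqnr_validation_error") {
  if (!isTRUE(ok)) nrStop(class, message)
  invisible(TRUE)
}
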