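#' @import methods
#' @import data.table
NULL

# Internal canonical column sets. Annotation facts use `func` internally to
# avoid the reserved word; user-facing tables rename it to `function`.
.annCols <- c("md5", "source", "native_id", "func", "organism", "taxid")
.hierCols <- c("source", "native_id", paste0("level", 1:5))

emptyAnnotations <- function() {
  data.frame(md5 = character(), source = character(),
             native_id = character(), func = character(),
             organism = character(), taxid = integer(),
             stringsAsFactors = FALSE)
}

emptyHierarchies <- function() {
  out <- data.frame(source = character(), native_id = character(),
                    stringsAsFactors = FALSE)
  for (l in paste0("level", 1:5)) out[[l]] <- character()
  out
}

#' SourceSpec: description of one input source bundle
#'
#' A `SourceSpec` names one annotation namespace and points at its input
#' files: a FASTA file of sequences, a 4-column tab-separated annotation
#' table (`native_id`, `function`, `organism`, `taxid`) and, optionally, a
#' functional-hierarchy table (`native_id` followed by 1--5 category levels,
#' most general first).
#'
#' @slot name Namespace name (e.g. `"COG"`); case-sensitive, no tabs or
#'   newlines.
#' @slot moltype `"protein"` or `"nucleotide"`.
#' @slot fastaPath,annotationPath,hierarchyPath File paths;
#'   `annotationPath` and `hierarchyPath` may be `NA` (a source may ship
#'   sequences only).
#' @aliases SourceSpec
#' @exportClass SourceSpec
setClass("SourceSpec", representation(
  name = "character",
  moltype = "character",
  fastaPath = "character",
  annotationPath = "character",
  hierarchyPath = "character"
))

setValidity("SourceSpec", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("name must be a nonempty string")
  if (grepl("[\t\n]", object@name))
    return("name must not contain tab or newline characters")
  if (!object@moltype %in% c("protein", "nucleotide"))
    return("moltype must be 'protein' or 'nucleotide'")
  if (length(object@fastaPath) != 1L || is.na(object@fastaPath))
    return("fastaPath is required")
  TRUE
})

#' @param name,moltype,fastaPath,annotationPath,hierarchyPath See slots.
#' @return A validated `SourceSpec`.
#' @examples
#' \dontrun{
#' spec <- sourceSpec("COG", "protein", "cog.fasta", "cog.tsv", "cog_hier.tsv")
#' }
#' @rdname SourceSpec-class
#' @export
sourceSpec <- function(name, moltype, fastaPath,
                       annotationPath = NA_character_,
                       hierarchyPath = NA_character_) {
  obj <- tryCatch(
    new("SourceSpec", name = as.character(name), moltype = as.character(moltype),
        fastaPath = as.character(fastaPath),
        annotationPath = as.character(annotationPath),
        hierarchyPath = as.character(hierarchyPath)),
    error = function(e) nrStop("seqnr_validation_error", conditionMessage(e)))
  obj
}

#' SourceBundle: one source converted to MD5-keyed form
#'
#' The result of [convertSource()]: sequences deduplicated within the source
#' and keyed by their MD5 fingerprint, annotation facts joined on native id,
#' hierarchy paths, and a record of every input row that was skipped during
#' conversion together with the reason.
#'
#' @slot name Namespace name.
#' @slot moltype `"protein"` or `"nucleotide"`.
#' @slot sequences Named character vector: MD5 id -> normalized residues.
#' @slot annotations data.frame with columns `md5`, `source`, `native_id`,
#'   `func`, `organism`, `taxid`; one row per annotation fact, with `NA` for
#'   absent values (an identity-only record has all three absent).
#' @slot hierarchies data.frame with columns `source`, `native_id`,
#'   `level1`..`level5` (`NA`-padded).
#' @slot skipped data.frame with columns `native_id`, `reason`.
#' @aliases SourceBundle
#' @exportClass SourceBundle
setClass("SourceBundle", representation(
  name = "character",
  moltype = "character",
  sequences = "character",
  annotations = "data.frame",
  hierarchies = "data.frame",
  skipped = "data.frame"
))

setValidity("SourceBundle", function(object) {
  if (!object@moltype %in% c("protein", "nucleotide"))
    return("moltype must be 'protein' or 'nucleotide'")
  md5s <- names(object@sequences)
  if (length(object@sequences) && (is.null(md5s) || !all(isMd5Id(md5s))))
    return("sequences must be named by 32-character hex MD5 ids")
  if (!identical(colnames(object@annotations), .annCols))
    return("annotations must have columns md5, source, native_id, func, organism, taxid")
  if (!identical(colnames(object@hierarchies), .hierCols))
    return("hierarchies must have columns source, native_id, level1..level5")
  if (nrow(object@annotations)) {
    if (!all(object@annotations$md5 %in% md5s))
      return("every annotation md5 must appear in sequences")
    if (!all(object@annotations$source == object@name))
      return("every annotation source must equal the bundle name")
  }
  TRUE
})

#' NrStore: the merged non-redundant database
#'
#' The central container: one normalized sequence per distinct MD5
#' fingerprint, plus the deduplicated union of all annotation facts and
#' hierarchy paths from every merged source. Adding a namespace whose
#' sequences already exist grows the metadata tables only — never the
#' sequence set.
#'
#' @slot moltype `"protein"` or `"nucleotide"` (a store is single-moltype).
#' @slot sequences Named character vector: MD5 id -> normalized residues.
#' @slot annotations Deduplicated data.frame of annotation facts (columns as
#'   in [SourceBundle-class]).
#' @slot hierarchies Deduplicated data.frame of hierarchy paths.
#' @slot sources data.frame with columns `name`, `moltype`, one row per
#'   merged source.
#' @seealso [mergeSources()], [addSource()], [writeStore()], [loadStore()]
#' @aliases NrStore
#' @exportClass NrStore
setClass("NrStore", representation(
  moltype = "character",
  sequences = "character",
  annotations = "data.frame",
  hierarchies = "data.frame",
  sources = "data.frame"
))

setValidity("NrStore", function(object) {
  if (!object@moltype %in% c("protein", "nucleotide"))
    return("moltype must be 'protein' or 'nucleotide'")
  md5s <- names(object@sequences)
  if (length(object@sequences) && (is.null(md5s) || !all(isMd5Id(md5s))))
    return("sequences must be named by 32-character hex MD5 ids")
  if (anyDuplicated(md5s)) return("duplicate MD5 keys in sequences")
  if (!identical(colnames(object@annotations), .annCols))
    return("annotations must have columns md5, source, native_id, func, organism, taxid")
  if (!setequal(unique(object@annotations$md5), md5s))
    return("annotation md5 set must equal the sequence md5 set (every sequence has >= 1 identity row)")
  if (!all(object@annotations$source %in% object@sources$name))
    return("annotation sources must be registered in sources")
  if (anyDuplicated(object@sources$name)) return("duplicate source names")
  TRUE
})

#' @describeIn NrStore-class Number of distinct sequences in the store.
#' @param x An `NrStore`.
#' @export
setMethod("length", "NrStore", function(x) length(x@sequences))

setMethod("show", "SourceSpec", function(object) {
  cat("SourceSpec '", object@name, "' (", object@moltype, ")\n",
      "  fasta:      ", object@fastaPath, "\n",
      "  annotation: ", object@annotationPath, "\n",
      "  hierarchy:  ", object@hierarchyPath, "\n", sep = "")
})

setMethod("show", "SourceBundle", function(object) {
  cat("SourceBundle '", object@name, "' (", object@moltype, ")\n",
      "  ", length(object@sequences), " distinct sequences (md5-keyed)\n",
      "  ", nrow(object@annotations), " annotation rows\n",
      "  ", nrow(object@hierarchies), " hierarchy rows\n",
      "  ", nrow(object@skipped), " skipped records\n", sep = "")
})

setMethod("show", "NrStore", function(object) {
  cat("NrStore (", object@moltype, ")\n",
      "  ", length(object@sequences), " distinct sequences\n",
      "  ", nrow(object@annotations), " annotation rows from ",
      nrow(object@sources), " source(s): ",
      paste(object@sources$name, collapse = ", "), "\n",
      "  ", nrow(object@hierarchies), " hierarchy rows\n", sep = "")
})

#' Accessors for store and bundle contents
#'
#' @param x An [NrStore-class] or [SourceBundle-class].
#' @return `nrSequences()`: named character vector (MD5 -> residues);
#'   `nrAnnotations()`: data.frame of annotation facts with the user-facing
#'   column name `function`; `nrHierarchies()`: data.frame of hierarchy
#'   paths; `nrSources()`: data.frame of registered sources;
#'   `skippedRecords()`: data.frame of records dropped during conversion.
#' @name nr-accessors
NULL

#' @rdname nr-accessors
#' @export
setGeneric("nrSequences", function(x) standardGeneric("nrSequences"))
#' @rdname nr-accessors
#' @export
setGeneric("nrAnnotations", function(x) standardGeneric("nrAnnotations"))
#' @rdname nr-accessors
#' @export
setGeneric("nrHierarchies", function(x) standardGeneric("nrHierarchies"))
#' @rdname nr-accessors
#' @export
setGeneric("nrSources", function(x) standardGeneric("nrSources"))
#' @rdname nr-accessors
#' @export
setGeneric("skippedRecords", function(x) standardGeneric("skippedRecords"))

.userAnn <- function(df) {
  colnames(df)[colnames(df) == "func"] <- "function"
  df
}

#' @rdname nr-accessors
setMethod("nrSequences", "NrStore", function(x) x@sequences)
#' @rdname nr-accessors
setMethod("nrSequences", "SourceBundle", function(x) x@sequences)
#' @rdname nr-accessors
setMethod("nrAnnotations", "NrStore", function(x) .userAnn(x@annotations))
#' @rdname nr-accessors
setMethod("nrAnnotations", "SourceBundle", function(x) .userAnn(x@annotations))
#' @rdname nr-accessors
setMethod("nrHierarchies", "NrStore", function(x) x@hierarchies)
#' @rdname nr-accessors
setMethod("nrHierarchies", "SourceBundle", function(x) x@hierarchies)
#' @rdname nr-accessors
setMethod("nrSources", "NrStore", function(x) x@sources)
#' @rdname nr-accessors
setMethod("skippedRecords", "SourceBundle", function(x) x@skipped)
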