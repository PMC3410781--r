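#' Read FASTA records
#'
#' Reads a FASTA file into raw records: the native id is the header token up
#' to the first whitespace, the description is the remainder, and residues
#' are the concatenated following lines (any line wrapping; blank lines
#' between records are tolerated). Records with empty residue strings are
#' returned as-is — normalization rejects them later.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `native_id`, `description`, `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 desc", "MKL", "VW"), fa)
#' parseFasta(fa)
#' @export
parseFasta <- function(path) {
  if (!file.exists(path))
    nrStop("seqnr_missing_file", sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) nrStop("seqnr_malformed_fasta",
                               sprintf("malformed FASTA '%s': %s", path,
                                       conditionMessage(e))))
  headers <- names(seqs)
  native_id <- sub("[[:space:]].*$", "", headers)
  if (any(!nzchar(native_id)))
    nrStop("seqnr_malformed_fasta",
           sprintf("malformed FASTA '%s': empty header token", path))
  description <- sub("^[^[:space:]]*[[:space:]]*", "", headers)
  data.frame(native_id = native_id, description = description,
             residues = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Split tab-separated lines enforcing an exact column count, with typed
# errors carrying line numbers. `ncol_max < 0` means variable width.
.readTsvLines <- function(path, what) {
  if (!file.exists(path))
    nrStop("seqnr_missing_file", sprintf("%s table not found: %s", what, path))
  readLines(path, warn = FALSE)
}

#' Read a 4-column annotation table
#'
#' The shipped annotation dialect: UTF-8, tab-separated, columns
#' `native_id`, `function`, `organism`, `taxid`; an optional header line is
#' recognized by its first cell being literally `native_id`; an empty cell
#' means the value is absent (`NA`), never the empty string.
#'
#' @param path Path to the table.
#' @return data.frame with columns `native_id`, `func`, `organism`
#'   (character, `NA` where absent) and `taxid` (integer, `NA` where
#'   absent).
#' @export
parseAnnotationTable <- function(path) {
  lines <- .readTsvLines(path, "annotation")
  out <- data.frame(native_id = character(), func = character(),
                    organism = character(), taxid = integer(),
                    stringsAsFactors = FALSE)
  if (!length(lines)) return(out)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (identical(cells[[1L]][1L], "native_id")) start <- 2L
  if (start > length(cells)) return(out)
  rows <- cells[start:length(cells)]
  # strsplit drops trailing empty fields; pad rows that are short only
  # because their last cells are empty in the raw line
  raw <- lines[start:length(lines)]
  ntab <- lengths(regmatches(raw, gregexpr("\t", raw, fixed = TRUE)))
  nfield <- ntab + 1L
  bad <- which(nfield != 4L)
  if (length(bad))
    nrStop("seqnr_malformed_row",
           sprintf("line %d of %s: %d columns, expected 4",
                   bad[1L] + start - 1L, path, nfield[bad[1L]]),
           line = bad[1L] + start - 1L)
  pick <- function(i) vapply(rows, function(r) {
    v <- if (i <= length(r)) r[i] else ""
    if (is.na(v) || !nzchar(v)) NA_character_ else v
  }, character(1))
  native_id <- pick(1L)
  if (anyNA(native_id))
    nrStop("seqnr_malformed_row",
           sprintf("empty native_id in %s (line %d)", path,
                   which(is.na(native_id))[1L] + start - 1L))
  taxraw <- pick(4L)
  taxid <- rep(NA_integer_, length(taxraw))
  has <- !is.na(taxraw)
  if (any(has)) {
    okint <- grepl("^[0-9]+$", taxraw[has])
    val <- suppressWarnings(as.integer(taxraw[has]))
    if (any(!okint | is.na(val) | val <= 0L)) {
      i <- which(has)[which(!okint | is.na(val) | val <= 0L)[1L]]
      nrStop("seqnr_bad_taxid",
             sprintf("line %d of %s: taxid '%s' is not a positive integer",
                     i + start - 1L, path, taxraw[i]))
    }
    taxid[has] <- val
  }
  data.frame(native_id = native_id, func = pick(2L), organism = pick(3L),
             taxid = taxid, stringsAsFactors = FALSE)
}

#' Read a functional-hierarchy table
#'
#' Tab-separated: `native_id` followed by 1--5 category level cells, most
#' general first; trailing empty cells are trimmed. A row whose level cells
#' are all empty raises `seqnr_empty_hierarchy`.
#'
#' @param path Path to the table.
#' @param source Namespace name recorded on each returned row.
#' @return data.frame with columns `source`, `native_id`,
#'   `level1`..`level5` (`NA`-padded).
#' @export
parseHierarchyTable <- function(path, source) {
  lines <- .readTsvLines(path, "hierarchy")
  out <- emptyHierarchies()
  if (!length(lines)) return(out)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (identical(cells[[1L]][1L], "native_id")) start <- 2L
  if (start > length(cells)) return(out)
  rows <- cells[start:length(cells)]
  lv <- matrix(NA_character_, nrow = length(rows), ncol = 5L)
  native_id <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    lineno <- i + start - 1L
    if (length(r) < 1L || !nzchar(r[1L]))
      nrStop("seqnr_malformed_row",
             sprintf("line %d of %s: missing native_id", lineno, path))
    native_id[i] <- r[1L]
    levels <- r[-1L]
    # trim trailing empties, then require the rest nonempty
    while (length(levels) && !nzchar(levels[length(levels)]))
      levels <- levels[-length(levels)]
    if (!length(levels))
      nrStop("seqnr_empty_hierarchy",
             sprintf("line %d of %s: no hierarchy levels", lineno, path))
    if (any(!nzchar(levels)))
      nrStop("seqnr_malformed_row",
             sprintf("line %d of %s: empty internal level cell", lineno, path))
    if (length(levels) > 5L)
      nrStop("seqnr_malformed_row",
             sprintf("line %d of %s: %d levels, maximum is 5", lineno, path,
                     length(levels)))
    lv[i, seq_along(levels)] <- levels
  }
  out <- data.frame(source = rep(source, length(rows)), native_id = native_id,
                    stringsAsFactors = FALSE)
  for (j in 1:5) out[[paste0("level", j)]] <- lv[, j]
  out
}

#' Convert one source bundle to MD5-keyed form
#'
#' The conversion step of the build pipeline: every FASTA record is
#' normalized and fingerprinted; records sharing a residue string collapse
#' onto one MD5 entry; annotation rows are joined on native id. A FASTA
#' record with no annotation row still enters the bundle as an identity-only
#' record (presence in a source is itself metadata). Dirty input is skipped,
#' not fatal: sequences failing normalization, duplicate native ids (first
#' occurrence wins) and annotation rows whose native id has no surviving
#' FASTA record (`"orphan_annotation"`) all land in the `skipped` slot with
#' their reason.
#'
#' @param spec A [SourceSpec-class].
#' @return A [SourceBundle-class]; raises `seqnr_source_empty` if no
#'   sequence survives conversion.
#' @export
convertSource <- function(spec) {
  nrAssert(is(spec, "SourceSpec"), "spec must be a SourceSpec")
  fa <- parseFasta(spec@fastaPath)
  skipped <- data.frame(native_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  dup <- duplicated(fa$native_id)
  if (any(dup)) {
    skipped <- rbind(skipped, data.frame(native_id = fa$native_id[dup],
                                         reason = "duplicate_native_id",
                                         stringsAsFactors = FALSE))
    fa <- fa[!dup, , drop = FALSE]
  }
  norm <- normalizeSequences(fa$residues, spec@moltype)
  bad <- is.na(norm$residues)
  if (any(bad)) {
    skipped <- rbind(skipped, data.frame(native_id = fa$native_id[bad],
                                         reason = norm$reason[bad],
                                         stringsAsFactors = FALSE))
  }
  keep <- fa$native_id[!bad]
  res <- norm$residues[!bad]
  if (!length(keep))
    nrStop("seqnr_source_empty",
           sprintf("source '%s': no sequences survive conversion", spec@name))
  md5 <- computeMd5Id(res)
  # within-source collision guard (same md5, different residues)
  firstRes <- res[!duplicated(md5)]
  names(firstRes) <- md5[!duplicated(md5)]
  if (any(firstRes[md5] != res))
    nrStop("seqnr_residue_mismatch",
           sprintf("source '%s': one MD5 maps to two residue strings", spec@name))
  sequences <- firstRes

  idmap <- data.frame(native_id = keep, md5 = md5, stringsAsFactors = FALSE)
  ann <- if (!is.na(spec@annotationPath)) parseAnnotationTable(spec@annotationPath)
         else data.frame(native_id = character(), func = character(),
                         organism = character(), taxid = integer(),
                         stringsAsFactors = FALSE)
  orphan <- !(ann$native_id %in% idmap$native_id)
  if (any(orphan)) {
    skipped <- rbind(skipped, data.frame(native_id = ann$native_id[orphan],
                                         reason = "orphan_annotation",
                                         stringsAsFactors = FALSE))
    ann <- ann[!orphan, , drop = FALSE]
  }
  annotated <- merge(idmap, ann, by = "native_id")
  bare <- idmap[!(idmap$native_id %in% ann$native_id), , drop = FALSE]
  if (nrow(bare)) {
    bare$func <- NA_character_; bare$organism <- NA_character_
    bare$taxid <- NA_integer_
    annotated <- rbind(annotated, bare)
  }
  annotations <- data.frame(md5 = annotated$md5,
                            source = rep(spec@name, nrow(annotated)),
                            native_id = annotated$native_id,
                            func = annotated$func,
                            organism = annotated$organism,
                            taxid = annotated$taxid,
                            stringsAsFactors = FALSE)
  annotations <- canonicalOrder(unique(annotations))

  hier <- if (!is.na(spec@hierarchyPath))
    unique(parseHierarchyTable(spec@hierarchyPath, spec@name))
  else emptyHierarchies()
  hier <- canonicalOrder(hier)

  new("SourceBundle", name = spec@name, moltype = spec@moltype,
      sequences = sequences, annotations = annotations,
      hierarchies = hier, skipped = skipped)
}
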