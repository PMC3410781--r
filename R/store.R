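# Canonical row order: lexicographic on all columns, C locale (data.table
# radix), NA last. Every table the package writes or returns goes through
# this, so identical content is always byte-identical on disk.
canonicalOrder <- function(df) {
  if (!nrow(df)) return(df)
  dt <- as.data.table(df)
  setorderv(dt, colnames(dt), na.last = TRUE)
  setDF(dt)
  rownames(dt) <- NULL
  dt
}

.STORE_FILES <- c(fasta = "nr.fasta", id = "md52id.tsv", func = "md52func.tsv",
                  org = "md52org.tsv", hier = "hierarchy.tsv",
                  src = "sources.tsv", manifest = "manifest.tsv")

#' Merge converted source bundles into a non-redundant store
#'
#' The merge step of the build pipeline: sequence maps are unioned by MD5
#' key (residues are identical by construction — a mismatch means an MD5
#' collision or a normalization bug and is fatal), and annotation and
#' hierarchy tables become deduplicated unions. Merging a source whose
#' sequences all exist already grows only the metadata tables; this is what
#' makes the store scale with the number of namespaces, not the number of
#' copies of each protein.
#'
#' @param bundles List of [SourceBundle-class] objects with distinct names
#'   and a common moltype.
#' @return An [NrStore-class].
#' @seealso [addSource()] for incremental growth, [convertSource()]
#' @export
mergeSources <- function(bundles) {
  nrAssert(is.list(bundles) && length(bundles) >= 1L &&
             all(vapply(bundles, is, logical(1), "SourceBundle")),
           "bundles must be a nonempty list of SourceBundle objects")
  nms <- vapply(bundles, function(b) b@name, character(1))
  if (anyDuplicated(nms))
    nrStop("seqnr_duplicate_source",
           sprintf("duplicate source name '%s'", nms[duplicated(nms)][1L]))
  mts <- unique(vapply(bundles, function(b) b@moltype, character(1)))
  if (length(mts) != 1L)
    nrStop("seqnr_mixed_moltype",
           sprintf("bundles mix moltypes: %s", paste(mts, collapse = ", ")))
  allseq <- unlist(lapply(bundles, function(b) b@sequences))
  first <- allseq[!duplicated(names(allseq))]
  clash <- first[names(allseq)] != allseq
  if (any(clash))
    nrStop("seqnr_residue_mismatch",
           sprintf("MD5 '%s' maps to two different residue strings",
                   names(allseq)[clash][1L]))
  ann <- canonicalOrder(unique(rbindlist(lapply(bundles, function(b) b@annotations))))
  hier <- canonicalOrder(unique(rbindlist(lapply(bundles, function(b) b@hierarchies))))
  sources <- data.frame(name = nms, moltype = mts, stringsAsFactors = FALSE)
  new("NrStore", moltype = mts, sequences = first,
      annotations = ann, hierarchies = hier,
      sources = canonicalOrder(sources))
}

#' Add one source to an existing store
#'
#' Equivalent to re-merging all bundles with the new one appended, but
#' incremental: existing sequence entries are never rewritten.
#'
#' @param store An [NrStore-class].
#' @param bundle A [SourceBundle-class] whose name is not yet in the store.
#' @return The grown [NrStore-class].
#' @export
addSource <- function(store, bundle) {
  nrAssert(is(store, "NrStore"), "store must be an NrStore")
  nrAssert(is(bundle, "SourceBundle"), "bundle must be a SourceBundle")
  if (bundle@name %in% store@sources$name)
    nrStop("seqnr_duplicate_source",
           sprintf("source '%s' already merged", bundle@name))
  if (bundle@moltype != store@moltype)
    nrStop("seqnr_mixed_moltype",
           sprintf("store is %s, bundle '%s' is %s", store@moltype,
                   bundle@name, bundle@moltype))
  shared <- intersect(names(store@sequences), names(bundle@sequences))
  if (length(shared) && any(store@sequences[shared] != bundle@sequences[shared]))
    nrStop("seqnr_residue_mismatch",
           "MD5 maps to two different residue strings across store and bundle")
  newmd5 <- setdiff(names(bundle@sequences), names(store@sequences))
  seqs <- c(store@sequences, bundle@sequences[newmd5])
  ann <- canonicalOrder(unique(rbindlist(list(store@annotations, bundle@annotations))))
  hier <- canonicalOrder(unique(rbindlist(list(store@hierarchies, bundle@hierarchies))))
  sources <- canonicalOrder(rbind(store@sources,
                                  data.frame(name = bundle@name,
                                             moltype = bundle@moltype,
                                             stringsAsFactors = FALSE)))
  new("NrStore", moltype = store@moltype, sequences = seqs,
      annotations = ann, hierarchies = hier, sources = sources)
}

#' Write the non-redundant FASTA
#'
#' One record per distinct MD5; the header is `>` plus the 32-character
#' fingerprint and nothing else (reduced headers are what keep the file
#' compact); records sorted lexicographically by MD5; residues wrapped at 80
#' columns, LF line endings.
#'
#' @param store An [NrStore-class] with at least one sequence.
#' @param path Output path.
#' @return Number of records written (invisibly).
#' @export
writeNrFasta <- function(store, path) {
  nrAssert(is(store, "NrStore"), "store must be an NrStore")
  if (!length(store@sequences))
    nrStop("seqnr_empty_store", "refusing to write a store with no sequences")
  md5s <- sort(names(store@sequences), method = "radix")
  x <- Biostrings::BStringSet(store@sequences[md5s])
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(length(x))
}

.assertClean <- function(df, file) {
  for (cn in colnames(df)) {
    v <- df[[cn]]
    if (is.character(v) && any(grepl("[\t\n]", v[!is.na(v)])))
      nrStop("seqnr_validation_error",
             sprintf("literal tab/newline in column '%s' of %s", cn, file))
  }
  invisible(df)
}

.writeDump <- function(df, path) {
  .assertClean(df, basename(path))
  dt <- as.data.table(df)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE, na = "",
         eol = "\n")
  nrow(dt)
}

#' Dump the metadata tables
#'
#' Writes the portable tabular form of the store into `directory`:
#' `md52id.tsv` (md5, source, native_id), `md52func.tsv` (md5, source,
#' function), `md52org.tsv` (md5, source, organism, taxid), `hierarchy.tsv`
#' (source, native_id, level1..level5), `sources.tsv` (name, moltype) and a
#' `manifest.tsv` listing (filename, row_count, md5-of-file). Rows are
#' deduplicated and sorted lexicographically on all columns, so two stores
#' built from the same inputs dump byte-identically regardless of merge
#' order. Records with an absent function or organism contribute no row to
#' the corresponding table — absent is never written as an empty string.
#'
#' @param store An [NrStore-class].
#' @param directory Output directory (created if needed).
#' @return The manifest as a data.frame (filename, row_count, md5).
#' @seealso [writeStore()] for FASTA + tables in one call, [loadStore()]
#' @export
dumpTables <- function(store, directory) {
  nrAssert(is(store, "NrStore"), "store must be an NrStore")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ann <- store@annotations
  tabs <- list()
  tabs[[.STORE_FILES["id"]]] <-
    canonicalOrder(unique(ann[, c("md5", "source", "native_id")]))
  tabs[[.STORE_FILES["func"]]] <-
    canonicalOrder(unique(ann[!is.na(ann$func), c("md5", "source", "func")]))
  tabs[[.STORE_FILES["org"]]] <-
    canonicalOrder(unique(ann[!is.na(ann$organism),
                              c("md5", "source", "organism", "taxid")]))
  tabs[[.STORE_FILES["hier"]]] <- canonicalOrder(unique(store@hierarchies))
  tabs[[.STORE_FILES["src"]]] <- canonicalOrder(store@sources)
  counts <- integer(0)
  for (fn in names(tabs))
    counts[fn] <- .writeDump(tabs[[fn]], file.path(directory, fn))
  files <- names(tabs)
  fapath <- file.path(directory, .STORE_FILES["fasta"])
  if (file.exists(fapath)) {
    files <- c(.STORE_FILES[["fasta"]], files)
    counts[.STORE_FILES[["fasta"]]] <- length(store@sequences)
  }
  manifest <- data.frame(
    filename = files,
    row_count = as.integer(counts[files]),
    md5 = unname(tools::md5sum(file.path(directory, files))),
    stringsAsFactors = FALSE)
  manifest <- canonicalOrder(manifest)
  .writeDump(manifest, file.path(directory, .STORE_FILES["manifest"]))
  manifest
}

#' Write a complete store directory
#'
#' Convenience wrapper: [writeNrFasta()] to `nr.fasta` plus [dumpTables()],
#' giving a directory that [loadStore()] round-trips.
#'
#' @inheritParams dumpTables
#' @return The manifest data.frame (invisibly).
#' @export
writeStore <- function(store, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  writeNrFasta(store, file.path(directory, .STORE_FILES["fasta"]))
  invisible(dumpTables(store, directory))
}

# read a headerless dump written by .writeDump; empty cells -> NA
.readDump <- function(path, cols) {
  if (!file.exists(path))
    nrStop("seqnr_missing_file", sprintf("missing store file: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- as.data.frame(matrix(NA_character_, nrow = length(lines),
                              ncol = length(cols),
                              dimnames = list(NULL, cols)),
                       stringsAsFactors = FALSE)
  if (!length(lines)) return(out)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  for (j in seq_along(cols)) {
    v <- vapply(cells, function(r) if (j <= length(r)) r[j] else "",
                character(1))
    v[!nzchar(v)] <- NA_character_
    out[[j]] <- v
  }
  out
}

#' Load a store directory
#'
#' Reads a directory produced by [writeStore()] back into an
#' [NrStore-class], verifying integrity: every MD5 referenced by a table
#' must be present in the FASTA, and every FASTA record's fingerprint must
#' equal its own header (so a corrupted table or sequence file is detected,
#' never silently loaded). The round trip `loadStore(writeStore(S))` dumps
#' byte-identically to `S`.
#'
#' @param directory A store directory.
#' @return An [NrStore-class].
#' @export
loadStore <- function(directory) {
  need <- .STORE_FILES[c("fasta", "id", "func", "org", "hier", "src")]
  for (fn in need)
    if (!file.exists(file.path(directory, fn)))
      nrStop("seqnr_missing_file",
             sprintf("missing store file: %s", file.path(directory, fn)))
  fa <- Biostrings::readBStringSet(file.path(directory, .STORE_FILES["fasta"]))
  seqs <- as.character(fa)
  if (length(seqs) && !all(isMd5Id(names(seqs))))
    nrStop("seqnr_integrity_error", "FASTA headers are not MD5 identifiers")
  recomputed <- computeMd5Id(unname(seqs))
  off <- recomputed != names(seqs)
  if (any(off))
    nrStop("seqnr_integrity_error",
           sprintf("FASTA record '%s' does not hash to its own header",
                   names(seqs)[off][1L]))

  src <- .readDump(file.path(directory, .STORE_FILES["src"]),
                   c("name", "moltype"))
  if (!nrow(src) || !all(src$moltype %in% c("protein", "nucleotide")) ||
      length(unique(src$moltype)) != 1L)
    nrStop("seqnr_integrity_error", "sources.tsv is empty or inconsistent")
  ids <- .readDump(file.path(directory, .STORE_FILES["id"]),
                   c("md5", "source", "native_id"))
  funcs <- .readDump(file.path(directory, .STORE_FILES["func"]),
                     c("md5", "source", "func"))
  orgs <- .readDump(file.path(directory, .STORE_FILES["org"]),
                    c("md5", "source", "organism", "taxid"))
  hier <- .readDump(file.path(directory, .STORE_FILES["hier"]), .hierCols)

  for (tb in list(ids, funcs, orgs)) {
    if (nrow(tb)) {
      unknown <- setdiff(unique(tb$md5), names(seqs))
      if (length(unknown))
        nrStop("seqnr_integrity_error",
               sprintf("table references MD5 '%s' absent from the FASTA",
                       unknown[1L]))
    }
  }
  if (length(setdiff(names(seqs), ids$md5)))
    nrStop("seqnr_integrity_error",
           "FASTA contains sequences with no identifier row")

  # Reconstruct annotation facts from the projected tables: ids left-joined
  # with per-(md5, source) functions and organisms. When a group carries
  # several ids and several functions this widens to the cross product; the
  # canonical dumps are unaffected (the dump re-projects).
  idDT <- as.data.table(ids)
  funcDT <- as.data.table(funcs)
  orgDT <- as.data.table(orgs)
  orgDT[, taxid := suppressWarnings(as.integer(taxid))]
  ann <- merge(idDT, funcDT, by = c("md5", "source"), all.x = TRUE,
               allow.cartesian = TRUE)
  ann <- merge(ann, orgDT, by = c("md5", "source"), all.x = TRUE,
               allow.cartesian = TRUE)
  if (!"taxid" %in% names(ann)) ann[, taxid := NA_integer_]
  ann <- unique(ann[, .annCols, with = FALSE])
  setDF(ann)
  new("NrStore", moltype = src$moltype[1L], sequences = seqs,
      annotations = canonicalOrder(ann),
      hierarchies = canonicalOrder(unique(hier)),
      sources = canonicalOrder(src))
}

#' Per-source uniqueness statistics
#'
#' For each merged source, counts its distinct native identifiers,
#' sequences (MD5s), function strings and organism strings, and the number
#' of each that occur in no other source ("unique added" — the measure of
#' what a namespace actually contributes beyond the rest of the collection).
#' String matching is exact and case-sensitive: the counts are of unique
#' representations, not of fuzzily merged labels. `percent_X` is
#' `unique_added_X / global distinct total of X`, reported to one decimal.
#'
#' @param store An [NrStore-class].
#' @return A `StoreStats` list with elements `per_source` (data.frame) and
#'   `totals` (named integer vector of global distinct counts).
#' @export
computeStatistics <- function(store) {
  nrAssert(is(store, "NrStore"), "store must be an NrStore")
  ann <- as.data.table(store@annotations)
  kinds <- list(ids = "native_id", sequences = "md5", functions = "func",
                organisms = "organism")
  srcs <- sort(store@sources$name, method = "radix")
  per <- data.frame(source = srcs, stringsAsFactors = FALSE)
  totals <- integer(0)
  for (k in names(kinds)) {
    col <- kinds[[k]]
    u <- unique(ann[!is.na(get(col)), .(source, value = get(col))])
    nsrc <- u[, .(nsource = .N), by = value]
    uniq <- merge(u, nsrc, by = "value")[nsource == 1L]
    percount <- u[, .N, by = source]
    uniqcount <- uniq[, .N, by = source]
    per[[paste0("n_", k)]] <-
      ifelse(is.na(m <- percount$N[match(srcs, percount$source)]), 0L, m)
    per[[paste0("unique_added_", k)]] <-
      ifelse(is.na(m <- uniqcount$N[match(srcs, uniqcount$source)]), 0L, m)
    totals[[paste0("total_", k)]] <- nrow(nsrc)
  }
  for (k in names(kinds)) {
    tot <- totals[[paste0("total_", k)]]
    per[[paste0("percent_", k)]] <-
      if (tot > 0) round(100 * per[[paste0("unique_added_", k)]] / tot, 1)
      else NA_real_
  }
  structure(list(per_source = per, totals = totals), class = "StoreStats")
}

#' @export
print.StoreStats <- function(x, ...) {
  cat("Store statistics (", length(x$per_source$source), " sources)\n",
      sep = "")
  cat("Global distinct totals:\n")
  print(x$totals)
  cat("Per source (n_X = distinct in source; unique_added_X = in no other source):\n")
  print(x$per_source, row.names = FALSE)
  invisible(x)
}
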