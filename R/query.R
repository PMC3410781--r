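.checkSource <- function(store, source) {
  nrAssert(is(store, "NrStore"), "store must be an NrStore")
  nrAssert(is.character(source) && length(source) == 1L && !is.na(source),
           "source must be a single namespace name")
  if (!source %in% store@sources$name)
    nrStop("seqnr_unknown_source",
           sprintf("unknown source '%s'; loaded sources: %s", source,
                   paste(sort(store@sources$name), collapse = ", ")))
  invisible(source)
}

#' Resolve MD5 identifiers to native identifiers
#'
#' Returns every (md5, source, native_id) fact for the given fingerprints,
#' optionally restricted to one namespace. Fingerprints absent from the
#' store contribute zero rows — in a batch pipeline absence is data, not an
#' error; only an unknown namespace name (always a caller bug) raises.
#'
#' @param store An [NrStore-class].
#' @param md5s Character vector of MD5 identifiers (any case; canonicalized).
#' @param source Optional namespace name.
#' @return data.frame (md5, source, native_id), canonically sorted.
#' @export
md52ids <- function(store, md5s, source = NULL) {
  nrAssert(is.character(md5s) && length(md5s) >= 1L, "md5s must be nonempty")
  md5s <- unique(validateMd5Id(md5s))
  qsrc <- source
  if (!is.null(qsrc)) .checkSource(store, qsrc)
  ann <- as.data.table(store@annotations)
  out <- ann[md5 %in% md5s, .(md5, source, native_id)]
  if (!is.null(qsrc)) out <- out[source == qsrc]
  canonicalOrder(unique(setDF(out)))
}

#' Overview of one MD5 in one namespace
#'
#' The single-identifier lookup of the command-line tool: all (native id,
#' function, organism) facts a namespace attaches to a fingerprint.
#'
#' @param store An [NrStore-class].
#' @param md5 One MD5 identifier (any case).
#' @param source Namespace name.
#' @return data.frame (md5, native_id, `function`, organism), deduplicated
#'   and sorted; zero rows if the namespace does not know the sequence.
#' @export
md52overview <- function(store, md5, source) {
  nrAssert(is.character(md5) && length(md5) == 1L, "md5 must be a single id")
  qmd5 <- validateMd5Id(md5)
  qsrc <- .checkSource(store, source)
  ann <- as.data.table(store@annotations)
  out <- ann[md5 == qmd5 & source == qsrc,
             .(md5, native_id, func, organism)]
  .userAnn(canonicalOrder(unique(setDF(out))))
}

#' Batch annotation lookup in one namespace
#'
#' The bulk form of [md52overview()]: one call resolves any number of
#' fingerprints (hundreds of thousands at a time) against one namespace.
#'
#' @param store An [NrStore-class].
#' @param md5s Character vector of MD5 identifiers.
#' @param source Namespace name.
#' @return Named list keyed by md5 — exactly the input fingerprints with at
#'   least one fact — each element a data.frame (native_id, `function`,
#'   organism).
#' @export
md5s2sets4source <- function(store, md5s, source) {
  qsrc <- .checkSource(store, source)
  if (!length(md5s)) return(structure(list(), names = character()))
  md5s <- unique(validateMd5Id(md5s))
  ann <- as.data.table(store@annotations)
  hit <- ann[source == qsrc & md5 %in% md5s,
             .(md5, native_id, func, organism)]
  hit <- unique(hit)
  setorderv(hit, c("md5", "native_id", "func", "organism"), na.last = TRUE)
  parts <- split(hit, by = "md5", keep.by = FALSE, sorted = TRUE)
  lapply(parts, function(d) .userAnn(setDF(d)))
}

#' Resolve a native identifier to its MD5 fingerprint(s)
#'
#' Normally one fingerprint; more are possible when a source reuses one
#' identifier for variant sequences. An unknown identifier yields an empty
#' vector.
#'
#' @param store An [NrStore-class].
#' @param native_id One source-native identifier.
#' @param source Namespace name.
#' @return Sorted character vector of MD5 identifiers.
#' @export
id2md5 <- function(store, native_id, source) {
  nrAssert(is.character(native_id) && length(native_id) == 1L,
           "native_id must be a single string")
  .checkSource(store, source)
  ann <- store@annotations
  sort(unique(ann$md5[ann$source == source & ann$native_id == native_id]),
       method = "radix")
}

#' Translate identifiers between namespaces through sequence identity
#'
#' The core translation operation: a `from`-namespace identifier maps to a
#' `to`-namespace identifier exactly when both annotate the same sequence
#' (the same MD5). Translation never uses function-string similarity — only
#' identity of the underlying residue string. Identifiers with no path
#' still appear, with an absent `to_id`, so batch accounting is lossless.
#'
#' @param store An [NrStore-class].
#' @param native_ids Character vector of `from_source` identifiers.
#' @param from_source,to_source Namespace names.
#' @return data.frame (from_id, md5, to_id, to_function), sorted; one row
#'   per (from_id, md5, to_id) path, plus one `NA` row per unresolvable
#'   from_id.
#' @export
translateIds <- function(store, native_ids, from_source, to_source) {
  nrAssert(is.character(native_ids) && length(native_ids) >= 1L,
           "native_ids must be nonempty")
  qfrom <- .checkSource(store, from_source)
  qto <- .checkSource(store, to_source)
  native_ids <- unique(native_ids)
  ann <- as.data.table(store@annotations)
  fromDT <- unique(ann[source == qfrom & native_id %in% native_ids,
                       .(from_id = native_id, md5)])
  toDT <- unique(ann[source == qto,
                     .(md5, to_id = native_id, to_function = func)])
  hit <- merge(fromDT, toDT, by = "md5", allow.cartesian = TRUE)
  hit <- hit[, .(from_id, md5, to_id, to_function)]
  unresolved <- setdiff(native_ids, hit$from_id)
  if (length(unresolved)) {
    # keep the md5 when the from-id resolves but the target namespace
    # lacks the sequence; NA md5 when the from-id itself is unknown
    resmd5 <- fromDT[from_id %in% unresolved]
    miss <- data.table(from_id = unresolved,
                       md5 = resmd5$md5[match(unresolved, resmd5$from_id)],
                       to_id = NA_character_, to_function = NA_character_)
    hit <- rbindlist(list(hit, miss))
  }
  canonicalOrder(unique(setDF(hit)))
}

#' Hierarchy paths of a native identifier
#'
#' Functional hierarchies (COG categories, subsystem trees, pathway
#' hierarchies) attach to the namespace identifier, not to the sequence; a
#' fingerprint reaches them through its identifier rows.
#'
#' @param store An [NrStore-class].
#' @param native_id One identifier.
#' @param source Namespace name.
#' @return List of character vectors (each a path, most general level
#'   first), sorted; empty list if none registered.
#' @export
id2hierarchy <- function(store, native_id, source) {
  nrAssert(is.character(native_id) && length(native_id) == 1L,
           "native_id must be a single string")
  .checkSource(store, source)
  h <- store@hierarchies
  h <- h[h$source == source & h$native_id == native_id, , drop = FALSE]
  if (!nrow(h)) return(list())
  paths <- lapply(seq_len(nrow(h)), function(i) {
    lv <- unlist(h[i, paste0("level", 1:5)], use.names = FALSE)
    lv[!is.na(lv)]
  })
  key <- vapply(paths, paste, character(1), collapse = "\t")
  paths[order(key, method = "radix")]
}
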