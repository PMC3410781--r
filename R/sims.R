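.M8_COLS <- c("query_id", "subject_md5", "pct_identity", "aln_length",
              "mismatches", "gap_openings", "q_start", "q_end", "s_start",
              "s_end", "e_value", "bit_score")

#' Parse 12-column tabular similarity results
#'
#' Reads BLAST/BLAT tabular output (the classic `-m 8` / `outfmt 6` layout:
#' query, subject, %identity, alignment length, mismatches, gap openings,
#' query start/end, subject start/end, e-value, bit score) whose subject
#' field is an MD5 fingerprint — the result of searching against the
#' non-redundant FASTA. Comment lines starting `#` are skipped. Coordinates
#' are carried verbatim (1-based inclusive, aligner convention) — this
#' module joins annotations onto hits, it never edits alignments.
#'
#' @param path Path to the tabular file.
#' @return data.frame of hits with columns
#'   `query_id, subject_md5, pct_identity, aln_length, mismatches,
#'   gap_openings, q_start, q_end, s_start, s_end, e_value, bit_score`,
#'   in input order.
#' @export
parseM8 <- function(path) {
  if (!file.exists(path))
    nrStop("seqnr_missing_file", sprintf("similarity file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  empty <- data.frame(query_id = character(), subject_md5 = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      mismatches = integer(), gap_openings = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      e_value = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  cells <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(cells)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    nrStop("seqnr_malformed_sim_line",
           sprintf("line %d of %s: %d fields, expected 12", keep[i], path,
                   nf[i]),
           line = keep[i])
  }
  m <- matrix(unlist(cells), ncol = 12L, byrow = TRUE)
  if (!all(isMd5Id(m[, 2L]))) {
    i <- which(!isMd5Id(m[, 2L]))[1L]
    nrStop("seqnr_malformed_id",
           sprintf("line %d of %s: subject '%s' is not an MD5 identifier",
                   keep[i], path, m[i, 2L]))
  }
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  int <- function(j) suppressWarnings(as.integer(m[, j]))
  hits <- data.frame(query_id = m[, 1L], subject_md5 = tolower(m[, 2L]),
                     pct_identity = num(3L), aln_length = int(4L),
                     mismatches = int(5L), gap_openings = int(6L),
                     q_start = int(7L), q_end = int(8L), s_start = int(9L),
                     s_end = int(10L), e_value = num(11L),
                     bit_score = num(12L), stringsAsFactors = FALSE)
  numbad <- !stats::complete.cases(hits) |
    hits$pct_identity < 0 | hits$pct_identity > 100 |
    hits$aln_length < 1L | hits$mismatches < 0L | hits$gap_openings < 0L |
    hits$q_start < 1L | hits$q_end < 1L | hits$s_start < 1L |
    hits$s_end < 1L | hits$e_value < 0
  if (any(numbad)) {
    i <- which(numbad)[1L]
    nrStop("seqnr_malformed_sim_line",
           sprintf("line %d of %s: invalid numeric field", keep[i], path),
           line = keep[i])
  }
  hits
}

#' Filter similarity hits by quality thresholds
#'
#' The defaults pass everything: no cutoffs are built in, so any filtering a
#' profile is based on is an explicit, reportable choice.
#'
#' @param hits data.frame from [parseM8()].
#' @param max_evalue Keep hits with `e_value <= max_evalue` (default `Inf`).
#' @param min_identity Keep hits with `pct_identity >= min_identity`
#'   (percent, default 0).
#' @param min_length Keep hits with `aln_length >= min_length` (default 0).
#' @return Filtered hits, input order preserved.
#' @export
filterHits <- function(hits, max_evalue = Inf, min_identity = 0,
                       min_length = 0) {
  nrAssert(max_evalue >= 0 && min_identity >= 0 && min_length >= 0,
           "thresholds must be nonnegative")
  keep <- hits$e_value <= max_evalue & hits$pct_identity >= min_identity &
    hits$aln_length >= min_length
  hits[keep, , drop = FALSE]
}

#' Reduce hits to the best hit per query
#'
#' Keeps one hit per query id: maximal bit score, ties broken by minimal
#' e-value, then by lexicographically smallest subject MD5. The rule is
#' total, so the result is deterministic and invariant to input order.
#'
#' @param hits data.frame from [parseM8()].
#' @return One row per query id, sorted by query id.
#' @export
bestHitPerQuery <- function(hits) {
  if (!nrow(hits)) return(hits)
  dt <- as.data.table(hits)
  setorderv(dt, c("query_id", "bit_score", "e_value", "subject_md5"),
            order = c(1L, -1L, 1L, 1L))
  best <- dt[!duplicated(query_id)]
  setDF(best)
  best
}

#' Annotate similarity hits in one namespace
#'
#' Joins each hit's subject fingerprint against the store: the output has
#' exactly one row per input hit, in input order, with the set of
#' annotation facts the chosen namespace holds for that sequence attached
#' as a list-column. A hit whose subject the namespace does not know (or
#' that is absent from the store entirely) is retained with an empty
#' annotation set — hits are never dropped, so read accounting downstream
#' stays exact.
#'
#' @param store An [NrStore-class].
#' @param hits data.frame from [parseM8()].
#' @param source Namespace name.
#' @return data.frame: the hit columns plus `source`, `n_annotations` and a
#'   list-column `annotations` (each element a data.frame with
#'   `native_id`, `function`, `organism`).
#' @seealso [flattenAnnotatedHits()] for the flat TSV-ready form.
#' @export
annotateSims <- function(store, hits, source) {
  qsrc <- .checkSource(store, source)
  sets <- if (nrow(hits))
    md5s2sets4source(store, unique(hits$subject_md5), qsrc)
  else list()
  emptyset <- data.frame(native_id = character(), stringsAsFactors = FALSE)
  emptyset[["function"]] <- character(); emptyset$organism <- character()
  ann <- lapply(hits$subject_md5, function(m) {
    s <- sets[[m]]
    if (is.null(s)) emptyset else s
  })
  out <- hits
  out$source <- rep(qsrc, nrow(hits))
  out$n_annotations <- vapply(ann, nrow, integer(1))
  out$annotations <- ann
  out
}

#' Flatten annotated hits for tabular output
#'
#' Expands the annotation list-column: one row per (hit, annotation fact),
#' or a single row with absent fields for an unannotated hit.
#'
#' @param annotated Output of [annotateSims()].
#' @return data.frame with the 12 hit columns plus `source`, `native_id`,
#'   `function`, `organism`.
#' @export
flattenAnnotatedHits <- function(annotated) {
  rows <- lapply(seq_len(nrow(annotated)), function(i) {
    h <- annotated[i, c(.M8_COLS, "source"), drop = FALSE]
    a <- annotated$annotations[[i]]
    if (!nrow(a)) {
      a <- data.frame(native_id = NA_character_, stringsAsFactors = FALSE)
      a[["function"]] <- NA_character_; a$organism <- NA_character_
    }
    cbind(h[rep(1L, nrow(a)), , drop = FALSE], a, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize best hits into hierarchy categories
#'
#' Maps a best-hit-reduced set of annotated reads onto one level of a
#' namespace's functional hierarchy — e.g. read abundance per COG functional
#' category or per subsystem. Abundance counts distinct queries (reads),
#' not hits: each query counts once in every distinct category it reaches
#' through its hit's annotations, so a query whose identifier sits in two
#' categories adds one to each (the multi-membership total is reported so
#' the double counting is auditable). Queries whose hit carries no
#' annotation, or whose identifiers have no hierarchy path of the requested
#' depth, are counted as unassigned. The accounting identity
#' `n_assigned + n_unassigned == total queries` always holds.
#'
#' @param store An [NrStore-class].
#' @param annotated Output of [annotateSims()] with one row per query
#'   (apply [bestHitPerQuery()] first); duplicate query ids raise
#'   `seqnr_not_best_hit_reduced`.
#' @param source Namespace name (must match the annotation namespace).
#' @param level Hierarchy depth to summarize at (1 = most general).
#' @return List of class `CategorySummary`: `summary` (data.frame
#'   `category`, `n_queries`, sorted), `n_queries_total`, `n_assigned`,
#'   `n_unassigned`, `n_category_assignments` (sum over categories; >
#'   `n_assigned` exactly when queries reach several categories), `level`,
#'   `source`.
#' @export
summarizeByCategory <- function(store, annotated, source, level) {
  qsrc <- .checkSource(store, source)
  nrAssert(is.numeric(level) && length(level) == 1L && level >= 1L,
           "level must be a single integer >= 1")
  level <- as.integer(level)
  if (anyDuplicated(annotated$query_id))
    nrStop("seqnr_not_best_hit_reduced",
           "duplicate query_id: input must be best-hit reduced (one hit per query)")
  h <- as.data.table(store@hierarchies)
  lvcol <- paste0("level", level)
  cats <- if (level <= 5L)
    unique(h[source == qsrc & !is.na(get(lvcol)),
             .(native_id, category = get(lvcol))])
  else data.table(native_id = character(), category = character())
  pairs <- vector("list", nrow(annotated))
  for (i in seq_len(nrow(annotated))) {
    a <- annotated$annotations[[i]]
    if (!nrow(a)) next
    cc <- unique(cats$category[cats$native_id %in% unique(a$native_id)])
    if (length(cc))
      pairs[[i]] <- data.table(query_id = annotated$query_id[i], category = cc)
  }
  qc <- rbindlist(pairs[!vapply(pairs, is.null, logical(1))])
  total <- nrow(annotated)
  if (!nrow(qc)) {
    summary <- data.frame(category = character(), n_queries = integer(),
                          stringsAsFactors = FALSE)
    assigned <- 0L
    nassign <- 0L
  } else {
    summary <- canonicalOrder(setDF(qc[, .(n_queries = .N), by = category]))
    assigned <- length(unique(qc$query_id))
    nassign <- nrow(qc)
  }
  structure(list(summary = summary, n_queries_total = total,
                 n_assigned = assigned, n_unassigned = total - assigned,
                 n_category_assignments = nassign,
                 level = level, source = qsrc),
            class = "CategorySummary")
}

#' @export
print.CategorySummary <- function(x, ...) {
  cat(sprintf("Category summary: source '%s', hierarchy level %d\n",
              x$source, x$level))
  print(x$summary, row.names = FALSE)
  cat(sprintf("# %d queries: %d assigned (+%d multi-category assignments), %d unassigned\n",
              x$n_queries_total, x$n_assigned,
              x$n_category_assignments - x$n_assigned, x$n_unassigned))
  invisible(x)
}
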