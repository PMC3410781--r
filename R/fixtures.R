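# Run expr with a fixed RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.NT4 <- c("A", "C", "G", "T")

# n random residue strings, lengths uniform in [30, 300], guaranteed
# pairwise distinct (and distinct from `avoid`)
.randomResidues <- function(n, moltype) {
  alphabet <- if (moltype == "protein") .AA20 else .NT4
  draw <- function(k) {
    lens <- sample(30:300, k, replace = TRUE)
    chars <- sample(alphabet, sum(lens), replace = TRUE)
    vapply(split(chars, rep(seq_len(k), lens)), paste, character(1),
           collapse = "")
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  unname(out)
}

.FUNC_POOL <- sprintf("hypothetical function %02d", 1:12)
.ORG_POOL <- sprintf("Syntheticus sp. %02d", 1:8)

#' Generate synthetic source bundles with controlled overlap
#'
#' Writes `n_sources` complete source directories (FASTA + annotation table
#' + hierarchy table) under `directory`, emulating the structure of real
#' annotation-source dumps: a shared sequence pool of size
#' `ceiling(overlap_fraction * seqs_per_source)` appears in every source
#' under different native identifiers (the cross-source redundancy the
#' non-redundant merge collapses), the remaining sequences are
#' source-unique, and a fixed fraction of identifiers carries a function,
#' organism, taxid and a two-level hierarchy path while the rest are
#' sequence-only. Residues are uniform over the 20 standard amino acids
#' (or `ACGT`), lengths uniform in 30--300, so chance collisions are
#' effectively impossible and FASTA wrapping is exercised. Fully
#' reproducible: the same seed yields byte-identical directories.
#'
#' @param directory Output directory (one subdirectory per source).
#' @param n_sources Number of sources (>= 1).
#' @param seqs_per_source Sequences per source (>= 1).
#' @param overlap_fraction Fraction of each source's sequences drawn from
#'   the shared pool (0--1).
#' @param moltype `"protein"` or `"nucleotide"`.
#' @param seed Integer RNG seed.
#' @param annotation_rate Fraction of native ids with an annotation row
#'   (default 0.8; the rest are identity-only).
#' @param hierarchy_rate Fraction of annotated ids with a hierarchy path
#'   (default 0.9).
#' @return A ground-truth ledger: list with `specs` (list of
#'   [SourceSpec-class]), `global_distinct_sequences`, `shared_pool_size`,
#'   `per_source` (data.frame with per-source totals and unique-added
#'   counts computed directly from the generated ground truth), and `idmap`
#'   (data.frame: source, native_id, md5, function/organism/taxid where
#'   annotated, category, has_hierarchy).
#' @export
generateSources <- function(directory, n_sources, seqs_per_source,
                            overlap_fraction, moltype = "protein",
                            seed = 1L, annotation_rate = 0.8,
                            hierarchy_rate = 0.9) {
  nrAssert(n_sources >= 1 && seqs_per_source >= 1, "need >= 1 source and sequence")
  nrAssert(overlap_fraction >= 0 && overlap_fraction <= 1,
           "overlap_fraction must be in [0, 1]")
  nrAssert(moltype %in% c("protein", "nucleotide"), "bad moltype")
  n_sources <- as.integer(n_sources)
  seqs_per_source <- as.integer(seqs_per_source)
  m <- as.integer(ceiling(overlap_fraction * seqs_per_source))
  m <- min(m, seqs_per_source)
  n_unique <- seqs_per_source - m
  withSeed(seed, {
    pool <- .randomResidues(m + n_sources * n_unique, moltype)
    shared <- if (m > 0) pool[seq_len(m)] else character()
    uniques <- if (n_unique > 0)
      split(pool[(m + 1):length(pool)], rep(seq_len(n_sources), each = n_unique))
    else rep(list(character()), n_sources)

    dir.create(directory, showWarnings = FALSE, recursive = TRUE)
    specs <- vector("list", n_sources)
    idmap <- vector("list", n_sources)
    for (i in seq_len(n_sources)) {
      name <- sprintf("SRC%02d", i)
      sdir <- file.path(directory, name)
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      residues <- c(shared, uniques[[i]])
      ids <- sprintf("%s_%05d", name, seq_along(residues))
      annotated <- stats::runif(length(ids)) < annotation_rate
      fk <- sample.int(length(.FUNC_POOL), length(ids), replace = TRUE)
      ok <- sample.int(length(.ORG_POOL), length(ids), replace = TRUE)
      hashier <- annotated & stats::runif(length(ids)) < hierarchy_rate
      category <- sprintf("Category %d", (fk - 1L) %/% 3L + 1L)

      fapath <- file.path(sdir, "sequences.fasta")
      Biostrings::writeXStringSet(
        Biostrings::BStringSet(structure(residues, names = ids)),
        fapath, width = 80L)

      annpath <- file.path(sdir, "annotations.tsv")
      annrows <- sprintf("%s\t%s\t%s\t%d", ids[annotated],
                         .FUNC_POOL[fk[annotated]], .ORG_POOL[ok[annotated]],
                         1000L + ok[annotated])
      writeLines(c("native_id\tfunction\torganism\ttaxid", annrows), annpath)

      hierpath <- file.path(sdir, "hierarchy.tsv")
      hierrows <- sprintf("%s\t%s\t%s", ids[hashier], category[hashier],
                          .FUNC_POOL[fk[hashier]])
      writeLines(hierrows, hierpath)

      specs[[i]] <- sourceSpec(name, moltype, fapath, annpath, hierpath)
      idmap[[i]] <- data.frame(
        source = name, native_id = ids, md5 = computeMd5Id(residues),
        shared = seq_along(residues) <= m,
        annotated = annotated,
        func = ifelse(annotated, .FUNC_POOL[fk], NA_character_),
        organism = ifelse(annotated, .ORG_POOL[ok], NA_character_),
        taxid = ifelse(annotated, 1000L + ok, NA_integer_),
        category = ifelse(hashier, category, NA_character_),
        has_hierarchy = hashier,
        stringsAsFactors = FALSE)
    }
  })
  idmap <- do.call(rbind, idmap)
  rownames(idmap) <- NULL

  # ground-truth uniqueness accounting by direct set construction on the
  # generated metadata (independent of the store implementation)
  per <- do.call(rbind, lapply(seq_len(n_sources), function(i) {
    name <- sprintf("SRC%02d", i)
    mine <- idmap[idmap$source == name, ]
    other <- idmap[idmap$source != name, ]
    uadd <- function(col) {
      v <- unique(mine[[col]][!is.na(mine[[col]])])
      length(setdiff(v, other[[col]]))
    }
    data.frame(source = name,
               n_ids = length(unique(mine$native_id)),
               n_sequences = length(unique(mine$md5)),
               n_functions = length(unique(mine$func[!is.na(mine$func)])),
               n_organisms = length(unique(mine$organism[!is.na(mine$organism)])),
               unique_added_ids = uadd("native_id"),
               unique_added_sequences = uadd("md5"),
               unique_added_functions = uadd("func"),
               unique_added_organisms = uadd("organism"),
               stringsAsFactors = FALSE)
  }))
  list(specs = specs,
       global_distinct_sequences = m + n_sources * n_unique,
       shared_pool_size = m,
       per_source = per,
       idmap = idmap)
}

#' Generate a synthetic similarity file against a fixture ledger
#'
#' Writes a 12-column tabular similarity file whose subjects are MD5
#' fingerprints from a [generateSources()] ledger, plus an optional
#' fraction of decoy subjects absent from the store. Bit scores within a
#' query are distinct, so the best hit is unambiguous, and the expected
#' category profile at hierarchy level 1 is computed directly from the
#' ledger's ground truth (not through the store).
#'
#' @param ledger Ledger returned by [generateSources()].
#' @param path Output file path.
#' @param n_queries Number of query reads.
#' @param hit_rate Fraction of queries with at least one hit.
#' @param decoy_fraction Fraction of hit subjects replaced by decoys.
#' @param hits_per_query Maximum hits per query (uniform 1..max).
#' @param seed Integer RNG seed.
#' @param source Namespace used for the expected summary (default first).
#' @return List: `path`, `n_hits`, `n_queries_with_hits`, and `expected`
#'   (for `source`, level 1: `summary` data.frame, `n_assigned`,
#'   `n_unassigned` over queries with hits).
#' @export
generateSims <- function(ledger, path, n_queries, hit_rate,
                         decoy_fraction = 0, hits_per_query = 3L, seed = 1L,
                         source = ledger$per_source$source[1L]) {
  nrAssert(n_queries >= 0 && hit_rate >= 0 && hit_rate <= 1 &&
             decoy_fraction >= 0 && decoy_fraction <= 1,
           "invalid sims generator parameters")
  storemd5 <- unique(ledger$idmap$md5)
  lines <- character()
  best <- data.frame(query_id = character(), subject_md5 = character(),
                     stringsAsFactors = FALSE)
  withSeed(seed, {
    rows <- list()
    bestrows <- list()
    for (q in seq_len(n_queries)) {
      qid <- sprintf("read_%05d", q)
      if (stats::runif(1) >= hit_rate) next
      k <- sample.int(hits_per_query, 1L)
      subj <- sample(storemd5, k, replace = TRUE)
      decoy <- stats::runif(k) < decoy_fraction
      if (any(decoy)) {
        dec <- computeMd5Id(sprintf("DECOY%s%d", qid, which(decoy)))
        dec[dec %in% storemd5] <- NA  # astronomically unlikely; drop if so
        subj[decoy] <- dec
        subj <- subj[!is.na(subj)]
        k <- length(subj)
        if (!k) next
      }
      bits <- sort(round(stats::runif(k, 50, 500), 1), decreasing = TRUE)
      bits <- bits + seq(0.09, 0, length.out = k)  # force distinct scores
      alen <- sample(30:300, k, replace = TRUE)
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.2f",
        qid, subj, round(stats::runif(k, 35, 100), 1), alen,
        sample(0:20, k, replace = TRUE), sample(0:3, k, replace = TRUE),
        1L, alen, sample(1:50, k, replace = TRUE),
        sample(51:400, k, replace = TRUE),
        10^-round(stats::runif(k, 3, 50), 1), bits)
      bestrows[[length(bestrows) + 1L]] <-
        data.frame(query_id = qid, subject_md5 = subj[1L],
                   stringsAsFactors = FALSE)
    }
    lines <- unlist(rows)
    if (length(bestrows)) best <- do.call(rbind, bestrows)
  })
  writeLines(c("# synthetic similarity fixture (12-column tabular)",
               lines), path)

  # expected level-1 profile from ground truth: best hit's subject ->
  # annotated native ids in `source` -> their categories
  im <- ledger$idmap[ledger$idmap$source == source, ]
  qcats <- lapply(seq_len(nrow(best)), function(i) {
    rows <- im[im$md5 == best$subject_md5[i] & im$annotated, ]
    unique(rows$category[!is.na(rows$category)])
  })
  assigned <- vapply(qcats, function(x) length(x) > 0L, logical(1))
  tab <- table(unlist(qcats))
  expected <- list(
    summary = if (length(tab))
      canonicalOrder(data.frame(category = names(tab),
                                n_queries = as.integer(tab),
                                stringsAsFactors = FALSE))
    else data.frame(category = character(), n_queries = integer(),
                    stringsAsFactors = FALSE),
    n_assigned = sum(assigned),
    n_unassigned = sum(!assigned))
  list(path = path, n_hits = length(lines),
       n_queries_with_hits = nrow(best), expected = expected,
       source = source)
}

#' Brute-force distinct-sequence oracle
#'
#' Counts distinct normalized residue strings across source FASTA files by
#' direct string-set construction — no fingerprinting anywhere on this
#' path — applying the same skip rule as conversion (records that are
#' empty or contain non-letter residues after normalization are excluded).
#' Used in tests as the independent check that MD5-keyed deduplication
#' neither merges distinct sequences nor keeps duplicates.
#'
#' @param fasta_paths Character vector of FASTA file paths.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return Integer: number of distinct normalized residue strings.
#' @export
naiveDedupOracle <- function(fasta_paths, moltype = "protein") {
  seen <- character()
  for (p in fasta_paths) {
    raw <- as.character(Biostrings::readBStringSet(p))
    s <- toupper(gsub("[[:space:]]+", "", raw))
    if (moltype == "protein") s <- sub("\\*$", "", s)
    s <- s[nzchar(s) & grepl("^[A-Z]+$", s)]
    seen <- unique(c(seen, s))
  }
  length(seen)
}
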