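test_that("merge unions sequences by fingerprint and keeps all identity rows", {
  dir <- tempfile()
  a <- convertSource(writeToySource(dir, "A", c(a1 = "MKL")))
  b <- convertSource(writeToySource(dir, "B", c(b1 = "MKL", b2 = "VVW")))
  st <- mergeSources(list(a, b))
  expect_identical(length(st), 2L)
  ann <- nrAnnotations(st)
  expect_identical(nrow(ann), 3L)
  m <- computeMd5Id("MKL")
  expect_setequal(ann$source[ann$md5 == m], c("A", "B"))
})

test_that("re-merging a renamed copy grows metadata only", {
  led <- generateSources(tempfile(), 2, 40, 0.25, seed = 21)
  bundles <- lapply(led$specs, convertSource)
  st <- mergeSources(bundles)
  n0 <- length(st)
  a0 <- nrow(nrAnnotations(st))
  renamed <- bundles[[1]]
  renamed@name <- "SRC01_COPY"
  renamed@annotations$source <- "SRC01_COPY"
  renamed@hierarchies$source <- "SRC01_COPY"
  st2 <- addSource(st, renamed)
  expect_identical(length(st2), n0)  # not one sequence added
  src1rows <- sum(nrAnnotations(st)$source == "SRC01")
  expect_identical(nrow(nrAnnotations(st2)), a0 + src1rows)
})

test_that("merge rejects mixed moltypes and duplicate names", {
  dir <- tempfile()
  a <- convertSource(writeToySource(dir, "A", c(a1 = "MKL")))
  b <- convertSource(writeToySource(dir, "B", c(b1 = "ACGT"),
                                    moltype = "nucleotide"))
  expect_error(mergeSources(list(a, b)), class = "seqnr_mixed_moltype")
  a2 <- convertSource(writeToySource(dir, "A", c(x = "VVW")))
  expect_error(mergeSources(list(a, a2)), class = "seqnr_duplicate_source")
  expect_error(addSource(mergeSources(list(a)), a2),
               class = "seqnr_duplicate_source")
})

test_that("addSource is equivalent to merging everything at once", {
  led <- generateSources(tempfile(), 3, 60, 0.4, seed = 22)
  bundles <- lapply(led$specs, convertSource)
  allAtOnce <- mergeSources(bundles)
  oneByOne <- Reduce(addSource, bundles[-1], mergeSources(bundles[1]))
  expect_identical(sort(names(nrSequences(oneByOne))),
                   sort(names(nrSequences(allAtOnce))))
  expect_identical(nrAnnotations(oneByOne), nrAnnotations(allAtOnce))
  expect_identical(nrHierarchies(oneByOne), nrHierarchies(allAtOnce))

  # disjoint source grows the sequence count by exactly its size
  led2 <- generateSources(tempfile(), 1, 25, 0, seed = 23)
  extra <- convertSource(led2$specs[[1]])
  extra@name <- "EXTRA"
  extra@annotations$source <- "EXTRA"
  extra@hierarchies$source <- "EXTRA"
  grown <- addSource(allAtOnce, extra)
  expect_identical(length(grown), length(allAtOnce) + length(nrSequences(extra)))
})

test_that("nr FASTA has reduced sorted headers and 80-column wrapping", {
  dir <- tempfile()
  long <- paste(rep("A", 100), collapse = "")
  a <- convertSource(writeToySource(dir, "A", c(a1 = "MKL", a2 = long)))
  st <- mergeSources(list(a))
  fa <- tempfile(fileext = ".fa")
  expect_identical(writeNrFasta(st, fa), 2L)
  lines <- readLines(fa)
  heads <- grep("^>", lines, value = TRUE)
  expect_length(heads, 2L)
  expect_true(all(grepl("^>[0-9a-f]{32}$", heads)))
  expect_identical(heads, sort(heads, method = "radix"))
  body <- lines[!startsWith(lines, ">")]
  expect_true(any(nchar(body) == 80L) && any(nchar(body) == 20L))
  back <- as.character(Biostrings::readBStringSet(fa))
  expect_identical(back[sort(names(back))],
                   nrSequences(st)[sort(names(nrSequences(st)))])
})

test_that("dump is canonical: byte-identical across rebuilds and merge orders", {
  led <- generateSources(tempfile(), 4, 50, 0.5, seed = 24)
  bundles <- lapply(led$specs, convertSource)
  d1 <- tempfile(); d2 <- tempfile()
  writeStore(mergeSources(bundles), d1)
  writeStore(mergeSources(rev(bundles)), d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d2, fn)),
                     readLines(file.path(d1, fn)), label = fn)
  }
})

test_that("absent organism yields no dump row; manifest counts are exact", {
  toy <- buildToyStore()
  d <- tempfile()
  manifest <- writeStore(toy$store, d)
  org <- readLines(file.path(d, "md52org.tsv"))
  # seed2's record has a function but no organism: absent, not empty
  expect_false(any(grepl("seed2", org)))
  expect_false(any(grepl("\t$", org)))  # taxid present whenever organism is
  for (i in seq_len(nrow(manifest))) {
    fn <- manifest$filename[i]
    if (fn == "nr.fasta") next
    expect_identical(length(readLines(file.path(d, fn))),
                     as.integer(manifest$row_count[i]), label = fn)
    expect_identical(unname(tools::md5sum(file.path(d, fn))),
                     manifest$md5[i], label = fn)
  }
  expect_true("nr.fasta" %in% manifest$filename)
})

test_that("store round-trips through its dump", {
  led <- generateSources(tempfile(), 3, 40, 0.3, seed = 25)
  st <- mergeSources(lapply(led$specs, convertSource))
  d1 <- tempfile()
  writeStore(st, d1)
  st2 <- loadStore(d1)
  expect_identical(st2@moltype, st@moltype)
  expect_identical(st2@sequences[sort(names(st2@sequences))],
                   st@sequences[sort(names(st@sequences))])
  d2 <- tempfile()
  writeStore(st2, d2)
  for (fn in list.files(d1))
    expect_identical(readLines(file.path(d2, fn)),
                     readLines(file.path(d1, fn)), label = fn)
})

test_that("loading detects missing files and corrupted identifiers", {
  toy <- buildToyStore()
  d <- tempfile()
  writeStore(toy$store, d)
  file.remove(file.path(d, "md52id.tsv"))
  expect_error(loadStore(d), class = "seqnr_missing_file")

  d2 <- tempfile()
  writeStore(toy$store, d2)
  idlines <- readLines(file.path(d2, "md52id.tsv"))
  bogus <- strrep("f", 32)
  idlines[1] <- sub("^[0-9a-f]{32}", bogus, idlines[1])
  writeLines(idlines, file.path(d2, "md52id.tsv"))
  err <- expect_error(loadStore(d2), class = "seqnr_integrity_error")
  expect_match(conditionMessage(err), bogus)
})

test_that("empty store refuses to write a FASTA", {
  toy <- buildToyStore()
  st <- toy$store
  st@sequences <- character()
  st@annotations <- seqnr:::emptyAnnotations()
  expect_error(writeNrFasta(st, tempfile()), class = "seqnr_empty_store")
})

test_that("statistics reproduce hand-computed uniqueness counts", {
  # A has {s1,s2,s3}, B has {s3,s4}: global 4; unique added A=2, B=1
  dir <- tempfile()
  a <- convertSource(writeToySource(dir, "A",
                                    c(a1 = "AAAA", a2 = "CCCC", a3 = "DDDD")))
  b <- convertSource(writeToySource(dir, "B", c(b1 = "DDDD", b2 = "EEEE")))
  st <- mergeSources(list(a, b))
  ps <- computeStatistics(st)$per_source
  expect_identical(ps$n_sequences, c(3L, 2L))
  expect_identical(ps$unique_added_sequences, c(2L, 1L))
  expect_identical(computeStatistics(st)$totals[["total_sequences"]], 4L)

  # single source: everything it has is unique-added
  solo <- computeStatistics(mergeSources(list(a)))$per_source
  expect_identical(solo$unique_added_sequences, solo$n_sequences)
  expect_identical(solo$unique_added_ids, solo$n_ids)
})

test_that("function strings are compared exactly and case-sensitively", {
  dir <- tempfile()
  a <- convertSource(writeToySource(dir, "A", c(a1 = "AAAA"),
                                    annLines = "a1\tKinase\t\t"))
  b <- convertSource(writeToySource(dir, "B", c(b1 = "CCCC"),
                                    annLines = "b1\tkinase\t\t"))
  stats <- computeStatistics(mergeSources(list(a, b)))
  expect_identical(stats$totals[["total_functions"]], 2L)
  expect_identical(stats$per_source$unique_added_functions, c(1L, 1L))
})

test_that("merged sequence count equals the brute-force distinct-string count", {
  led <- generateSources(tempfile(), 3, 80, 0.4, seed = 26)
  st <- mergeSources(lapply(led$specs, convertSource))
  fastas <- vapply(led$specs, function(s) s@fastaPath, character(1))
  expect_identical(length(st), naiveDedupOracle(fastas))
  expect_identical(length(st), led$global_distinct_sequences)
})

test_that("per-source unique-added never exceeds per-source totals", {
  led <- generateSources(tempfile(), 4, 60, 0.6, seed = 27)
  ps <- computeStatistics(mergeSources(lapply(led$specs, convertSource)))$per_source
  for (k in c("ids", "sequences", "functions", "organisms")) {
    expect_true(all(ps[[paste0("unique_added_", k)]] <= ps[[paste0("n_", k)]]))
    expect_true(all(ps[[paste0("unique_added_", k)]] >= 0L))
  }
})
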