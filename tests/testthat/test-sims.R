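toy <- buildToyStore()
st <- toy$store
P <- toy$md5

test_that("tabular similarity parser maps the 12 fields and skips comments", {
  f <- tempfile()
  writeLines(c("# BLASTP 2.2.26 [Sep-21-2011]",
               m8line("q1", "068792e95e38032059ba7d9c26c1be78")), f)
  h <- parseM8(f)
  expect_identical(nrow(h), 1L)
  expect_identical(h$subject_md5, "068792e95e38032059ba7d9c26c1be78")
  expect_identical(h$pct_identity, 98.5)
  expect_identical(h$aln_length, 120L)
  expect_identical(h$e_value, 1e-50)
  expect_identical(h$bit_score, 230)

  writeLines("q1\tsubj\t98.5\t120\t2\t0\t1\t120\t5\t124\t1e-50", f)  # 11 fields
  err <- expect_error(parseM8(f), class = "seqnr_malformed_sim_line")
  expect_match(conditionMessage(err), "line 1")

  writeLines(m8line("q1", "not_an_md5_subject_field_at_all!"), f)
  expect_error(parseM8(f), class = "seqnr_malformed_id")

  writeLines(m8line("q1", strrep("a", 32), ident = 101), f)
  expect_error(parseM8(f), class = "seqnr_malformed_sim_line")

  writeLines("# only comments", f)
  expect_identical(nrow(parseM8(f)), 0L)
})

test_that("filters default to pass-through and apply each threshold", {
  f <- tempfile()
  writeLines(c(m8line("q1", strrep("a", 32), ev = 1e-50, len = 120),
               m8line("q2", strrep("b", 32), ev = 1e-3, len = 40,
                      ident = 55)), f)
  hits <- parseM8(f)
  expect_identical(filterHits(hits), hits)
  expect_identical(filterHits(hits, max_evalue = 1e-5)$query_id, "q1")
  expect_identical(filterHits(hits, min_identity = 90)$query_id, "q1")
  expect_identical(filterHits(hits, min_length = 100)$query_id, "q1")
})

test_that("best-hit reduction is deterministic with the documented tie rules", {
  f <- tempfile()
  writeLines(c(m8line("q1", strrep("a", 32), bit = 230),
               m8line("q1", strrep("b", 32), bit = 180),
               m8line("q2", strrep("d", 32), bit = 100, ev = 1e-10),
               m8line("q2", strrep("c", 32), bit = 100, ev = 1e-20),
               m8line("q3", strrep("f", 32), bit = 90, ev = 1e-5),
               m8line("q3", strrep("e", 32), bit = 90, ev = 1e-5)), f)
  hits <- parseM8(f)
  best <- bestHitPerQuery(hits)
  expect_identical(best$subject_md5,
                   c(strrep("a", 32),   # higher bit score
                     strrep("c", 32),   # tie on bit, lower e-value
                     strrep("e", 32)))  # full tie, smaller md5
  expect_false(anyDuplicated(best$query_id) > 0)
  # invariant to input permutation
  for (i in 1:5) {
    perm <- hits[sample(nrow(hits)), ]
    expect_identical(bestHitPerQuery(perm), best)
  }
  expect_identical(nrow(bestHitPerQuery(hits[0, ])), 0L)
})

test_that("annotation conserves every hit, including unknown subjects", {
  f <- tempfile()
  writeLines(c(m8line("q1", P[["P1"]]),
               m8line("q2", P[["P4"]]),          # in store, not in COG
               m8line("q3", strrep("0", 32))), f)  # decoy, absent entirely
  ann <- annotateSims(st, parseM8(f), "COG")
  expect_identical(nrow(ann), 3L)
  expect_identical(ann$query_id, c("q1", "q2", "q3"))  # input order kept
  expect_identical(ann$n_annotations, c(2L, 0L, 0L))
  expect_identical(ann$annotations[[1]]$native_id, c("COG0001", "COG0001"))
  flat <- flattenAnnotatedHits(ann)
  expect_identical(nrow(flat), 4L)  # 2 facts + 2 placeholder rows
  expect_true(all(is.na(flat$native_id[flat$query_id != "q1"])))
  expect_error(annotateSims(st, parseM8(f), "NOPE"),
               class = "seqnr_unknown_source")
})

test_that("category summary counts distinct reads with exact accounting", {
  # 4 queries: q1 -> Metabolism (COG0001), q2 -> Metabolism + Transport
  # (COG0002, multi-membership), q3 -> identity-only hit, q4 -> decoy
  f <- tempfile()
  writeLines(c(m8line("q1", P[["P1"]]), m8line("q2", P[["P2"]]),
               m8line("q3", P[["P3"]]), m8line("q4", strrep("0", 32))), f)
  ann <- annotateSims(st, parseM8(f), "COG")
  cs <- summarizeByCategory(st, ann, "COG", 1)
  expect_identical(cs$summary$category, c("Metabolism", "Transport"))
  expect_identical(cs$summary$n_queries, c(2L, 1L))
  expect_identical(cs$n_assigned, 2L)
  expect_identical(cs$n_unassigned, 2L)
  expect_identical(cs$n_category_assignments, 3L)  # q2 counted twice
  expect_identical(cs$n_assigned + cs$n_unassigned, cs$n_queries_total)

  # at level 2 the categories are the leaf names
  cs2 <- summarizeByCategory(st, ann, "COG", 2)
  expect_setequal(cs2$summary$category,
                  c("Amino acid transport", "Carbohydrates",
                    "ABC transporters"))

  # a level deeper than every path: everything unassigned
  cs9 <- summarizeByCategory(st, ann, "COG", 9)
  expect_identical(cs9$n_assigned, 0L)
  expect_identical(cs9$n_unassigned, 4L)

  dup <- rbind(ann, ann)
  expect_error(summarizeByCategory(st, dup, "COG", 1),
               class = "seqnr_not_best_hit_reduced")
})

test_that("accounting identity holds on randomized generated fixtures", {
  led <- generateSources(tempfile(), 2, 60, 0.3, seed = 41)
  big <- mergeSources(lapply(led$specs, convertSource))
  for (seed in 42:45) {
    sims <- generateSims(led, tempfile(fileext = ".m8"), n_queries = 40,
                         hit_rate = 0.7, decoy_fraction = 0.2, seed = seed)
    hits <- parseM8(sims$path)
    expect_identical(nrow(hits), sims$n_hits)
    best <- bestHitPerQuery(hits)
    ann <- annotateSims(big, best, sims$source)
    expect_identical(nrow(ann), nrow(best))  # conservation
    cs <- summarizeByCategory(big, ann, sims$source, 1)
    expect_identical(cs$n_assigned + cs$n_unassigned, cs$n_queries_total)
    expect_identical(cs$n_queries_total, sims$n_queries_with_hits)
    # ground-truth profile from the generator ledger
    expect_identical(cs$summary, sims$expected$summary)
    expect_identical(cs$n_unassigned, sims$expected$n_unassigned)
  }
})
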