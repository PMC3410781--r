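---
title: "Methods: building and querying an MD5-keyed non-redundant annotation store"
author: "seqnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and querying an MD5-keyed non-redundant annotation store}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqnr)
```

## The model

Comparative reference databases duplicate each other heavily: the same
protein appears in an archive database, a pathway database and an
orthologous-group catalog, each time under a different identifier and with
different annotations. `seqnr` separates the two concerns. The **data** is
the set of distinct residue strings; the **metadata** is everything the
sources say about them. The join key between the two is the sequence
itself, represented by the 32-character hexadecimal MD5 digest of its
normalized form. Because the key is a pure function of the residues,
merging sources needs no identifier reconciliation: two records agree on
the key exactly when they are the same sequence, and a newly imported
namespace whose proteins already exist contributes only metadata rows.

Three consequences drive the whole design:

* **Deduplication is exact, not heuristic.** Identity of the normalized
  residue string — never clustering, never similarity — decides whether
  two records collapse.
* **Namespace translation is a join.** `from_id → md5 → to_id` resolves
  through two exact-key lookups, which is why bulk translation scales to
  hundreds of thousands of identifiers per second in memory.
* **A similarity search is computed once.** Tabular BLAST/BLAT output
  against the store's FASTA has MD5 subjects, so the same hit file can be
  re-interpreted in every namespace without re-searching.

MD5 collisions are theoretically possible and are deliberately treated as
identity *except* that the store verifies residues on every merge: if one
fingerprint ever maps to two different residue strings the merge aborts
with a fatal `ResidueMismatch`-class error rather than silently picking a
winner, because that situation can only mean an implementation bug or a
genuine collision, and both must surface.

## The normalization contract

The fingerprint is only as stable as the normalization in front of it, so
the normalization is a published, frozen contract:

1. remove all whitespace;
2. uppercase;
3. for proteins only, strip exactly one trailing `*` (a translated stop
   codon);
4. reject anything that is then empty or contains a character outside
   `A`–`Z`.

Rare and ambiguity codes (`B`, `J`, `O`, `U`, `X`, `Z`) are letters and
pass. Alignment gaps (`-`) and internal stops are rejected, not removed: a
gapped string is an alignment artifact, and silently deleting characters
would merge sequences that differ in ways the user can see. The digest
input encoding is fixed at one byte per residue character (ASCII), so the
fingerprint is bit-reproducible across implementations; the raw digest
path is validated against the seven published RFC 1321 test vectors.
Other MD5-keyed sequence resources do not document their normalization,
so fingerprints computed here may differ from theirs for edge cases
(lowercase input, trailing stops); within this package the contract above
is the definition of sequence identity.

## Conversion and merge semantics

Conversion of one source (FASTA + annotation table) is tolerant of dirty
input by design — real database dumps contain malformed records, and a
batch build must complete. Sequences failing normalization, duplicate
native identifiers (first occurrence wins) and annotation rows referencing
unknown identifiers are all skipped with a recorded reason, never fatal.
Two decisions deserve explanation:

* **Unannotated sequences still enter the store** as identity-only rows
  (source + native id, no function/organism). Presence in a source is
  itself metadata: "which databases contain this protein" is a query the
  store must answer.
* **Absent is never the empty string.** A missing function is `NA`
  everywhere, contributes no row to the function dump table, and is not
  counted in function statistics.

Merging is a union keyed by fingerprint with deduplicated metadata. It is
associative and order-insensitive by construction, and the tests assert
the stronger property that any permutation of sources produces
byte-identical output files.

## Canonical ordering and the dump contract

Every table the package writes is deduplicated and sorted
lexicographically on all columns in the C locale (`data.table` radix
ordering), and the FASTA is sorted by fingerprint with 80-column wrapping.
Byte-reproducibility is a feature, not a nicety: releases can be diffed,
and determinism failures become visible as single-byte differences.

The on-disk dump (`nr.fasta`, `md52id.tsv`, `md52func.tsv`, `md52org.tsv`,
`hierarchy.tsv`, `sources.tsv`, `manifest.tsv`) is the portable contract;
whether a deployment keeps the store in memory, in flat files or loads it
into a relational engine is an implementation detail behind the same
operations. One subtlety follows from the fixed schema: the dump projects
the annotation facts `(md5, source, native_id, function, organism, taxid)`
onto three two-or-three-column tables, so *store equality is defined as
canonical-dump equality*. Reloading widens a `(md5, source)` group to the
cross product of its identifiers and functions only in the rare case where
a group has several of both; the dumps re-project identically, every query
about "which functions does this namespace attach to this sequence"
is unaffected, and the load path additionally verifies that every FASTA
record hashes to its own header and that no table references an unknown
fingerprint.

## Statistics

Per-source statistics count distinct native identifiers, fingerprints,
function strings and organism strings, and the **unique added** number of
each — elements present in that source and in no other. String matching is
exact and case-sensitive: the totals are counts of unique
*representations*, and no fuzzy merging of annotation vocabulary is
attempted (`"Kinase"` and `"kinase"` are two functions). The percentage
column is defined in this package as
`unique_added / global distinct total`, reported to one decimal; the
denominator choice is our convention and is stated here because other
reasonable denominators (per-source totals) exist.

## Similarity post-processing

The sims module consumes the standard 12-column tabular alignment format
and never edits alignments: coordinates are carried verbatim (1-based,
inclusive, aligner convention). Filtering has pass-everything defaults so
any threshold in a published profile is an explicit caller choice. Best-hit
reduction keeps, per query, the maximal bit score, breaking ties by
minimal e-value and then smallest subject fingerprint — a total order, so
the reduction is deterministic and permutation-invariant.

Category profiles count **distinct queries (reads), not hits**: each query
adds one to every distinct hierarchy category it reaches through its best
hit's annotations. A query reaching two categories is counted in both;
the summary reports the number of category assignments alongside the
number of assigned queries so the double counting is auditable, and the
accounting identity `assigned + unassigned = total queries` is asserted on
every summary. Annotation is conservative: a hit whose subject the
namespace does not know (including subjects absent from the store
entirely) is retained with an empty annotation set, never dropped.

Hierarchies are flat ordered paths of one to five levels attached to
`(source, native_id)`, not to the fingerprint: hierarchy membership is a
property of the source's identifier (a COG belongs to a functional
category; a sequence merely maps to the COG). A fingerprint reaches
hierarchies through its identifier rows. The alternative — attaching paths
directly to fingerprints — would lose the distinction between two
identifiers of the same sequence sitting in different subsystems.

## The synthetic data generator

`generateSources()` emulates the *structure* of multi-source input — not
sequence biology. It draws residues uniformly over the 20 standard amino
acids (lengths uniform in 30–300, exercising FASTA wrapping), plants a
shared sequence pool in every source under different native identifiers
(the redundancy the merge must collapse), annotates 80% of identifiers
from small function/organism pools (the remainder are identity-only), and
gives 90% of annotated identifiers a two-level hierarchy path. Every
generated bundle comes with a ground-truth ledger (expected distinct
counts, per-source unique-added counts, the full id↔fingerprint map)
computed from the construction itself, so store results can be checked
against values the store code never touched; a separate brute-force
oracle recounts distinct sequences by direct string-set construction with
no hashing anywhere on its path.

What the generator does **not** emulate — homology, near-duplicates
differing by one residue, biased composition, real annotation vocabulary —
bounds what passing tests show: they demonstrate the bookkeeping
(deduplication, merge, translation, accounting) is exact, not that any
biological interpretation is sensible. Near-duplicate sequences are by
design *not* merged by this system, so their absence from the fixtures is
not a blind spot of the tests.

Problem sizes used in the shipped checks were chosen to keep the full
suite comfortably interactive while still exceeding the scales at which
bookkeeping bugs hide: twenty merge fixtures up to 10 sources × 1,000
sequences with overlaps spanning 0–1, and a bulk-lookup check of 10^5
identifiers against a 10^4-sequence store (which completes in well under a
second; the 10-second bound in the test is a smoke-test ceiling, not a
benchmark). The acceptance script uses 5 × 500 sequences at 30% overlap
and 300 queries.

## Numerical and degenerate-input choices

* Empty store: writing a FASTA with zero records is refused (typed error)
  rather than producing a headerless file other tools mis-parse.
* Empty query batches return empty results; unknown fingerprints and
  identifiers yield empty results, while unknown *namespaces* raise —
  a missing sequence is data, a typo'd namespace is a caller bug.
* The `taxid` column must be a positive integer when present; `0`,
  negatives and non-numerics are typed errors at parse time.
* Tabs and newlines are forbidden in all values written to dump tables
  (checked at write time), keeping the TSV dialect quoting-free.
* The hierarchy depth cap is five levels; deeper paths are rejected at
  parse time rather than silently truncated.

## Known limitations

* MD5 is cryptographically broken; it is used here as a content
  fingerprint, exactly as in the systems this design follows, and
  adversarial collisions are out of scope (the residue-verification on
  merge would detect one).
* The store is held in memory; the design targets reference collections
  up to a few million sequences on a workstation, not arbitrary scale.
* Only the generic 4-column annotation dialect is parsed; adapters for
  vendor-native dump formats are intentionally out of scope, and the
  dialect is the documented integration point for writing them.
* Nucleotide stores are supported by the engine (normalization accepts
  any `A`–`Z` letters, so IUPAC ambiguity codes pass), but no curated
  rRNA-style source adapters ship.
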