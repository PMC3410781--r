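# seqnr — a non-redundant sequence annotation store keyed by MD5 fingerprints

Similarity searching is the dominant computational cost of metagenome
analysis, and much of that cost is spent re-searching the *same proteins*
because every annotation resource (GenBank-style archives, KEGG-style
pathway databases, subsystem collections, orthologous-group catalogs)
ships its own FASTA with its own identifiers. `seqnr` is for
bioinformaticians who want to search **once** against a collapsed
reference and then interpret that single result set in *any* annotation
namespace.

## The idea

Sequence collections split cleanly into **data** (the residue strings)
and **metadata** (identifiers, functions, organisms, taxonomy,
functional hierarchies). `seqnr` keys everything on the sequence itself:
each raw sequence is normalized (whitespace removed, uppercased, one
trailing stop `*` stripped for proteins) and fingerprinted with its
32-character hexadecimal MD5 digest,

```
md5 = MD5(normalized residue string)        # e.g. 6082a8b0eca486ae07ff251961ef1532
```

Identical sequences from any number of sources collapse onto one FASTA
record `>md5`, and every source's facts become rows in metadata tables
`(md5, source, native_id)`, `(md5, source, function)`,
`(md5, source, organism, taxid)`. Adding a new annotation source whose
proteins already exist **appends metadata only — the sequence set does
not grow**, which is what makes the approach scale with the number of
namespaces. Translation between namespaces (say, orthologous-group IDs
to subsystem roles) is then a pair of exact-key joins through the shared
fingerprint — strictly sequence *identity*, never annotation-string
similarity — and runs at hundreds of thousands of identifiers per
second. BLAST/BLAT tabular results computed against the non-redundant
FASTA carry MD5 subjects, so one similarity computation can be mapped
onto functions, organisms, and hierarchy categories in every loaded
namespace after the fact.

## Worked example

```r
library(seqnr)

# two synthetic annotation sources, 10 proteins each, 2 shared between them
led     <- generateSources("ex_sources", n_sources = 2, seqs_per_source = 10,
                           overlap_fraction = 0.2, seed = 7)
bundles <- lapply(led$specs, convertSource)
store   <- mergeSources(bundles)
store
#> NrStore (protein)
#>   18 distinct sequences
#>   20 annotation rows from 2 source(s): SRC01, SRC02
#>   14 hierarchy rows
```

Two of the twenty input proteins are shared, so the non-redundant store
holds 18 distinct sequences while keeping all 20 identifier rows. The
per-source statistics report what each source contributes beyond the
rest ("unique added"):

```r
computeStatistics(store)
#> Global distinct totals:
#>       total_ids total_sequences total_functions total_organisms
#>              20              18              10               6
#>  source n_sequences unique_added_sequences ...
#>   SRC01          10                      8
#>   SRC02          10                      8
```

Each source holds 10 sequences, 8 of which occur nowhere else — the 2
shared proteins are counted in both sources' totals but in neither's
unique-added column. Any fingerprint resolves into any namespace, and
identifiers translate between namespaces through the shared sequence:

```r
md52overview(store, "6082a8b0eca486ae07ff251961ef1532", "SRC01")
#>                                md5   native_id                 function           organism
#> 1 6082a8b0eca486ae07ff251961ef1532 SRC01_00001 hypothetical function 03 Syntheticus sp. 04

translateIds(store, "SRC01_00001", "SRC01", "SRC02")
#>       from_id                              md5       to_id              to_function
#> 1 SRC01_00001 6082a8b0eca486ae07ff251961ef1532 SRC02_00001 hypothetical function 05
```

The same protein carries the id `SRC01_00001` in one namespace and
`SRC02_00001` in the other; the translation runs purely over the MD5
key. A command-line tool wraps the same operations:

```sh
Rscript inst/scripts/nrtool.R build -config sources.yaml -out db/
Rscript inst/scripts/nrtool.R -store db/ -md5 6082a8b0eca486ae07ff251961ef1532 \
        -option md52overview -source SRC01
Rscript inst/scripts/nrtool.R sims -store db/ -sims hits.m8 -source SRC01 -summarize 1
```

Data rows go to stdout as TSV, diagnostics to stderr; exit codes are
0 (ok), 2 (usage/config), 3 (fatal build error), 4 (data error).

## Scope

`seqnr` builds, stores, queries and post-processes; it does not run
BLAST/BLAT (point your aligner at the `nr.fasta` it writes), does not
download real source databases (the generic 4-column tab-separated
annotation dialect is the documented integration point), and does not
model GO-style DAGs (hierarchies are flat ordered paths). See the
methods vignette (`vignettes/nr-store-methods.Rmd`) for the design
decisions, normalization contract and known limitations.
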