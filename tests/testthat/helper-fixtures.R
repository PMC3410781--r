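# Small hand-countable source bundles, built in code at test time.

writeToySource <- function(dir, name, seqs, annLines = NULL, hierLines = NULL,
                           moltype = "protein", header = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fasta"))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), fa)
  ann <- NA_character_
  if (!is.null(annLines)) {
    ann <- file.path(dir, paste0(name, "_ann.tsv"))
    hdr <- if (header) "native_id\tfunction\torganism\ttaxid" else character()
    writeLines(c(hdr, annLines), ann)
  }
  hier <- NA_character_
  if (!is.null(hierLines)) {
    hier <- file.path(dir, paste0(name, "_hier.tsv"))
    writeLines(hierLines, hier)
  }
  sourceSpec(name, moltype, fa, ann, hier)
}

# Two namespaces over four distinct proteins; P1 is shared between them.
toyProteins <- c(P1 = "MKLVWAAPQ", P2 = "GGHHIIKKL",
                 P3 = "TTTTVVVVW", P4 = "QQQQPPPPA")

buildToyStore <- function(dir = tempfile("toy")) {
  specA <- writeToySource(
    dir, "COG",
    c(COG0001 = toyProteins[["P1"]], COG0002 = toyProteins[["P2"]],
      COG0003 = toyProteins[["P3"]]),
    annLines = c("COG0001\tkinase\tEscherichia coli\t562",
                 "COG0001\tphosphatase\tEscherichia coli\t562",
                 "COG0002\ttransporter\tBacillus subtilis\t1423"),
    hierLines = c("COG0001\tMetabolism\tAmino acid transport",
                  "COG0002\tMetabolism\tCarbohydrates",
                  "COG0002\tTransport\tABC transporters"))
  specB <- writeToySource(
    dir, "SEED",
    c(seed1 = toyProteins[["P1"]], seed2 = toyProteins[["P4"]]),
    annLines = c("seed1\tkinase-like protein\tEscherichia coli K-12\t83333",
                 "seed2\thypothetical protein\t\t"),
    hierLines = c("seed1\tProtein Metabolism\tProtein phosphorylation"))
  bundles <- lapply(list(specA, specB), convertSource)
  list(store = mergeSources(bundles), specs = list(specA, specB),
       bundles = bundles, dir = dir,
       md5 = vapply(toyProteins, computeMd5Id, character(1)))
}

# m8 line builder
m8line <- function(q, s, ident = 98.5, len = 120, mism = 2, gaps = 0,
                   qs = 1, qe = 120, ss = 5, se = 124, ev = 1e-50,
                   bit = 230) {
  sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
          q, s, format(ident), len, mism, gaps, qs, qe, ss, se,
          format(ev), format(bit))
}

rscriptBin <- function() file.path(R.home("bin"), "Rscript")
nrtoolScript <- function() system.file("scripts", "nrtool.R", package = "seqnr")

runTool <- function(...) {
  out <- tempfile(); err <- tempfile()
  status <- suppressWarnings(
    system2(rscriptBin(), c(nrtoolScript(), ...), stdout = out, stderr = err))
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
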