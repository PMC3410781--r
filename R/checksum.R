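#' Normalize raw residue strings
#'
#' Normalization is the published identity contract of the store: two raw
#' FASTA sequences receive the same MD5 fingerprint if and only if they
#' normalize to the same residue string. The rules are
#' \enumerate{
#'   \item remove all whitespace characters,
#'   \item uppercase,
#'   \item for `moltype = "protein"`, strip exactly one trailing `*`
#'     (translated stop), if present.
#' }
#' After normalization the sequence must be nonempty and contain only the
#' letters `A`--`Z`. Ambiguity and rare-residue codes (`B`, `J`, `O`, `U`,
#' `X`, `Z`) are letters and therefore pass; alignment gaps (`-`) and internal
#' stops are rejected rather than silently removed, because a gapped string
#' is an alignment artifact, not a sequence.
#'
#' @param raw Character vector of raw residue strings as read from FASTA.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return For [normalizeSequence()], a single normalized residue string;
#'   errors of class `seqnr_empty_sequence` / `seqnr_illegal_character` on
#'   invalid input. For [normalizeSequences()], a list with `residues`
#'   (character, `NA` where invalid) and `reason` (`NA` where valid;
#'   otherwise `"empty_sequence"` or `"illegal_character at position <i>"`),
#'   used by the ingest path where per-record failures are skipped, not
#'   fatal.
#' @examples
#' normalizeSequence("mkl v*", "protein")   # "MKLV"
#' normalizeSequence("ACGT\n", "nucleotide") # "ACGT"
#' @seealso [computeMd5Id()], [validateMd5Id()]
#' @export
normalizeSequence <- function(raw, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  nrAssert(is.character(raw) && length(raw) == 1L && !is.na(raw),
           "raw must be a single string")
  res <- normalizeSequences(raw, moltype)
  if (is.na(res$residues)) {
    if (res$reason == "empty_sequence") {
      nrStop("seqnr_empty_sequence", "sequence is empty after normalization")
    }
    nrStop("seqnr_illegal_character",
           sprintf("illegal character in sequence (%s)", res$reason))
  }
  res$residues
}

#' @rdname normalizeSequence
#' @export
normalizeSequences <- function(raw, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  nrAssert(is.character(raw), "raw must be a character vector")
  s <- toupper(gsub("[[:space:]]+", "", raw))
  if (moltype == "protein") s <- sub("\\*$", "", s)
  reason <- rep(NA_character_, length(s))
  empty <- !is.na(s) & !nzchar(s)
  reason[empty | is.na(s)] <- "empty_sequence"
  bad <- !is.na(s) & nzchar(s) & !grepl("^[A-Z]+$", s)
  if (any(bad)) {
    pos <- regexpr("[^A-Z]", s[bad])
    chr <- substr(regmatches(s[bad], pos), 1L, 1L)
    reason[bad] <- sprintf("illegal_character '%s' at position %d", chr, as.integer(pos))
  }
  s[!is.na(reason)] <- NA_character_
  list(residues = s, reason = reason)
}

#' MD5 fingerprints of residue strings
#'
#' Computes the lowercase hexadecimal MD5 digest of each residue string,
#' hashing one byte per character (ASCII). This digest is the universal
#' sequence key of the store: all metadata attaches to it, and identical
#' sequences from different sources collapse onto one entry. The raw digest
#' path accepts any ASCII string (including the empty string) so that it can
#' be validated against the published MD5 test vectors; store keys themselves
#' are always digests of nonempty normalized `A-Z` strings.
#'
#' @param residues Character vector (typically output of
#'   [normalizeSequences()]).
#' @return Character vector of 32-character lowercase hex fingerprints.
#' @examples
#' computeMd5Id("abc")  # "900150983cd24fb0d6963f7d28e17f72"
#' @export
computeMd5Id <- function(residues) {
  nrAssert(is.character(residues) && !anyNA(residues),
           "residues must be a character vector without NA")
  as.character(openssl::md5(residues))
}

#' Validate and canonicalize MD5 identifiers
#'
#' Accepts 32-character hexadecimal strings in any case and returns the
#' canonical lowercase form; anything else raises `seqnr_malformed_id`.
#'
#' @param text Character vector of candidate identifiers.
#' @return Character vector of canonical lowercase identifiers.
#' @examples
#' validateMd5Id("068792E95E38032059BA7D9C26C1BE78")
#' @export
validateMd5Id <- function(text) {
  nrAssert(is.character(text), "text must be a character vector")
  ok <- !is.na(text) & grepl("^[0-9a-fA-F]{32}$", text)
  if (!all(ok)) {
    bad <- text[!ok][1L]
    nrStop("seqnr_malformed_id",
           sprintf("not a 32-character hexadecimal MD5 identifier: '%s'",
                   if (is.na(bad)) "NA" else bad))
  }
  tolower(text)
}

# TRUE/FALSE without raising; used where absence is data, not an error
isMd5Id <- function(text) {
  !is.na(text) & grepl("^[0-9a-fA-F]{32}$", text)
}
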