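#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats pchisq p.adjust cor prcomp rbinom rmultinom rnbinom runif
#'   rgamma quantile sd predict ks.test var residuals setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Missing genotype sentinel used in all tab-delimited serializations.
MISSING_CALL <- "-"

DNA_BASES <- c("A", "C", "G", "T")

#' IUPAC degenerate code covering a set of bases
#'
#' @param bases character vector of bases from A/C/G/T.
#' @return single IUPAC letter.
#' @keywords internal
iupacCode <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  stopifnot(all(bases %in% DNA_BASES))
  Biostrings::mergeIUPACLetters(paste(bases, collapse = ""))
}

#' Expand an IUPAC letter into its base set
#' @keywords internal
iupacExpand <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(code)]], "")[[1]]
}

## Convert a probe (possibly containing IUPAC letters) to a fixed-string
## regular expression matching its expansion set.
probeRegex <- function(probe) {
  ch <- strsplit(probe, "")[[1]]
  out <- vapply(ch, function(x) {
    if (x %in% DNA_BASES) x else paste0("[", Biostrings::IUPAC_CODE_MAP[[x]], "]")
  }, character(1))
  paste(out, collapse = "")
}

## Stage seeds are derived from one master seed so that every source of
## randomness is reproducible and below 2^31.
deriveSeed <- function(master, stage) {
  (as.integer(master) * 1009L + as.integer(stage) * 9973L) %% 2147483647L
}

randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""), character(1))
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Writers emit a first comment line beginning "#"; readers skip it.
writeTsvWithHeader <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# GTseqPanel %s v1", what), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

readTsvWithHeader <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = NA, na.strings = "NA")
}

## Canonical unordered diplotype string, e.g. c("CT","AG") -> "AG/CT".
diplotypeString <- function(h1, h2) {
  paste(pmin(h1, h2), pmax(h1, h2), sep = "/")
}
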