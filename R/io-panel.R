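#' Write panel primer and probe tables
#'
#' Writes two tab-delimited files for a panel (list of
#' \linkS4class{PanelEntry}): a primer table
#' (\code{locus, rank, fwd, rev, product_start, product_end, template,
#' kept_start, kept_end, discarded_snps}) and a
#' probe table with the eight columns
#' \code{locus, ploidy, alleles, probes, fwd_primer, snp_offset,
#' allele_correction, notes} — one row per SNP, alleles and their probes
#' comma-separated in matching order. This dialect is documented in the
#' package vignette; \code{\link{readPanelTables}} restores the identical
#' panel (lossless round trip).
#'
#' @param panel non-empty list of \linkS4class{PanelEntry}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
writePanelTables <- function(panel, dir, prefix = "panel") {
  if (!length(panel)) stop("panel is empty")
  noPrimer <- vapply(panel, function(e) !nzchar(e@primer@fwd), logical(1))
  if (any(noPrimer))
    stop("panel entries lacking primers: ",
         paste(vapply(panel[noPrimer], locusId, character(1)), collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  primers <- do.call(rbind, lapply(panel, function(e) {
    p <- e@primer
    data.frame(locus = p@locusId, rank = p@rank, fwd = p@fwd, rev = p@rev,
               product_start = p@productStart, product_end = p@productEnd,
               template = e@locus@sequence,
               kept_start = e@locus@keptStart, kept_end = e@locus@keptEnd,
               discarded_snps = e@locus@discardedSnps,
               stringsAsFactors = FALSE)
  }))
  probes <- do.call(rbind, lapply(panel, function(e) {
    pr <- e@probes
    do.call(rbind, lapply(split(pr, pr$snpOffset), function(s) {
      data.frame(locus = locusId(e), ploidy = 2L,
                 alleles = paste(s$allele, collapse = ","),
                 probes = paste(s$probe, collapse = ","),
                 fwd_primer = e@primer@fwd,
                 snp_offset = s$snpOffset[1],
                 allele_correction = 0,
                 notes = if (any(s$truncated)) "truncated" else ".",
                 stringsAsFactors = FALSE)
    }))
  }))
  probes <- probes[order(probes$locus, probes$snp_offset), ]
  pPath <- file.path(dir, paste0(prefix, "_primers.tsv"))
  qPath <- file.path(dir, paste0(prefix, "_probes.tsv"))
  writeTsvWithHeader(primers, pPath, "primer table")
  writeTsvWithHeader(probes, qPath, "probe table")
  invisible(c(primers = pPath, probes = qPath))
}

#' Read panel primer and probe tables
#'
#' @param primerPath,probePath the two files written by
#'   \code{\link{writePanelTables}}.
#' @param strict reject tables whose column layout differs from the
#'   documented dialect (default TRUE).
#' @return List of \linkS4class{PanelEntry}, named by locus.
#' @export
readPanelTables <- function(primerPath, probePath, strict = TRUE) {
  primers <- readTsvWithHeader(primerPath)
  probes <- readTsvWithHeader(probePath)
  primerCols <- c("locus", "rank", "fwd", "rev", "product_start",
                  "product_end", "template", "kept_start", "kept_end",
                  "discarded_snps")
  probeCols <- c("locus", "ploidy", "alleles", "probes", "fwd_primer",
                 "snp_offset", "allele_correction", "notes")
  if (strict) {
    if (!identical(names(primers), primerCols))
      stop("unexpected primer-table layout; expected columns: ",
           paste(primerCols, collapse = ", "))
    if (!identical(names(probes), probeCols))
      stop("unexpected probe-table layout; expected columns: ",
           paste(probeCols, collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(primers)), function(i) {
    loc <- primers$locus[i]
    pq <- probes[probes$locus == loc, , drop = FALSE]
    pq <- pq[order(pq$snp_offset), , drop = FALSE]
    if (!nrow(pq)) stop("no probe rows for locus ", loc)
    snpAlleles <- lapply(strsplit(pq$alleles, ","), toupper)
    probeDf <- do.call(rbind, lapply(seq_len(nrow(pq)), function(s) {
      al <- snpAlleles[[s]]
      pb <- strsplit(pq$probes[s], ",")[[1]]
      data.frame(locusId = loc, snpOffset = pq$snp_offset[s], allele = al,
                 probe = pb, truncated = identical(pq$notes[s], "truncated"),
                 stringsAsFactors = FALSE)
    }))
    tl <- new("TrimmedLocus", locusId = loc,
              sequence = toupper(primers$template[i]),
              snps = {
                df <- data.frame(offset = as.integer(pq$snp_offset))
                df$alleles <- snpAlleles
                ## a standalone panel file carries no upstream SNP history
                df$origIndex <- seq_len(nrow(df))
                df
              },
              keptStart = as.integer(primers$kept_start[i]),
              keptEnd = as.integer(primers$kept_end[i]),
              discardedSnps = as.integer(primers$discarded_snps[i]),
              removed = character(0))
    pp <- new("PrimerPair", locusId = loc, fwd = toupper(primers$fwd[i]),
              rev = toupper(primers$rev[i]), rank = as.integer(primers$rank[i]),
              productStart = as.integer(primers$product_start[i]),
              productEnd = as.integer(primers$product_end[i]))
    PanelEntry(tl, pp, probeDf)
  })
  names(entries) <- primers$locus
  entries
}
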