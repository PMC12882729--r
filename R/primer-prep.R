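#' Iterative SNP-position trimming for primer compatibility
#'
#' A SNP lying within the first \code{flank} bases of the current sequence
#' forces removal of everything from the current start through that SNP
#' inclusive; the remaining sequence is rescanned, iterating to a fixpoint;
#' the 3' end is treated symmetrically. The surviving sequence therefore
#' has at least \code{flank} bases before the first and after the last
#' retained SNP (25 bp of primer annealing room plus 8 bp of probe flank at
#' the default 33). Returns a removed marker when no SNP survives.
#'
#' The two passes commute for this rule, so the 5'-then-3' order is
#' presentational only.
#'
#' @param locus a \linkS4class{MicrohapLocus} with >= 1 SNP.
#' @param flank required clear flank in bp (default 33).
#' @return A \linkS4class{TrimmedLocus} (check \code{@removed}).
#' @export
trimSnpsForPrimers <- function(locus, flank = 33L) {
  if (flank < 1L) stop("flank must be >= 1")
  if (!nrow(locus@snps)) stop("locus has no SNPs")
  offs <- locus@snps$offset
  len <- nchar(locus@sequence)
  start <- 0L; end <- len                     # kept window, half-open
  keep <- rep(TRUE, length(offs))
  discarded <- 0L
  repeat {                                    # 5' pass to fixpoint
    live <- which(keep & offs >= start & offs < end)
    if (!length(live)) break
    first <- live[1]
    if (offs[first] - start < flank) {
      start <- offs[first] + 1L
      keep[first] <- FALSE
      discarded <- discarded + 1L
    } else break
  }
  repeat {                                    # 3' pass to fixpoint
    live <- which(keep & offs >= start & offs < end)
    if (!length(live)) break
    last <- live[length(live)]
    if (end - 1L - offs[last] < flank) {
      end <- offs[last]
      keep[last] <- FALSE
      discarded <- discarded + 1L
    } else break
  }
  live <- which(keep & offs >= start & offs < end)
  if (!length(live))
    return(new("TrimmedLocus", locusId = locus@locusId, sequence = "",
               snps = locus@snps[0, ], keptStart = 0L, keptEnd = 0L,
               discardedSnps = discarded, removed = "no_snps"))
  snps <- locus@snps[live, , drop = FALSE]
  snps$offset <- snps$offset - start
  snps$origIndex <- live          # position of each retained SNP in the
  rownames(snps) <- NULL          # original locus's SNP (haplotype) order
  new("TrimmedLocus", locusId = locus@locusId,
      sequence = substr(locus@sequence, start + 1L, end),
      snps = snps, keptStart = start, keptEnd = end,
      discardedSnps = discarded, removed = character(0))
}

#' Template length gate
#'
#' Trimmed sequences longer than \code{maxLen} are removed (strictly
#' longer: a 150 bp template is retained, 151 bp is not).
#'
#' @param t a \linkS4class{TrimmedLocus}.
#' @param maxLen maximum template length (default 150).
#' @return \code{t}, possibly with \code{removed = "too_long"}.
#' @export
filterTemplateLength <- function(t, maxLen = 150L) {
  if (length(t@removed)) return(t)
  if (nchar(t@sequence) > maxLen)
    t@removed <- "too_long"
  t
}

#' Build per-SNP allele probes
#'
#' One probe per allele and SNP: the SNP base flanked by \code{probeFlank}
#' template nucleotides on each side (17 nt at the default 8). Any other
#' retained SNP falling inside the flank is encoded as the IUPAC degenerate
#' base covering its alleles. Probes truncated by a template edge are
#' flagged.
#'
#' @param t a kept \linkS4class{TrimmedLocus}.
#' @param probeFlank flank width in nt (default 8).
#' @param allowTruncated tolerate template-edge truncation (default FALSE:
#'   a flank shortfall is an error, since trimming guarantees the room).
#' @return data.frame (locusId, snpOffset, allele, probe, truncated).
#' @export
buildProbes <- function(t, probeFlank = 8L, allowTruncated = FALSE) {
  if (length(t@removed)) stop("cannot build probes for a removed locus")
  len <- nchar(t@sequence)
  offs <- t@snps$offset
  tmpl <- strsplit(t@sequence, "")[[1]]
  ## overlay IUPAC codes for all retained SNPs once
  overlay <- tmpl
  for (s in seq_along(offs))
    overlay[offs[s] + 1L] <- iupacCode(t@snps$alleles[[s]])
  rows <- list()
  for (s in seq_along(offs)) {
    o <- offs[s]
    from <- o - probeFlank; to <- o + probeFlank
    truncated <- from < 0L || to >= len
    if (truncated && !allowTruncated)
      stop(sprintf("SNP at offset %d of %s lacks the %d nt probe flank",
                   o, t@locusId, probeFlank))
    from <- max(from, 0L); to <- min(to, len - 1L)
    for (al in t@snps$alleles[[s]]) {
      pb <- overlay[(from:to) + 1L]
      pb[o - from + 1L] <- al
      rows[[length(rows) + 1L]] <-
        data.frame(locusId = t@locusId, snpOffset = o, allele = al,
                   probe = paste(pb, collapse = ""), truncated = truncated,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Screen a primer pair for off-target sites
#'
#' Each primer is searched as an exact full-length match on both strands of
#' every reference sequence (IUPAC-ambiguous genome bases never match). A
#' pair is off-target when either primer has at least one exact match
#' outside its own locus interval; the on-target match itself never counts.
#'
#' @param pair a \linkS4class{PrimerPair}.
#' @param genome a \code{DNAStringSet} (see
#'   \code{\link{readReferenceFasta}}).
#' @param target the pair's own locus interval:
#'   \code{list(contig=, start=, end=)}, 1-based closed coordinates on the
#'   contig (the report/reference boundary convention); matches overlapping
#'   it are on-target.
#' @return List with \code{status} ("UNIQUE"/"OFF_TARGET") and
#'   \code{sites}: data.frame (primer, contig, start, end, strand) of
#'   off-target matches.
#' @export
screenPrimerPair <- function(pair, genome, target) {
  hitsFor <- function(primer, label) {
    out <- list()
    for (ct in names(genome)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") primer else revComp(primer)
        m <- Biostrings::matchPattern(pat, genome[[ct]], fixed = TRUE)
        if (length(m))
          out[[length(out) + 1L]] <-
            data.frame(primer = label, contig = ct,
                       start = Biostrings::start(m),
                       end = Biostrings::end(m), strand = strand,
                       stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(primer = character(0), contig = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0))
  }
  hits <- rbind(hitsFor(pair@fwd, "fwd"), hitsFor(pair@rev, "rev"))
  if (!nrow(hits))
    stop("no exact match for either primer of ", pair@locusId,
         ": template/genome mismatch")
  onTarget <- hits$contig == target$contig &
    hits$end >= target$start & hits$start <= target$end
  off <- hits[!onTarget, , drop = FALSE]
  list(status = if (nrow(off)) "OFF_TARGET" else "UNIQUE", sites = off)
}

#' Select the first locus-specific primer pair
#'
#' Candidates are screened in designer rank order; the first pair whose
#' primers match only the target locus is returned. When no candidate is
#' specific (or none exists) the locus is marked removed.
#'
#' @param candidates list of \linkS4class{PrimerPair} for one locus,
#'   ordered by rank.
#' @param genome,target as in \code{\link{screenPrimerPair}}.
#' @return List with \code{pair} (or NULL), \code{removedReason} (NULL,
#'   "no_specific_pair" or "no_candidates") and \code{screens} (per-rank
#'   results).
#' @export
selectPrimerPair <- function(candidates, genome, target) {
  if (!length(candidates))
    return(list(pair = NULL, removedReason = "no_candidates",
                screens = list()))
  screens <- list()
  for (pp in candidates[order(vapply(candidates, function(p) p@rank,
                                     integer(1)))]) {
    sc <- screenPrimerPair(pp, genome, target)
    screens[[as.character(pp@rank)]] <- sc
    if (sc$status == "UNIQUE")
      return(list(pair = pp, removedReason = NULL, screens = screens))
  }
  list(pair = NULL, removedReason = "no_specific_pair", screens = screens)
}

#' Naive primer candidates from a trimmed template
#'
#' A deliberately simple candidate generator for simulation and testing:
#' candidate r uses the template's first \code{primerLen} bases shifted by
#' r-1 as the forward primer and the reverse complement of the last
#' \code{primerLen} bases as the reverse primer (the amplicon is the whole
#' remaining template). It involves no thermodynamics; real panels should
#' import designer output via \code{\link{readPrimerCandidates}}.
#'
#' @param t a kept \linkS4class{TrimmedLocus}.
#' @param nCandidates up to this many ranked candidates (default 5).
#' @param primerLen primer length (default 20).
#' @return List of \linkS4class{PrimerPair}.
#' @export
makeNaivePrimerCandidates <- function(t, nCandidates = 5L, primerLen = 20L) {
  len <- nchar(t@sequence)
  firstSnp <- if (nrow(t@snps)) min(t@snps$offset) else len
  maxShift <- min(nCandidates - 1L, max(0L, firstSnp - primerLen))
  lapply(0:maxShift, function(sh) {
    fwd <- substr(t@sequence, sh + 1L, sh + primerLen)
    rev <- revComp(substr(t@sequence, len - primerLen + 1L, len))
    new("PrimerPair", locusId = t@locusId, fwd = fwd, rev = rev,
        rank = sh + 1L, productStart = as.integer(sh),
        productEnd = as.integer(len))
  })
}

#' Read a candidate primer table
#'
#' Expected columns: \code{locus_id, rank, fwd, rev, product_start,
#' product_end} (0-based half-open product interval on the locus).
#'
#' @param path tab-delimited file (e.g. exported from a primer designer).
#' @param strict enforce the 18-25 bp primer / 100-150 bp product window.
#' @return Named list (by locus) of rank-ordered \linkS4class{PrimerPair}
#'   lists.
#' @export
readPrimerCandidates <- function(path, strict = TRUE) {
  df <- readTsvWithHeader(path)
  need <- c("locus_id", "rank", "fwd", "rev", "product_start", "product_end")
  if (!all(need %in% names(df)))
    stop("candidate table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$locus_id), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    lapply(seq_len(nrow(d)), function(i)
      PrimerPair(d$locus_id[i], d$fwd[i], d$rev[i], d$rank[i],
                 d$product_start[i], d$product_end[i], strict = strict))
  })
  out
}
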