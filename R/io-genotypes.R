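#' Read a microhaplotype genotype table or VCF
#'
#' Two input routes are supported. The tab-delimited table route carries
#' phased microhaplotype calls: columns \code{individual}, \code{collection},
#' then one column per locus holding "hap1/hap2" strings
#' (e.g. \code{"ACT/ATT"}, single-SNP loci degenerate to \code{"A/C"}) with
#' \code{"-"} for missing. The VCF route yields single-SNP loci only
#' (microhaplotypes require a phased table); 1-based VCF coordinates are
#' converted to 0-based locus ids \code{chrom_pos0} when no ID is present.
#'
#' @param path input file.
#' @param collectionMap named character vector individual -> collection
#'   (year). Required for VCF; for tables it overrides the
#'   \code{collection} column when given.
#' @param format "auto" (default, by extension), "table" or "vcf".
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, collectionMap = NULL,
                          format = c("auto", "table", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "table"
  if (format == "vcf") readGenotypesVcf(path, collectionMap)
  else readGenotypesTable(path, collectionMap)
}

readGenotypesTable <- function(path, collectionMap = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (!all(c("individual", "collection") %in% names(df)))
    stop("genotype table needs 'individual' and 'collection' columns")
  lociCols <- setdiff(names(df), c("individual", "collection"))
  inds <- df$individual
  coll <- df$collection
  if (!is.null(collectionMap)) {
    coll <- unname(collectionMap[inds])
  }
  if (any(is.na(coll) | !nzchar(coll)))
    stop("individual without a collection label: ",
         paste(inds[is.na(coll) | !nzchar(coll)], collapse = ", "))
  n <- length(inds); L <- length(lociCols)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  alleles <- vector("list", L); names(alleles) <- lociCols
  for (j in seq_len(L)) {
    v <- df[[lociCols[j]]]
    miss <- is.na(v) | v == MISSING_CALL | v == "" | v == "./."
    bad <- !miss & !grepl("^[ACGTacgt]+/[ACGTacgt]+$", v)
    if (any(bad))
      stop(sprintf("unknown allele code '%s' at line %d, locus %s",
                   v[which(bad)[1]], which(bad)[1] + 1L, lociCols[j]))
    parts <- strsplit(toupper(v[!miss]), "/", fixed = TRUE)
    h1 <- vapply(parts, `[`, character(1), 1L)
    h2 <- vapply(parts, `[`, character(1), 2L)
    cat_j <- sort(unique(c(h1, h2)))
    if (length(unique(nchar(cat_j))) > 1L)
      stop("haplotype alleles of locus ", lociCols[j], " differ in length")
    alleles[[j]] <- cat_j
    a1[!miss, j] <- match(h1, cat_j)
    a2[!miss, j] <- match(h2, cat_j)
  }
  GenotypeMatrix(a1, a2, alleles, coll, individuals = inds, loci = lociCols)
}

readGenotypesVcf <- function(path, collectionMap) {
  if (is.null(collectionMap))
    stop("collectionMap is required when reading genotypes from VCF")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  inds <- colnames(gt)
  coll <- unname(collectionMap[inds])
  if (any(is.na(coll)))
    stop("individual without a collection label: ",
         paste(inds[is.na(coll)], collapse = ", "))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ## 1-based VCF POS -> 0-based internal offset in the generated id
  ids[noid] <- paste0(fix[noid, "CHROM"], "_",
                      as.integer(fix[noid, "POS"]) - 1L)
  L <- nrow(gt); n <- length(inds)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  alleles <- vector("list", L); names(alleles) <- ids
  for (j in seq_len(L)) {
    cat_j <- toupper(c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",")[[1]]))
    cat_j <- cat_j[!is.na(cat_j) & nzchar(cat_j) & cat_j != "."]
    ord <- order(cat_j)
    v <- gt[j, ]
    miss <- is.na(v) | v %in% c("./.", ".|.", ".")
    parts <- strsplit(v[!miss], "[/|]")
    g1 <- as.integer(vapply(parts, `[`, character(1), 1L)) + 1L
    g2 <- as.integer(vapply(parts, `[`, character(1), 2L)) + 1L
    if (any(g1 > length(cat_j) | g2 > length(cat_j), na.rm = TRUE))
      stop("GT allele index beyond ALT alleles at record ", ids[j])
    alleles[[j]] <- cat_j[ord]
    a1[!miss, j] <- match(cat_j[g1], cat_j[ord])
    a2[!miss, j] <- match(cat_j[g2], cat_j[ord])
  }
  GenotypeMatrix(a1, a2, alleles, coll, individuals = inds, loci = ids)
}

#' Write a genotype table
#'
#' Serializes a \linkS4class{GenotypeMatrix} in the tab-delimited dialect
#' read back by \code{\link{readGenotypes}} (lossless round trip).
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gm, path) {
  cs <- callStrings(gm)
  df <- data.frame(individual = individuals(gm),
                   collection = collections(gm),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(cs, check.names = FALSE,
                                stringsAsFactors = FALSE))
  writeTsvWithHeader(df, path, "genotypes")
}

#' Build a GenotypeMatrix from call strings
#'
#' Convenience constructor used heavily in simulations and tests: takes a
#' character matrix of "hap1/hap2" calls (\code{"-"} or NA = missing).
#'
#' @param calls character matrix, individuals x loci.
#' @param collections per-individual collection labels.
#' @param alleles optional named list of locus catalogues; inferred from the
#'   observed calls when NULL.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
gtFromCalls <- function(calls, collections, alleles = NULL) {
  n <- nrow(calls); L <- ncol(calls)
  loci <- colnames(calls) %||% paste0("loc", seq_len(L))
  a1 <- a2 <- matrix(NA_integer_, n, L)
  catal <- vector("list", L); names(catal) <- loci
  for (j in seq_len(L)) {
    v <- calls[, j]
    miss <- is.na(v) | v == MISSING_CALL
    parts <- strsplit(toupper(v[!miss]), "/", fixed = TRUE)
    h1 <- vapply(parts, `[`, character(1), 1L)
    h2 <- vapply(parts, `[`, character(1), 2L)
    cat_j <- if (!is.null(alleles)) alleles[[loci[j]]]
             else sort(unique(c(h1, h2)))
    catal[[j]] <- cat_j
    a1[!miss, j] <- match(h1, cat_j)
    a2[!miss, j] <- match(h2, cat_j)
  }
  GenotypeMatrix(a1, a2, catal, collections,
                 individuals = rownames(calls) %||% paste0("ind", seq_len(n)),
                 loci = loci)
}

#' Read a reference FASTA
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet}, case-normalized to uppercase, retrievable
#'   by sequence name; duplicate names are an error.
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(x))
}
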