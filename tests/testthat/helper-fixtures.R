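suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## uniform fragment library on a single-chromosome toy genome
mkUniformLib <- function(n, genomeLen = 1e5, chrom = "chr1",
                         role = "chip", fragSize = 300L) {
  si <- GenomeInfoDb::Seqinfo(chrom, genomeLen)
  p5 <- sample.int(genomeLen, n, replace = TRUE)
  str <- sample(c("+", "-"), n, replace = TRUE)
  s <- ifelse(str == "+", p5, p5 - fragSize + 1L)
  e <- ifelse(str == "+", p5 + fragSize - 1L, p5)
  gr <- GRanges(chrom, IRanges(pmax(s, 1L), pmin(e, genomeLen)),
                strand = str, seqinfo = si)
  new("FragmentLibrary", label = libraryLabel("C", 0, 1, role),
      fragments = sort(gr))
}

## fragment library with + strand fragments fully inside [st, st+w-1]
mkImplantLib <- function(bg, st, w, nExtra, genomeLen = 1e5,
                         chrom = "chr1", fragSize = 300L) {
  si <- GenomeInfoDb::Seqinfo(chrom, genomeLen)
  p5 <- sample(st:(st + w - fragSize), nExtra, replace = TRUE)
  extra <- GRanges(chrom, IRanges(p5, p5 + fragSize - 1L), strand = "+",
                   seqinfo = si)
  new("FragmentLibrary", label = bg@label,
      fragments = sort(c(bg@fragments, extra)))
}

## window track built by hand (counts + lambda), for eligibility tests
mkTrack <- function(counts, lambda, W = 200L, chrom = "chr1") {
  n <- length(counts)
  si <- GenomeInfoDb::Seqinfo(chrom, n * W)
  gr <- GRanges(chrom, IRanges(seq(1L, by = W, length.out = n), width = W),
                seqinfo = si)
  mcols(gr)$count <- as.integer(counts)
  mcols(gr)$lambda <- rep_len(lambda, n)
  metadata(gr) <- list(librarySize = sum(counts), windowBp = W,
                       lambdaWindow = lambda[1])
  gr
}

## minimal GeneAnnotation built directly
mkAnnotation <- function(genomeLen = 100000, genes, features = NULL,
                         repeats = NULL, chrom = "chr1") {
  si <- GenomeInfoDb::Seqinfo(chrom, genomeLen)
  g <- GRanges(chrom, IRanges(genes$start, genes$end),
               strand = genes$strand, seqinfo = si)
  mcols(g)$gene_id <- genes$gene_id
  mcols(g)$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  mcols(g)$tes <- ifelse(genes$strand == "-", genes$start, genes$end)
  f <- if (is.null(features)) {
    empty <- GRanges(seqinfo = si)
    mcols(empty) <- DataFrame(type = character(0), gene_id = character(0))
    empty
  } else {
    x <- GRanges(chrom, IRanges(features$start, features$end),
                 strand = features$strand, seqinfo = si)
    mcols(x)$type <- features$type
    mcols(x)$gene_id <- features$gene_id
    x
  }
  r <- if (is.null(repeats)) GRanges(seqinfo = si) else
    GRanges(chrom, IRanges(repeats$start, repeats$end), seqinfo = si)
  new("GeneAnnotation", genes = sort(g), features = sort(f),
      repeats = sort(r))
}

## directly-assembled region universe from a membership matrix
mkUniverse <- function(isDiff, direction = NULL, regionWidth = 1000L) {
  n <- nrow(isDiff)
  si <- GenomeInfoDb::Seqinfo("chr1", (n + 1L) * 2L * regionWidth)
  regions <- GRanges("chr1",
                     IRanges(seq(1L, by = 2L * regionWidth,
                                 length.out = n),
                             width = regionWidth), seqinfo = si)
  if (is.null(direction)) direction <- ifelse(isDiff, 1L, 0L)
  storage.mode(direction) <- "integer"
  colnames(direction) <- colnames(isDiff)
  new("RegionUniverse", regions = regions, isDiff = isDiff,
      direction = direction)
}

## contrast:timepoint key, as used by the classifier
ctKey <- function(A, B, tp) sprintf("%s.%s:%g", A, B, tp)

## Printed feature-class counts of the study's three contrasts
TABLE2 <- list(
  "DT.C" = c(five_prime_UTR = 327, CDS = 720, upstream = 465,
             intron = 435, three_prime_UTR = 45, downstream = 384,
             "repeat" = 4028, intergenic = 938),
  "DTHT.C" = c(five_prime_UTR = 326, CDS = 947, upstream = 345,
               intron = 352, three_prime_UTR = 27, downstream = 309,
               "repeat" = 3446, intergenic = 758),
  "DTHT.DT" = c(five_prime_UTR = 485, CDS = 995, upstream = 590,
                intron = 437, three_prime_UTR = 56, downstream = 452,
                "repeat" = 4312, intergenic = 1209))
TABLE2_TOTALS <- c("DT.C" = 7342, "DTHT.C" = 6510, "DTHT.DT" = 8536)
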