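## Feature classification, Table-style summaries, TSS distances and
## metaprofiles, peak-gene overlap, per-chromosome density, hypergeometric
## enrichment, and MapMan export.

FEATURE_LEVELS <- c("five_prime_UTR", "CDS", "upstream", "intron",
                    "three_prime_UTR", "downstream", "repeat", "intergenic")

.midpoints <- function(peaks)
  GRanges(seqnames(peaks),
          IRanges(floor((start(peaks) + end(peaks)) / 2), width = 1L),
          seqinfo = seqinfo(peaks))

## strand-aware flank intervals per gene: upstream within flank of the TSS,
## downstream within flank past the TES
.flankRanges <- function(ann, flankBp, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  g <- ann@genes
  str <- as.character(strand(g))
  tss <- mcols(g)$tss; tes <- mcols(g)$tes
  if (side == "upstream") {
    s <- ifelse(str == "-", tss + 1L, tss - flankBp)
    e <- ifelse(str == "-", tss + flankBp, tss - 1L)
  } else {
    s <- ifelse(str == "-", tes - flankBp, tes + 1L)
    e <- ifelse(str == "-", tes - 1L, tes + flankBp)
  }
  sl <- seqlengths(g)[as.character(seqnames(g))]
  s <- pmax(s, 1L); e <- pmin(e, sl)
  keep <- s <= e
  GRanges(seqnames(g)[keep], IRanges(s[keep], e[keep]),
          strand = str[keep], seqinfo = seqinfo(g),
          gene_id = mcols(g)$gene_id[keep])
}

#' Classify peaks by genomic feature
#'
#' Each peak's midpoint is tested against the annotation in a fixed
#' precedence order: 5'-UTR > CDS > 3'-UTR > intron > upstream (within
#' \code{flankBp} of a TSS, strand-aware) > downstream (within
#' \code{flankBp} past a TES, strand-aware) > repeat > intergenic. The
#' first hit wins, so every peak receives exactly one label.
#'
#' @param peaks a \code{GRanges} of peaks/regions.
#' @param ann a \linkS4class{GeneAnnotation}.
#' @param flankBp flank width in bp (default 2000).
#' @return Factor of feature labels, one per peak, with levels in
#'   precedence order.
#' @export
classifyFeature <- function(peaks, ann, flankBp = 2000L) {
  flankBp <- as.integer(flankBp)
  mids <- .midpoints(peaks)
  unknown <- !as.character(seqnames(mids)) %in%
    seqnames(seqinfo(ann@genes))
  if (any(unknown))
    stop("peak midpoint on unknown chromosome: ",
         as.character(seqnames(mids))[which(unknown)[1]])
  lab <- rep(NA_character_, length(mids))
  hitType <- function(targets) overlapsAny(mids, targets, minoverlap = 1L)
  feat <- ann@features
  for (tp in c("five_prime_UTR", "CDS", "three_prime_UTR", "intron")) {
    sel <- is.na(lab) & hitType(feat[mcols(feat)$type == tp])
    lab[sel] <- tp
  }
  sel <- is.na(lab) & hitType(.flankRanges(ann, flankBp, "upstream"))
  lab[sel] <- "upstream"
  sel <- is.na(lab) & hitType(.flankRanges(ann, flankBp, "downstream"))
  lab[sel] <- "downstream"
  sel <- is.na(lab) & hitType(ann@repeats)
  lab[sel] <- "repeat"
  lab[is.na(lab)] <- "intergenic"
  factor(lab, levels = FEATURE_LEVELS)
}

#' Summarize feature labels
#'
#' Counts and percentages (2 decimal places, 100 * count / total) per
#' feature class, in the conventional row order.
#'
#' @param labels factor (or character) of feature labels, or a named
#'   numeric vector of per-class counts.
#' @return A data.frame with columns \code{feature}, \code{count},
#'   \code{percent}; counts sum to the total and percentages to 100 up to
#'   rounding.
#' @examples
#' summarizeFeatures(c(CDS = 720, "intergenic" = 280))
#' @export
summarizeFeatures <- function(labels) {
  if (is.numeric(labels)) {
    cnt <- stats::setNames(rep(0, length(FEATURE_LEVELS)), FEATURE_LEVELS)
    nm <- sub("^repeat\\.$", "repeat", names(labels))
    bad <- setdiff(nm, FEATURE_LEVELS)
    if (length(bad)) stop("unknown feature label(s): ",
                          paste(bad, collapse = ", "))
    cnt[nm] <- labels
  } else {
    if (!length(labels)) stop("no labels to summarize")
    labels <- factor(as.character(labels), levels = FEATURE_LEVELS)
    if (anyNA(labels)) stop("unknown feature label(s)")
    cnt <- table(labels)
  }
  total <- sum(cnt)
  if (total == 0) stop("no labels to summarize")
  data.frame(feature = FEATURE_LEVELS,
             count = as.numeric(cnt),
             percent = round(100 * as.numeric(cnt) / total, 2),
             row.names = NULL)
}

#' Signed distance from peak midpoints to the nearest TSS
#'
#' For each peak, the nearest TSS on the same chromosome is found and the
#' distance from the peak midpoint is signed in transcription orientation:
#' positive downstream of the TSS (into the gene), negative upstream. Ties
#' between equidistant genes break to the lexicographically smaller gene
#' id; peaks on chromosomes without genes get \code{NA}.
#'
#' @param peaks a \code{GRanges}.
#' @param ann a \linkS4class{GeneAnnotation}.
#' @return A data.frame with columns \code{gene_id} and \code{distance}.
#' @export
nearestTssDistance <- function(peaks, ann) {
  if (!length(ann@genes)) stop("annotation contains no genes")
  mids <- .midpoints(peaks)
  g <- ann@genes
  out <- data.frame(gene_id = rep(NA_character_, length(mids)),
                    distance = rep(NA_real_, length(mids)))
  for (chr in unique(as.character(seqnames(mids)))) {
    gi <- which(as.character(seqnames(g)) == chr)
    pi <- which(as.character(seqnames(mids)) == chr)
    if (!length(gi) || !length(pi)) next
    ord <- gi[order(mcols(g)$tss[gi], mcols(g)$gene_id[gi])]
    tss <- mcols(g)$tss[ord]
    for (p in pi) {
      m <- start(mids)[p]
      d <- abs(tss - m)
      cand <- which(d == min(d))
      # equidistant genes: lexicographically smaller id wins
      best <- ord[cand[order(mcols(g)$gene_id[ord[cand]])][1]]
      signedDist <- if (as.character(strand(g))[best] == "-")
        mcols(g)$tss[best] - m else m - mcols(g)$tss[best]
      out$gene_id[p] <- mcols(g)$gene_id[best]
      out$distance[p] <- signedDist
    }
  }
  out
}

#' TSS metaprofile
#'
#' Fragment coverage in orientation-aligned bins around every TSS,
#' averaged over genes and scaled to fragments per million: bin i covers
#' [TSS + offset, TSS + offset + binBp) in each gene's transcription
#' orientation, offsets running from -flankBp to +flankBp.
#'
#' @param frags a \linkS4class{FragmentLibrary}.
#' @param ann a \linkS4class{GeneAnnotation}.
#' @param flankBp profile half-width in bp (default 2000); must be a
#'   multiple of \code{binBp}.
#' @param binBp bin width in bp (default 100).
#' @return A data.frame with columns \code{offset} (signed bp of the bin
#'   start relative to the TSS) and \code{rpm} (mean fragments per million
#'   per gene).
#' @export
tssMetaprofile <- function(frags, ann, flankBp = 2000L, binBp = 100L) {
  flankBp <- as.integer(flankBp); binBp <- as.integer(binBp)
  if (flankBp %% binBp != 0L) stop("flankBp must be a multiple of binBp")
  if (!length(ann@genes)) stop("annotation contains no genes")
  g <- ann@genes
  nBins <- 2L * flankBp %/% binBp
  offsets <- seq.int(-flankBp, flankBp - binBp, by = binBp)
  str <- as.character(strand(g))
  tss <- mcols(g)$tss
  # absolute bin starts, orientation-aligned: for "-" genes bin i runs
  # from tss - offset downwards
  counts <- matrix(0, length(g), nBins)
  fr <- frags@fragments
  for (i in seq_len(nBins)) {
    s <- ifelse(str == "-", tss - offsets[i] - binBp + 1L, tss + offsets[i])
    e <- s + binBp - 1L
    valid <- which(s >= 1L &
                   e <= seqlengths(g)[as.character(seqnames(g))])
    if (!length(valid)) next
    bins <- GRanges(seqnames(g)[valid], IRanges(s[valid], e[valid]),
                    seqinfo = seqinfo(g))
    counts[valid, i] <- countOverlaps(bins, fr, minoverlap = 1L)
  }
  n <- length(fr)
  rpm <- colMeans(counts) * 1e6 / max(n, 1L)
  data.frame(offset = offsets, rpm = rpm)
}

#' Overlap responsive regions with flanked genes
#'
#' Links every region to every gene whose interval, extended by
#' \code{flankBp} on both sides, overlaps it by at least 1 bp.
#' Many-to-many links are allowed, so the distinct region and gene counts
#' are reported separately (two regions over one gene give 2 links, 2
#' regions, 1 gene).
#'
#' @param regions a \linkS4class{ResponsiveSet} or a \code{GRanges}.
#' @param ann a \linkS4class{GeneAnnotation}.
#' @param flankBp flank width in bp (default 2000).
#' @return A list with \code{links} (data.frame: region index, region
#'   coordinates, gene_id, plus direction/pvalue columns when present on
#'   the regions), \code{nRegions} and \code{nGenes} (distinct counts).
#' @export
overlapWithGenes <- function(regions, ann, flankBp = 2000L) {
  flankBp <- as.integer(flankBp)
  gr <- if (is(regions, "ResponsiveSet")) regions@regions else regions
  g <- ann@genes
  sl <- seqlengths(g)[as.character(seqnames(g))]
  ext <- GRanges(seqnames(g),
                 IRanges(pmax(start(g) - flankBp, 1L),
                         pmin(end(g) + flankBp, sl)),
                 seqinfo = seqinfo(g))
  hits <- findOverlaps(gr, ext, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  links <- data.frame(region = qh,
                      chrom = as.character(seqnames(gr))[qh],
                      start = start(gr)[qh], end = end(gr)[qh],
                      gene_id = mcols(g)$gene_id[sh],
                      stringsAsFactors = FALSE)
  for (col in c("direction", "pvalue"))
    if (col %in% names(mcols(gr))) links[[col]] <- mcols(gr)[[col]][qh]
  list(links = links, nRegions = length(unique(qh)),
       nGenes = length(unique(links$gene_id)))
}

#' Per-chromosome peak density
#'
#' Peaks per megabase for each chromosome, with the ratio of each
#' chromosome's density to the genome-wide density.
#'
#' @param peaks a \code{GRanges} (or \linkS4class{ResponsiveSet}).
#' @param genome named vector of chromosome lengths.
#' @return A data.frame with columns \code{chrom}, \code{lengthMb},
#'   \code{count}, \code{density} (peaks/Mb) and \code{ratio}.
#' @export
chromosomeDensity <- function(peaks, genome) {
  if (is(peaks, "ResponsiveSet")) peaks <- peaks@regions
  sl <- .genomeLengths(genome)
  cnt <- table(factor(as.character(seqnames(peaks)), levels = names(sl)))
  lenMb <- sl / 1e6
  density <- as.numeric(cnt) / lenMb
  genomeDensity <- length(peaks) / sum(lenMb)
  data.frame(chrom = names(sl), lengthMb = as.numeric(lenMb),
             count = as.numeric(cnt), density = density,
             ratio = if (genomeDensity > 0) density / genomeDensity
                     else rep(0, length(sl)),
             row.names = NULL)
}

#' Hypergeometric term enrichment
#'
#' For every term, tests over-representation of the study set in the
#' term's genes by the hypergeometric upper tail (probability of at least
#' the observed number of study hits), with Benjamini-Hochberg adjustment
#' across terms. Fold enrichment is (study hits / study size) /
#' (population hits / population size); a row is significant iff adjusted
#' p < 0.05 and fold > 1.3 (both conditions required).
#'
#' @param study character vector of study gene ids (must be a subset of
#'   \code{population}).
#' @param population character vector of population gene ids.
#' @param termMap named list mapping term id to a character vector of gene
#'   ids (intersected with the population).
#' @return A data.frame with columns \code{term}, \code{studyHits},
#'   \code{studySize}, \code{popHits}, \code{popSize}, \code{fold},
#'   \code{pvalue}, \code{padj}, \code{significant}.
#' @export
hypergeomEnrichment <- function(study, population, termMap) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    stop("study set must be a subset of the population")
  n <- length(study); N <- length(population)
  rows <- lapply(names(termMap), function(term) {
    termGenes <- intersect(unique(termMap[[term]]), population)
    K <- length(termGenes)
    k <- length(intersect(study, termGenes))
    fold <- if (k == 0 || K == 0) 0 else (k / n) / (K / N)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, studyHits = k, studySize = n, popHits = K,
               popSize = N, fold = fold, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$padj < 0.05 & out$fold > 1.3
  out[order(out$pvalue), , drop = FALSE]
}

#' MapMan-style gene-by-class response matrix
#'
#' Builds the {0, 1, -1} experiment encoding: a gene scores 1 in a class
#' when linked to at least one responsive region with direction +1 there,
#' -1 when linked only to loss regions, and 0 when unlinked. A gene linked
#' to regions of both directions takes the direction of the smallest-p
#' region.
#'
#' @param linksByClass named list (class -> \code{links} data.frame from
#'   [overlapWithGenes()], which must carry \code{direction} and
#'   \code{pvalue} columns).
#' @param genes character vector of all gene ids to report (rows).
#' @return A data.frame with column \code{gene_id} plus one integer column
#'   per class.
#' @export
mapmanExport <- function(linksByClass, genes) {
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cls in names(linksByClass)) {
    links <- linksByClass[[cls]]
    val <- stats::setNames(rep(0L, length(genes)), genes)
    if (nrow(links)) {
      if (!all(c("direction", "pvalue") %in% names(links)))
        stop("links must carry direction and pvalue columns")
      byGene <- split(seq_len(nrow(links)), links$gene_id)
      for (gid in names(byGene)) {
        i <- byGene[[gid]]
        dirs <- unique(links$direction[i])
        val[gid] <- if (length(dirs) == 1L) as.integer(dirs) else
          as.integer(links$direction[i][which.min(links$pvalue[i])])
      }
    }
    out[[cls]] <- as.integer(val[out$gene_id])
  }
  out
}

#' Write the MapMan experiment file
#'
#' Two-column text per class (gene identifier, value in {0, 1, -1}) as
#' consumed by MapMan's experiment loader.
#'
#' @param mm data.frame from [mapmanExport()].
#' @param dir output directory; one file per class column is written.
#' @return Paths of the written files, invisibly.
#' @export
writeMapman <- function(mm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  classes <- setdiff(names(mm), "gene_id")
  paths <- vapply(classes, function(cls) {
    p <- file.path(dir, paste0("mapman_", cls, ".txt"))
    utils::write.table(mm[, c("gene_id", cls)], p, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = c("IDENTIFIER", "VALUE"))
    p
  }, character(1))
  invisible(paths)
}
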