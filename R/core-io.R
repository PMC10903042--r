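## Readers/writers for BED and GFF3, read deduplication and fragment
## extension. Internal coordinates are GRanges (1-based, closed); BED's
## 0-based half-open convention is converted by rtracklayer on I/O.

.asSeqinfo <- function(genome) {
  if (is(genome, "Seqinfo")) return(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named vector of chromosome lengths")
  Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome))
}

.genomeLengths <- function(genome) {
  si <- .asSeqinfo(genome)
  stats::setNames(as.numeric(seqlengths(si)), seqnames(si))
}

#' Read aligned reads from a BED file
#'
#' Each BED record is reduced to its strand-aware 5' end: the leftmost base
#' for \code{+} reads, the rightmost for \code{-} reads. Requires BED6
#' (strand in column 6); records on chromosomes absent from \code{genome}
#' are a hard error, as they indicate a genome/annotation mismatch.
#'
#' @param path BED file (>= 6 columns).
#' @param genome named vector of chromosome lengths (bp).
#' @param label a \linkS4class{LibraryLabel} for the library.
#' @return A \linkS4class{ReadLibrary}; the read count equals the record
#'   count.
#' @seealso [writeReadsBed()] for the inverse, [extendReads()] for fragment
#'   extension.
#' @export
readBedReads <- function(path, genome, label = libraryLabel("C", 0, 1)) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  si <- .asSeqinfo(genome)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  nf <- lengths(strsplit(lines, "[ \t]+"))
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1]
    if (nf[bad] >= 3L)
      stop("BED record at line ", bad, " has no strand column; ",
           "6-column BED (chrom, start, end, name, score, strand) required")
    stop("malformed BED record at line ", bad)
  }
  gr <- rtracklayer::import(path, format = "BED")
  unknown <- !as.character(seqnames(gr)) %in% seqnames(si)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("BED record ", i, " is on chromosome '",
         as.character(seqnames(gr))[i], "', absent from the genome map")
  }
  str <- as.character(strand(gr))
  if (any(str == "*"))
    stop("BED record ", which(str == "*")[1], " has strand '.'; ",
         "6-column BED with +/- strand required")
  pos <- ifelse(str == "+", start(gr), end(gr))
  reads <- GRanges(seqnames(gr), IRanges(pos, width = 1L), strand = str,
                   seqinfo = si)
  new("ReadLibrary", label = label, reads = sort(reads))
}

#' Write 5' read positions to BED6
#'
#' Inverse of [readBedReads()]: re-reading the emitted file reproduces the
#' same positions and strands.
#'
#' @param lib a \linkS4class{ReadLibrary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReadsBed <- function(lib, path) {
  gr <- lib@reads
  mcols(gr)$name <- sprintf("read%d", seq_along(gr))
  mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one representative model per gene (the longest mRNA when several
#' are annotated), converts coordinates to the internal convention, derives
#' introns as the gaps between exons, and sets TSS/TES by strand (TSS is
#' the gene start on \code{+}, the gene end on \code{-}).
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS/five_prime_UTR/
#'   three_prime_UTR records (1-based closed coordinates).
#' @param repeats optional BED file of repeat intervals (BED3 suffices).
#' @param genome optional named vector of chromosome lengths; when missing,
#'   lengths are taken from the GFF3 header or feature extents.
#' @return A \linkS4class{GeneAnnotation}. Child features whose gene parent
#'   cannot be resolved are skipped with a warning.
#' @export
readGff3Genes <- function(path, repeats = NULL, genome = NULL) {
  if (!file.exists(path)) stop("no such GFF3 file: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  if (!is.null(genome)) {
    si <- .asSeqinfo(genome)
    gff <- GRanges(seqnames(gff), IRanges(start(gff), end(gff)),
                   strand = strand(gff), seqinfo = si,
                   type = mcols(gff)$type, ID = mcols(gff)$ID,
                   Parent = mcols(gff)$Parent)
  }
  type <- as.character(mcols(gff)$type)
  ids <- as.character(mcols(gff)$ID)
  parent <- vapply(mcols(gff)$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  geneRows <- which(type == "gene")
  if (!length(geneRows)) stop("GFF3 contains no gene records")
  geneIds <- ids[geneRows]
  mrnaRows <- which(type %in% c("mRNA", "transcript"))
  mrnaGene <- parent[mrnaRows]
  orphanM <- mrnaRows[!mrnaGene %in% geneIds]
  if (length(orphanM)) {
    warning(length(orphanM), " mRNA record(s) without a resolvable gene ",
            "parent were skipped")
    keep <- mrnaGene %in% geneIds
    mrnaRows <- mrnaRows[keep]; mrnaGene <- mrnaGene[keep]
  }
  # representative = longest mRNA per gene
  mw <- width(gff)[mrnaRows]
  repIdx <- vapply(split(seq_along(mrnaRows), mrnaGene), function(i)
    i[which.max(mw[i])], integer(1))
  repMrna <- stats::setNames(ids[mrnaRows][repIdx], names(repIdx))

  childRows <- which(type %in% c("exon", "CDS", "five_prime_UTR",
                                 "three_prime_UTR"))
  childParent <- parent[childRows]
  known <- childParent %in% ids[mrnaRows] | childParent %in% geneIds
  if (any(!known)) {
    warning(sum(!known), " sub-feature(s) without a resolvable gene parent ",
            "were skipped")
    childRows <- childRows[known]; childParent <- childParent[known]
  }
  # map each child to its gene via its (kept) mRNA, or directly
  mrnaToGene <- stats::setNames(mrnaGene, ids[mrnaRows])
  childGene <- ifelse(childParent %in% names(mrnaToGene),
                      mrnaToGene[childParent], childParent)
  # keep only children of the representative mRNA (or direct gene children)
  keepChild <- !childParent %in% names(mrnaToGene) |
    childParent == repMrna[childGene]
  childRows <- childRows[keepChild]
  childGene <- childGene[keepChild]
  childType <- type[childRows]

  featL <- list()
  for (tp in c("five_prime_UTR", "CDS", "three_prime_UTR")) {
    sel <- childType == tp
    if (any(sel)) {
      f <- granges(gff[childRows[sel]])
      mcols(f)$type <- tp
      mcols(f)$gene_id <- childGene[sel]
      featL[[tp]] <- f
    }
  }
  # introns: gaps between exons of the representative model
  exSel <- childType == "exon"
  if (any(exSel)) {
    exons <- granges(gff[childRows[exSel]])
    mcols(exons)$gene_id <- childGene[exSel]
    intrL <- lapply(split(exons, mcols(exons)$gene_id), function(ex) {
      ex <- sort(ex)
      if (length(ex) < 2L) return(GRanges(seqinfo = seqinfo(ex)))
      g <- GRanges(seqnames(ex)[-1],
                   IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L),
                   strand = strand(ex)[-1], seqinfo = seqinfo(ex))
      g[width(g) > 0L]
    })
    gid <- rep(names(intrL), vapply(intrL, length, integer(1)))
    intr <- unlist(GenomicRanges::GRangesList(intrL), use.names = FALSE)
    names(intr) <- NULL
    if (length(intr)) {
      mcols(intr)$type <- "intron"
      mcols(intr)$gene_id <- gid
      featL[["intron"]] <- intr
    }
  }
  features <- if (length(featL))
    sort(do.call(c, unname(featL))) else {
    empty <- GRanges(seqinfo = seqinfo(gff))
    mcols(empty) <- DataFrame(type = character(0), gene_id = character(0))
    empty
  }

  genes <- granges(gff[geneRows])
  str <- as.character(strand(genes))
  mcols(genes)$gene_id <- geneIds
  mcols(genes)$tss <- ifelse(str == "-", end(genes), start(genes))
  mcols(genes)$tes <- ifelse(str == "-", start(genes), end(genes))
  genes <- sort(genes)

  reps <- if (is.null(repeats)) GRanges(seqinfo = seqinfo(gff)) else {
    r <- rtracklayer::import(repeats, format = "BED")
    GRanges(seqnames(r), IRanges(start(r), end(r)), seqinfo = seqinfo(gff))
  }
  new("GeneAnnotation", genes = genes, features = features, repeats = reps)
}

#' Remove redundant reads
#'
#' Keeps at most \code{threshold} reads per (chromosome, 5' position,
#' strand), the redundancy rule applied before island calling. The result
#' is independent of input order, and the operation is idempotent.
#'
#' @param lib a \linkS4class{ReadLibrary}.
#' @param threshold maximum retained duplicates (default 1).
#' @return A deduplicated \linkS4class{ReadLibrary}.
#' @export
deduplicateReads <- function(lib, threshold = 1L) {
  threshold <- as.integer(threshold)
  if (threshold < 1L) stop("redundancy threshold must be >= 1")
  gr <- sort(lib@reads)
  if (length(gr) > 1L) {
    key <- paste(as.character(seqnames(gr)), start(gr),
                 as.character(strand(gr)))
    occ <- stats::ave(rep(1L, length(gr)), key, FUN = seq_along)
    gr <- gr[occ <= threshold]
  }
  new("ReadLibrary", label = lib@label, reads = gr)
}

#' Extend reads to fragment size
#'
#' A \code{+} read at position p becomes the interval covering
#' [p, p+size-1]; a \code{-} read at p becomes [p-size+1, p]. Fragments are
#' clipped at chromosome edges; the fragment count always equals the read
#' count.
#'
#' @param lib a \linkS4class{ReadLibrary}.
#' @param fragmentSize fragment length in bp (default 300).
#' @return A \linkS4class{FragmentLibrary}.
#' @export
extendReads <- function(lib, fragmentSize = 300L) {
  fragmentSize <- as.integer(fragmentSize)
  if (fragmentSize < 1L) stop("fragmentSize must be >= 1")
  gr <- lib@reads
  str <- as.character(strand(gr))
  s <- ifelse(str == "+", start(gr), start(gr) - fragmentSize + 1L)
  e <- ifelse(str == "+", start(gr) + fragmentSize - 1L, start(gr))
  sl <- seqlengths(gr)[as.character(seqnames(gr))]
  s <- pmax(s, 1L)
  e <- pmin(e, sl)
  frags <- GRanges(seqnames(gr), IRanges(s, e), strand = str,
                   seqinfo = seqinfo(gr))
  new("FragmentLibrary", label = lib@label, fragments = sort(frags))
}

#' Read a sample manifest
#'
#' The manifest is a TSV with columns \code{path}, \code{condition},
#' \code{timepoint}, \code{replicate}, \code{role} that maps each BED file
#' to its place in the design.
#'
#' @param path manifest TSV.
#' @param baseDir directory against which relative \code{path} entries are
#'   resolved (defaults to the manifest's directory).
#' @return A data.frame with the five columns above.
#' @export
readManifest <- function(path, baseDir = dirname(path)) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("path", "condition", "timepoint", "replicate", "role")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  rel <- !grepl("^/", m$path)
  m$path[rel] <- file.path(baseDir, m$path[rel])
  m
}

#' Load all libraries of an experiment
#'
#' Reads every BED file named in a manifest, deduplicates and extends
#' reads, and returns the fragment libraries keyed by label.
#'
#' @param manifest data.frame from [readManifest()].
#' @param genome named vector of chromosome lengths.
#' @param config a \linkS4class{MarkConfig}.
#' @return Named list of \linkS4class{FragmentLibrary} (names are
#'   \code{condition_timepoint_replicate_role}).
#' @export
loadExperiment <- function(manifest, genome, config = markConfig()) {
  libs <- lapply(seq_len(nrow(manifest)), function(i) {
    lab <- libraryLabel(manifest$condition[i],
                        manifest$timepoint[i],
                        manifest$replicate[i],
                        manifest$role[i])
    rl <- readBedReads(manifest$path[i], genome, lab)
    rl <- deduplicateReads(rl, config@redundancyThreshold)
    extendReads(rl, config@fragmentSizeBp)
  })
  names(libs) <- vapply(libs, function(x) .labelString(x@label), character(1))
  if (anyDuplicated(names(libs)))
    stop("duplicate (condition, timepoint, replicate, role) in manifest")
  libs
}

## BED6+ writer shared by island/peak/region exporters
.writeBed6Plus <- function(gr, path, names, scores, strands = ".", extra = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = names, score = scores, strand = strands,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pool fragment libraries
#'
#' Concatenates the fragments of several libraries (e.g. the replicates of
#' one condition at one time point) into a single library for group-level
#' counting.
#'
#' @param libs list of \linkS4class{FragmentLibrary}.
#' @param label optional \linkS4class{LibraryLabel} for the pool (defaults
#'   to the first library's label).
#' @return A \linkS4class{FragmentLibrary}.
#' @export
poolFragments <- function(libs, label = NULL) {
  if (!length(libs)) stop("no libraries to pool")
  frags <- sort(do.call(c, unname(lapply(libs, function(x) x@fragments))))
  if (is.null(label)) label <- libs[[1]]@label
  new("FragmentLibrary", label = label, fragments = frags)
}
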