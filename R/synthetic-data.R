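## Synthetic experiment generator. Emulates the factorial study design
## (3 conditions x 6 time points x 3 replicates plus per-condition input
## controls) on a toy genome: uniform Poisson background fragments in
## every library, plus implanted enrichment islands whose fragment rate is
## multiplied when the island's effect class is active for the library's
## condition and time point. Heat is imposed after 72 h of drought, so
## heat-effect islands act only in the combined arm and only from 96 h on.

#' Ground-truth specification for the synthetic experiment
#'
#' Defines the toy genome, the gene/repeat annotation, the background
#' fragment rate, and the implanted islands. Islands are placed at the TSS
#' of randomly chosen genes (interval [TSS, TSS + width) in transcription
#' orientation). Defaults are the package's standard study conditions:
#' 2 x 500 kb chromosomes, 100 genes of 2 kb, background 1.25 fragments/kb
#' per library, 2.5-kb islands at 4x enrichment with effect onset at 96 h,
#' 24 drought-effect islands (12 gains and 12 losses of the mark, so
#' library mass stays balanced across conditions), 12 combined- and 12
#' heat-effect gain islands, plus 2 constitutive ones.
#'
#' @slot genome named numeric, chromosome lengths (bp).
#' @slot nGenes number of genes.
#' @slot geneLengthBp gene length (bp).
#' @slot repeatFraction fraction of the genome covered by intergenic
#'   repeats.
#' @slot backgroundRate background fragments per kb per library.
#' @slot islandsPerClass named integer: islands per class (\code{DT},
#'   \code{DTHT}, \code{HT}, \code{constitutive}).
#' @slot islandWidthBp island width (bp).
#' @slot multiplier fragment-rate multiplier inside an active island.
#' @slot onsets named numeric: onset time (h) per effect class; heat-class
#'   onsets must be >= 96 h.
#' @slot fragmentSizeBp fragment length (bp).
#' @slot seed RNG seed.
#' @export
setClass("TruthSpec",
  representation(genome = "numeric", nGenes = "integer",
                 geneLengthBp = "integer", repeatFraction = "numeric",
                 backgroundRate = "numeric", islandsPerClass = "integer",
                 islandWidthBp = "integer", multiplier = "numeric",
                 onsets = "numeric", fragmentSizeBp = "integer",
                 seed = "integer"))

setValidity("TruthSpec", function(object) {
  msg <- NULL
  if (is.null(names(object@genome)) || any(object@genome < 1))
    msg <- c(msg, "genome must be a named vector of positive lengths")
  need <- c("DT", "DTHT", "HT", "constitutive")
  if (!all(need %in% names(object@islandsPerClass)))
    msg <- c(msg, "islandsPerClass must name DT, DTHT, HT, constitutive")
  if (object@multiplier < 1) msg <- c(msg, "multiplier must be >= 1")
  eff <- c("DT", "DTHT", "HT")
  if (!all(eff %in% names(object@onsets)))
    msg <- c(msg, "onsets must name DT, DTHT, HT")
  else {
    if (!all(object@onsets[eff] %in% c(72, 96, 120, 144, 168)))
      msg <- c(msg, "onsets must lie in {72, 96, 120, 144, 168}")
    # heat is imposed after 72 h of drought
    if (!is.na(object@onsets["HT"]) && object@onsets["HT"] < 96)
      msg <- c(msg, "HT onset must be >= 96 h (heat starts at 72 h)")
  }
  if (object@backgroundRate <= 0)
    msg <- c(msg, "backgroundRate must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a truth specification
#'
#' @param genome named vector of chromosome lengths (bp).
#' @param nGenes number of genes to place.
#' @param geneLengthBp gene length (bp).
#' @param repeatFraction target fraction of the genome covered by repeats.
#' @param backgroundRate background fragments per kb per library.
#' @param islandsPerClass named integer vector over
#'   \code{DT}/\code{DTHT}/\code{HT}/\code{constitutive}.
#' @param islandWidthBp island width (bp).
#' @param multiplier in-island fragment-rate multiplier.
#' @param onsets named numeric vector of effect onsets (h) for
#'   \code{DT}/\code{DTHT}/\code{HT}.
#' @param fragmentSizeBp fragment length (bp).
#' @param seed RNG seed.
#' @return A \linkS4class{TruthSpec}.
#' @export
truthSpec <- function(genome = c(chrA = 500000, chrB = 500000),
                      nGenes = 100, geneLengthBp = 2000,
                      repeatFraction = 0.1, backgroundRate = 1.25,
                      islandsPerClass = c(DT = 24L, DTHT = 12L, HT = 12L,
                                          constitutive = 2L),
                      islandWidthBp = 2500, multiplier = 4,
                      onsets = c(DT = 96, DTHT = 96, HT = 96),
                      fragmentSizeBp = 300, seed = 42) {
  new("TruthSpec", genome = genome, nGenes = as.integer(nGenes),
      geneLengthBp = as.integer(geneLengthBp),
      repeatFraction = repeatFraction, backgroundRate = backgroundRate,
      islandsPerClass = stats::setNames(as.integer(islandsPerClass),
                                        names(islandsPerClass)),
      islandWidthBp = as.integer(islandWidthBp), multiplier = multiplier,
      onsets = onsets, fragmentSizeBp = as.integer(fragmentSizeBp),
      seed = as.integer(seed))
}

setMethod("show", "TruthSpec", function(object) {
  cat(sprintf("TruthSpec: %d chromosome(s), %.0f kb; %d genes; %s islands\n",
              length(object@genome), sum(object@genome) / 1000,
              object@nGenes,
              paste(sprintf("%s=%d", names(object@islandsPerClass),
                            object@islandsPerClass), collapse = " ")))
  cat(sprintf("  background %.2g frags/kb, multiplier %.3g, seed %d\n",
              object@backgroundRate, object@multiplier, object@seed))
})

#' Is an island's effect active in a given library?
#'
#' The design's activity rules: constitutive islands are enriched in every
#' ChIP library; drought-effect islands in the DT and DTHT arms from their
#' onset; combined-effect islands only in the DTHT arm from onset;
#' heat-effect islands only in the DTHT arm from onset (onset >= 96 h since
#' heat begins at 72 h of drought). Input libraries see background only.
#'
#' @param class island class (\code{DT}, \code{DTHT}, \code{HT},
#'   \code{constitutive}).
#' @param onset onset time (h); ignored for constitutive islands.
#' @param condition library condition (\code{C}, \code{DT}, \code{DTHT}).
#' @param timepoint library time point (h).
#' @param role \code{"chip"} or \code{"input"}.
#' @return Logical.
#' @export
islandActive <- function(class, onset, condition, timepoint,
                         role = "chip") {
  if (role == "input") return(FALSE)
  switch(class,
         constitutive = TRUE,
         DT = condition %in% c("DT", "DTHT") && timepoint >= onset,
         DTHT = condition == "DTHT" && timepoint >= onset,
         HT = condition == "DTHT" && timepoint >= onset,
         stop("unknown island class: ", class))
}

#' Expected responsive classes of an island
#'
#' Derives, analytically from the activity rules, which of the three
#' factorial rules an island's true differential pattern satisfies. Note
#' the classes overlap by construction: a drought-effect island is also
#' differential in DTHT vs C (it is active in the combined arm) and never
#' differential in DTHT vs DT, so it satisfies all three rules; a
#' heat-effect island satisfies DTHT and HT; a combined-effect island with
#' onset 72 h satisfies only DTHT (its 72-h DTHT-vs-DT difference breaks
#' the heat baseline).
#'
#' @param class island class.
#' @param onset onset time (h).
#' @return Character vector of satisfied classes (possibly empty).
#' @export
expectedClasses <- function(class, onset) {
  trulyDiff <- function(contrast, tp)
    islandActive(class, onset, contrast[1], tp) !=
      islandActive(class, onset, contrast[2], tp)
  satisfied <- character(0)
  for (cls in names(STRESS_RULES)) {
    rule <- STRESS_RULES[[cls]]
    baseClean <- !any(vapply(rule$baseline$timepoints, function(tp)
      trulyDiff(rule$baseline$contrast, tp), logical(1)))
    supported <- any(vapply(rule$support$timepoints, function(tp)
      trulyDiff(rule$support$contrast, tp), logical(1)))
    if (baseClean && supported) satisfied <- c(satisfied, cls)
  }
  satisfied
}

## non-overlapping placement of n intervals of width w on the genome:
## counts are spread over chromosomes proportional to length, then the
## leftover slack on each chromosome is divided uniformly at random among
## the intervals ("stars and bars"), which is exact and rejection-free
.placeIntervals <- function(genome, n, w, minGap = 200L) {
  chroms <- sample(names(genome), n, replace = TRUE,
                   prob = genome / sum(genome))
  pitch <- w + minGap
  out <- list()
  for (chr in unique(chroms)) {
    nc <- sum(chroms == chr)
    slack <- as.integer(genome[[chr]]) - nc * pitch
    if (slack < 0)
      stop("could not place ", n, " non-overlapping intervals of ", w,
           " bp; use a larger genome")
    u <- sort(sample.int(slack + 1L, nc, replace = TRUE)) - 1L
    s <- u + (seq_len(nc) - 1L) * pitch + 1L
    out[[chr]] <- GRanges(factor(chr, levels = names(genome)),
                          IRanges(s, width = w))
  }
  sort(do.call(c, unname(out)))
}

## gene structure in transcript orientation (fractions of gene length):
## 5'UTR, exon/intron alternation, 3'UTR
.geneParts <- function(L) {
  utr5 <- max(50L, as.integer(0.075 * L))
  utr3 <- max(50L, as.integer(0.075 * L))
  intron1 <- as.integer(0.10 * L); intron2 <- as.integer(0.075 * L)
  cdsTotal <- L - utr5 - utr3 - intron1 - intron2
  cds1 <- as.integer(0.37 * cdsTotal); cds2 <- as.integer(0.37 * cdsTotal)
  cds3 <- cdsTotal - cds1 - cds2
  list(utr5 = utr5, cds = c(cds1, cds2, cds3),
       introns = c(intron1, intron2), utr3 = utr3)
}

.simulateAnnotationImpl <- function(spec, dir = NULL) {
  si <- .asSeqinfo(spec@genome)
  L <- spec@geneLengthBp
  geneLoc <- .placeIntervals(spec@genome, spec@nGenes, L, minGap = 2500L)
  strandV <- sample(c("+", "-"), spec@nGenes, replace = TRUE)
  ids <- sprintf("gene%03d", seq_len(spec@nGenes))
  parts <- .geneParts(L)

  recs <- list()
  for (i in seq_len(spec@nGenes)) {
    gs <- start(geneLoc)[i]; ge <- end(geneLoc)[i]
    chr <- as.character(seqnames(geneLoc))[i]; str <- strandV[i]
    # segment boundaries in transcript orientation
    segW <- c(parts$utr5, parts$cds[1], parts$introns[1], parts$cds[2],
              parts$introns[2], parts$cds[3], parts$utr3)
    segT <- c("five_prime_UTR", "CDS", "intron", "CDS", "intron", "CDS",
              "three_prime_UTR")
    off <- cumsum(c(0L, segW[-length(segW)]))
    if (str == "+") {
      ss <- gs + off; se <- ss + segW - 1L
    } else {
      se <- ge - off; ss <- se - segW + 1L
    }
    mk <- function(type, s, e, id = NULL, parent = NULL)
      data.frame(chr = chr, type = type, start = s, end = e, strand = str,
                 id = if (is.null(id)) NA_character_ else id,
                 parent = if (is.null(parent)) NA_character_ else parent,
                 stringsAsFactors = FALSE)
    mrna <- paste0(ids[i], ".1")
    rec <- rbind(mk("gene", gs, ge, id = ids[i]),
                 mk("mRNA", gs, ge, id = mrna, parent = ids[i]))
    ex <- which(segT != "intron")
    # exons: contiguous runs of non-intron segments
    runs <- split(ex, cumsum(c(1, diff(ex) != 1))[seq_along(ex)])
    for (r in runs) {
      es <- min(ss[r]); ee <- max(se[r])
      rec <- rbind(rec, mk("exon", es, ee, parent = mrna))
    }
    for (j in which(segT == "CDS"))
      rec <- rbind(rec, mk("CDS", ss[j], se[j], parent = mrna))
    rec <- rbind(rec,
                 mk("five_prime_UTR", ss[1], se[1], parent = mrna),
                 mk("three_prime_UTR", ss[7], se[7], parent = mrna))
    recs[[i]] <- rec
  }
  tab <- do.call(rbind, recs)

  # repeats in intergenic space
  repTarget <- spec@repeatFraction * sum(spec@genome)
  repW <- 500L
  nRep <- as.integer(repTarget / repW)
  reps <- GRanges(seqinfo = si)
  if (nRep > 0) {
    # oversample, then keep the intergenic ones up to the target count
    candidate <- .placeIntervals(spec@genome, nRep * 2L, repW, minGap = 1L)
    candidate <- candidate[!overlapsAny(candidate, geneLoc)]
    candidate <- utils::head(candidate, nRep)
    reps <- GRanges(seqnames(candidate), IRanges(start(candidate),
                                                 end(candidate)),
                    seqinfo = si)
  }

  paths <- list(gff = NULL, repeats = NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths$gff <- file.path(dir, "annotation.gff3")
    attrs <- ifelse(is.na(tab$id),
                    paste0("Parent=", tab$parent),
                    ifelse(is.na(tab$parent), paste0("ID=", tab$id),
                           paste0("ID=", tab$id, ";Parent=", tab$parent)))
    gffLines <- c("##gff-version 3",
                  sprintf("##sequence-region %s 1 %d", names(spec@genome),
                          as.integer(spec@genome)),
                  paste(tab$chr, "stressmark", tab$type, tab$start, tab$end,
                        ".", tab$strand, ".", attrs, sep = "\t"))
    writeLines(gffLines, paths$gff)
    paths$repeats <- file.path(dir, "repeats.bed")
    utils::write.table(
      data.frame(as.character(seqnames(reps)), start(reps) - 1L, end(reps)),
      paths$repeats, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }

  # in-memory GeneAnnotation mirroring what the GFF3 reader would build
  genes <- GRanges(tab$chr[tab$type == "gene"],
                   IRanges(tab$start[tab$type == "gene"],
                           tab$end[tab$type == "gene"]),
                   strand = tab$strand[tab$type == "gene"], seqinfo = si)
  mcols(genes)$gene_id <- ids
  mcols(genes)$tss <- ifelse(strandV == "-", end(genes), start(genes))
  mcols(genes)$tes <- ifelse(strandV == "-", start(genes), end(genes))
  featRows <- tab$type %in% c("five_prime_UTR", "CDS", "three_prime_UTR")
  features <- GRanges(tab$chr[featRows],
                      IRanges(tab$start[featRows], tab$end[featRows]),
                      strand = tab$strand[featRows], seqinfo = si)
  mcols(features)$type <- tab$type[featRows]
  mcols(features)$gene_id <- sub("\\.1$", "", tab$parent[featRows])
  # introns as inter-exon gaps
  exTab <- tab[tab$type == "exon", , drop = FALSE]
  intrL <- lapply(split(seq_len(nrow(exTab)), exTab$parent), function(i) {
    e <- exTab[i, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return(NULL)
    data.frame(chr = e$chr[-1], start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, strand = e$strand[-1],
               gene_id = sub("\\.1$", "", e$parent[-1]))
  })
  intrTab <- do.call(rbind, intrL)
  if (!is.null(intrTab) && nrow(intrTab)) {
    intr <- GRanges(intrTab$chr, IRanges(intrTab$start, intrTab$end),
                    strand = intrTab$strand, seqinfo = si)
    mcols(intr)$type <- "intron"
    mcols(intr)$gene_id <- intrTab$gene_id
    features <- c(features, intr)
  }
  ann <- new("GeneAnnotation", genes = sort(genes),
             features = sort(features), repeats = sort(reps))
  list(annotation = ann, genes = geneLoc, strand = strandV, ids = ids,
       paths = paths)
}

#' Simulate a toy annotation
#'
#' Places non-overlapping genes with 5'-UTR/CDS/intron/3'-UTR structure
#' uniformly on the toy genome and fills intergenic space with repeats to
#' the requested fraction. Deterministic given the spec's seed; the same
#' seed produces byte-identical files.
#'
#' @param spec a \linkS4class{TruthSpec}.
#' @param dir output directory for \code{annotation.gff3} and
#'   \code{repeats.bed}; \code{NULL} for in-memory only.
#' @return A list with \code{annotation} (a
#'   \linkS4class{GeneAnnotation}) and \code{paths}.
#' @export
simulateAnnotation <- function(spec, dir = NULL) {
  set.seed(spec@seed)
  res <- .simulateAnnotationImpl(spec, dir)
  res[c("annotation", "paths")]
}

## island placement at TSSs of distinct sampled genes, oriented
## downstream. Effect-class islands alternate direction: gains (+1) sit at
## background level and rise to multiplier-fold when active; losses (-1)
## are constitutively marked at multiplier-fold and drop to background
## when active. Pairing gains and losses keeps the expected library mass
## identical across conditions, so library-size normalization stays
## composition-free.
.placeIslands <- function(spec, annInfo) {
  counts <- spec@islandsPerClass
  total <- sum(counts)
  if (total > spec@nGenes)
    stop("more islands than genes; increase nGenes")
  pick <- sample(seq_len(spec@nGenes), total)
  classes <- rep(names(counts), counts)
  direction <- unlist(lapply(counts, function(n)
    rep_len(c(1L, -1L), n)), use.names = FALSE)
  # losses only in the DT class: a high-high null region (a loss island of
  # another class seen by an unaffected contrast) is where the raw-p window
  # test is least conservative, so the other classes implant gains only;
  # DT gain/loss pairs balance library mass in both the DT and DTHT arms
  direction[classes != "DT"] <- 1L
  ann <- annInfo$annotation
  g <- ann@genes
  ord <- match(annInfo$ids[pick], mcols(g)$gene_id)
  tss <- mcols(g)$tss[ord]
  str <- as.character(strand(g))[ord]
  # constitutive promoter marks are sharp; stress-modulated domains broad
  w <- ifelse(classes == "constitutive",
              min(spec@islandWidthBp, 800L), spec@islandWidthBp)
  s <- ifelse(str == "-", tss - w + 1L, tss)
  e <- ifelse(str == "-", tss, tss + w - 1L)
  sl <- .genomeLengths(spec@genome)[as.character(seqnames(g))[ord]]
  s <- pmax(s, 1L); e <- pmin(e, sl)
  onset <- ifelse(classes == "constitutive", NA_real_,
                  spec@onsets[classes])
  data.frame(chrom = as.character(seqnames(g))[ord], start = s, end = e,
             class = classes, onset = onset, direction = direction,
             multiplier = spec@multiplier,
             gene_id = mcols(g)$gene_id[ord],
             stringsAsFactors = FALSE)
}

.libraryPlan <- function() {
  chip <- expand.grid(replicate = 1:3, timepoint = STRESS_TIMEPOINTS,
                      condition = STRESS_CONDITIONS,
                      stringsAsFactors = FALSE)[, 3:1]
  chip$role <- "chip"
  input <- data.frame(condition = STRESS_CONDITIONS, timepoint = NA_real_,
                      replicate = 1L, role = "input")
  rbind(chip, input)
}

## one library's fragments: uniform background + active-island extras
.simulateLibrary <- function(spec, islands, condition, timepoint, role) {
  sl <- .genomeLengths(spec@genome)
  si <- .asSeqinfo(spec@genome)
  fs <- spec@fragmentSizeBp
  chrom <- character(0); p5 <- integer(0); str <- character(0)
  for (chr in names(sl)) {
    nBg <- stats::rpois(1, spec@backgroundRate * sl[[chr]] / 1000)
    if (nBg > 0) {
      chrom <- c(chrom, rep(chr, nBg))
      p5 <- c(p5, sample.int(as.integer(sl[[chr]]), nBg, replace = TRUE))
      str <- c(str, sample(c("+", "-"), nBg, replace = TRUE))
    }
  }
  for (k in seq_len(nrow(islands))) {
    isl <- islands[k, ]
    active <- islandActive(isl$class, isl$onset, condition, timepoint, role)
    # gains are elevated while active; losses are elevated while inactive
    # (constitutive mark that the stress removes); inputs see background
    elevated <- if (role == "input") FALSE else
      if (isl$direction > 0) active else !active
    if (!elevated) next
    w <- isl$end - isl$start + 1L
    nExtra <- stats::rpois(1, (spec@multiplier - 1) *
                           spec@backgroundRate * w / 1000)
    if (nExtra > 0) {
      chrom <- c(chrom, rep(isl$chrom, nExtra))
      p5 <- c(p5, isl$start + sample.int(w, nExtra, replace = TRUE) - 1L)
      str <- c(str, sample(c("+", "-"), nExtra, replace = TRUE))
    }
  }
  if (!length(p5)) stop("zero fragments simulated; raise backgroundRate")
  s <- ifelse(str == "+", p5, p5 - fs + 1L)
  e <- ifelse(str == "+", p5 + fs - 1L, p5)
  s <- pmax(s, 1L); e <- pmin(e, as.integer(sl[chrom]))
  sort(GRanges(chrom, IRanges(s, e), strand = str, seqinfo = si))
}

#' Simulate the full factorial experiment
#'
#' Generates the annotation, implants islands at gene TSSs, and simulates
#' every library of the design (3 conditions x 6 time points x 3
#' replicates plus one input control per condition, 57 libraries).
#' Fragments are emitted directly (the pipeline operates on
#' fragment-extended intervals); each BED record is a fragment whose
#' strand-aware 5' end reproduces it when re-read and re-extended.
#'
#' @param spec a \linkS4class{TruthSpec}.
#' @param dir output directory; when given, one BED6 file per library plus
#'   \code{manifest.tsv}, \code{annotation.gff3}, \code{repeats.bed} and
#'   \code{truth.json} are written. \code{NULL} keeps everything in
#'   memory.
#' @return A list with \code{libraries} (named list of
#'   \linkS4class{FragmentLibrary}), \code{annotation}
#'   (\linkS4class{GeneAnnotation}), \code{islands} (truth data.frame with
#'   an \code{expected} column of comma-joined rule-derived classes),
#'   \code{manifest} (data.frame) and \code{dir}.
#' @export
simulateExperiment <- function(spec, dir = NULL) {
  set.seed(spec@seed)
  annInfo <- .simulateAnnotationImpl(spec, dir)
  islands <- .placeIslands(spec, annInfo)
  islands$expected <- vapply(seq_len(nrow(islands)), function(k)
    paste(expectedClasses(islands$class[k], islands$onset[k]),
          collapse = ","), character(1))

  plan <- .libraryPlan()
  libs <- vector("list", nrow(plan))
  paths <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    frags <- .simulateLibrary(spec, islands, plan$condition[i],
                              plan$timepoint[i], plan$role[i])
    lab <- libraryLabel(plan$condition[i], plan$timepoint[i],
                        plan$replicate[i], plan$role[i])
    libs[[i]] <- new("FragmentLibrary", label = lab, fragments = frags)
    names(libs)[i] <- .labelString(lab)
    if (!is.null(dir)) {
      paths[i] <- file.path(dir, paste0(.labelString(lab), ".bed"))
      .writeBed6Plus(frags, paths[i],
                     names = sprintf("frag%d", seq_along(frags)),
                     scores = 0L, strands = as.character(strand(frags)))
    }
  }
  manifest <- data.frame(path = if (is.null(dir)) names(libs) else
                           basename(paths),
                         condition = plan$condition,
                         timepoint = plan$timepoint,
                         replicate = plan$replicate, role = plan$role,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(genome = as.list(spec@genome), islands = islands,
           backgroundRate = spec@backgroundRate,
           multiplier = spec@multiplier, seed = spec@seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  list(libraries = libs, annotation = annInfo$annotation,
       islands = islands, manifest = manifest, dir = dir)
}

#' Evaluate class recovery against the ground truth
#'
#' Scores the classifier's output against the rule-derived expected
#' classes of the implanted islands: for each class, an island counts as
#' predicted when at least one called responsive region of that class
#' overlaps it. Precision is TP / predicted islands, recall is TP / truth
#' islands, per class. Called regions overlapping no island at all are
#' tallied separately as background calls.
#'
#' @param responsive named list of \linkS4class{ResponsiveSet} (names
#'   \code{DT}, \code{DTHT}, \code{HT}).
#' @param islands truth data.frame from [simulateExperiment()].
#' @return A list with \code{perClass} (data.frame: class, nTruth,
#'   nPredicted, TP, precision, recall) and \code{backgroundRegions}.
#' @export
evaluateRecovery <- function(responsive, islands) {
  islGr <- GRanges(islands$chrom, IRanges(islands$start, islands$end))
  background <- 0L
  rows <- lapply(names(responsive), function(cls) {
    regions <- responsive[[cls]]@regions
    hitIsl <- overlapsAny(islGr, regions)
    background <<- background + sum(!overlapsAny(regions, islGr))
    truth <- grepl(paste0("(^|,)", cls, "(,|$)"), islands$expected)
    tp <- sum(hitIsl & truth)
    data.frame(class = cls, nTruth = sum(truth), nPredicted = sum(hitIsl),
               TP = tp,
               precision = if (sum(hitIsl)) tp / sum(hitIsl) else NA_real_,
               recall = if (sum(truth)) tp / sum(truth) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(perClass = do.call(rbind, rows), backgroundRegions = background)
}
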