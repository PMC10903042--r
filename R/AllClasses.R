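#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce resize granges
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#'   keepSeqlevels seqlengths<-
NULL

STRESS_CONDITIONS <- c("C", "DT", "DTHT")
STRESS_TIMEPOINTS <- c(0, 72, 96, 120, 144, 168)

#' Library label
#'
#' Identifies one sequencing library within the factorial design:
#' condition (\code{C}, \code{DT} or \code{DTHT}), collection time point in
#' hours, replicate number, and role (\code{chip} for the immunoprecipitated
#' library, \code{input} for the sonicated-chromatin control). Input
#' libraries carry no time point (one control per condition).
#'
#' @slot condition character, one of \code{C}, \code{DT}, \code{DTHT}.
#' @slot timepoint numeric, hours since drought onset; \code{NA} for input.
#' @slot replicate integer replicate number.
#' @slot role \code{"chip"} or \code{"input"}.
#' @export
setClass("LibraryLabel",
  representation(condition = "character", timepoint = "numeric",
                 replicate = "integer", role = "character"),
  prototype(condition = "C", timepoint = 0, replicate = 1L, role = "chip"))

setValidity("LibraryLabel", function(object) {
  msg <- NULL
  if (!object@condition %in% STRESS_CONDITIONS)
    msg <- c(msg, sprintf("condition must be one of %s",
                          paste(STRESS_CONDITIONS, collapse = ", ")))
  if (object@role == "chip" &&
      !(length(object@timepoint) == 1 && object@timepoint %in% STRESS_TIMEPOINTS))
    msg <- c(msg, sprintf("chip timepoint must be one of %s",
                          paste(STRESS_TIMEPOINTS, collapse = ", ")))
  if (!object@role %in% c("chip", "input"))
    msg <- c(msg, "role must be 'chip' or 'input'")
  if (length(object@replicate) != 1 || is.na(object@replicate) ||
      object@replicate < 1L)
    msg <- c(msg, "replicate must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' Construct a library label
#'
#' @param condition one of \code{"C"}, \code{"DT"}, \code{"DTHT"}.
#' @param timepoint collection time in hours (0, 72, 96, 120, 144, 168);
#'   ignored (set to \code{NA}) for input libraries.
#' @param replicate replicate number.
#' @param role \code{"chip"} or \code{"input"}.
#' @return A \linkS4class{LibraryLabel}.
#' @examples
#' libraryLabel("DT", 96, 2)
#' @export
libraryLabel <- function(condition, timepoint = NA_real_, replicate = 1,
                         role = c("chip", "input")) {
  role <- match.arg(role)
  if (role == "input") timepoint <- NA_real_
  new("LibraryLabel", condition = condition,
      timepoint = as.numeric(timepoint),
      replicate = as.integer(replicate), role = role)
}

setMethod("show", "LibraryLabel", function(object) {
  tp <- if (is.na(object@timepoint)) "-" else paste0(object@timepoint, "h")
  cat(sprintf("<%s %s rep%d %s>\n", object@condition, tp,
              object@replicate, object@role))
})

.labelString <- function(label) {
  tp <- if (is.na(label@timepoint)) "NA" else format(label@timepoint)
  paste(label@condition, tp, label@replicate, label@role, sep = "_")
}

#' Pipeline configuration
#'
#' Holds all tunable parameters of the island-calling and differential
#' pipeline. Defaults are the analysis parameters used throughout: 200-bp
#' windows with 200-bp gaps and an effective genome fraction of 0.7 for
#' island calling at FDR 0.05; 200-bp windows stepped every 100 bp, gap 0,
#' fragment size 300 and a raw p-value cutoff of 0.01 for differential
#' detection; 2-kb flanks for gene/TSS work.
#'
#' @slot windowBp island-calling window width (bp).
#' @slot gapBp maximum gap bridged when clustering eligible windows (bp).
#' @slot redundancyThreshold maximum retained reads per (chrom, position,
#'   strand).
#' @slot effectiveGenomeFraction mappable fraction of the genome used for
#'   the Poisson background rate.
#' @slot islandFdr island acceptance threshold (Benjamini-Hochberg FDR).
#' @slot diffWindowBp differential window width (bp).
#' @slot diffStepBp differential window step (bp).
#' @slot diffGapBp gap for merging significant differential windows (bp).
#' @slot fragmentSizeBp length to which reads are extended (bp).
#' @slot diffPCutoff raw p-value cutoff for differential windows.
#' @slot flankBp flank used for upstream/downstream classes and gene overlap.
#' @slot eligibleWindowP per-window Poisson probability below which a window
#'   is eligible to seed an island.
#' @export
setClass("MarkConfig",
  representation(windowBp = "integer", gapBp = "integer",
                 redundancyThreshold = "integer",
                 effectiveGenomeFraction = "numeric", islandFdr = "numeric",
                 diffWindowBp = "integer", diffStepBp = "integer",
                 diffGapBp = "integer", fragmentSizeBp = "integer",
                 diffPCutoff = "numeric", flankBp = "integer",
                 eligibleWindowP = "numeric"),
  prototype(windowBp = 200L, gapBp = 200L, redundancyThreshold = 1L,
            effectiveGenomeFraction = 0.7, islandFdr = 0.05,
            diffWindowBp = 200L, diffStepBp = 100L, diffGapBp = 0L,
            fragmentSizeBp = 300L, diffPCutoff = 0.01, flankBp = 2000L,
            eligibleWindowP = 0.2))

setValidity("MarkConfig", function(object) {
  msg <- NULL
  sizes <- c(windowBp = object@windowBp, redundancyThreshold =
             object@redundancyThreshold, diffWindowBp = object@diffWindowBp,
             diffStepBp = object@diffStepBp,
             fragmentSizeBp = object@fragmentSizeBp,
             flankBp = object@flankBp)
  if (any(sizes < 1L)) msg <- c(msg, "all sizes must be positive")
  if (object@gapBp < 0L || object@diffGapBp < 0L)
    msg <- c(msg, "gaps must be non-negative")
  if (!(object@effectiveGenomeFraction > 0 &&
        object@effectiveGenomeFraction <= 1))
    msg <- c(msg, "effectiveGenomeFraction must be in (0, 1]")
  probs <- c(object@islandFdr, object@diffPCutoff, object@eligibleWindowP)
  if (any(probs <= 0 | probs >= 1))
    msg <- c(msg, "probability thresholds must be in (0, 1)")
  if (object@diffStepBp > object@diffWindowBp)
    msg <- c(msg, "diffStepBp must not exceed diffWindowBp")
  if (is.null(msg)) TRUE else msg
})

#' Construct a pipeline configuration
#'
#' @param ... named parameters overriding the defaults; see
#'   \linkS4class{MarkConfig} for the slot list.
#' @return A \linkS4class{MarkConfig}.
#' @examples
#' markConfig()
#' markConfig(islandFdr = 0.01)
#' @export
markConfig <- function(...) {
  args <- list(...)
  ints <- c("windowBp", "gapBp", "redundancyThreshold", "diffWindowBp",
            "diffStepBp", "diffGapBp", "fragmentSizeBp", "flankBp")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("MarkConfig"), args))
}

setMethod("show", "MarkConfig", function(object) {
  cat("MarkConfig\n")
  cat(sprintf("  island calling : window %d bp, gap %d bp, FDR %g, eff. fraction %g\n",
              object@windowBp, object@gapBp, object@islandFdr,
              object@effectiveGenomeFraction))
  cat(sprintf("  differential   : window %d bp, step %d bp, gap %d bp, p < %g\n",
              object@diffWindowBp, object@diffStepBp, object@diffGapBp,
              object@diffPCutoff))
  cat(sprintf("  fragments      : %d bp, redundancy %d; flank %d bp\n",
              object@fragmentSizeBp, object@redundancyThreshold,
              object@flankBp))
})

.validRanges <- function(gr, what) {
  sl <- seqlengths(gr)
  if (any(is.na(sl)))
    return(sprintf("%s must carry seqlengths for every chromosome", what))
  bad <- start(gr) < 1L | end(gr) > sl[as.character(seqnames(gr))]
  if (any(bad))
    return(sprintf("%d %s fall outside chromosome bounds", sum(bad), what))
  TRUE
}

#' Read library: strand-aware 5' read positions
#'
#' One aligned sequencing library reduced to the 5'-most base of each read
#' (width-1 ranges), with strand, on a genome with known chromosome lengths.
#'
#' @slot label a \linkS4class{LibraryLabel}.
#' @slot reads a \code{GRanges} of width-1 positions with strand
#'   \code{+}/\code{-} and seqlengths set.
#' @export
setClass("ReadLibrary",
  representation(label = "LibraryLabel", reads = "GRanges"))

setValidity("ReadLibrary", function(object) {
  msg <- NULL
  if (length(object@reads) && any(width(object@reads) != 1L))
    msg <- c(msg, "reads must be width-1 positions")
  if (length(object@reads) &&
      !all(as.character(strand(object@reads)) %in% c("+", "-")))
    msg <- c(msg, "read strand must be + or -")
  v <- .validRanges(object@reads, "reads")
  if (!isTRUE(v)) msg <- c(msg, v)
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ReadLibrary", function(object) {
  cat(sprintf("ReadLibrary: %d reads on %d chromosome(s)\n",
              length(object@reads), length(seqlevels(object@reads))))
  show(object@label)
})

#' Fragment library: extended read intervals
#'
#' Reads extended to the expected fragment size (clipped at chromosome
#' edges), the unit counted by all window- and island-level statistics.
#'
#' @slot label a \linkS4class{LibraryLabel}.
#' @slot fragments a \code{GRanges} with seqlengths set.
#' @export
setClass("FragmentLibrary",
  representation(label = "LibraryLabel", fragments = "GRanges"))

setValidity("FragmentLibrary", function(object)
  .validRanges(object@fragments, "fragments"))

setMethod("show", "FragmentLibrary", function(object) {
  cat(sprintf("FragmentLibrary: %d fragments on %d chromosome(s)\n",
              length(object@fragments), length(seqlevels(object@fragments))))
  show(object@label)
})

#' Enriched island set for one library
#'
#' Islands called against the input control. The \code{islands} GRanges
#' carries metadata columns \code{score} (sum over eligible member windows
#' of -log Poisson probability), \code{chipCount}, \code{inputScaled}
#' (input fragment count scaled by the library-size ratio), \code{pvalue},
#' and \code{fdr}.
#'
#' @slot label the ChIP library's \linkS4class{LibraryLabel}.
#' @slot islands a \code{GRanges} with the columns above, sorted and
#'   non-overlapping; all retained islands pass the configured FDR.
#' @slot lambdaWindow expected fragments per full window under the uniform
#'   background model.
#' @slot config the \linkS4class{MarkConfig} used.
#' @export
setClass("IslandSet",
  representation(label = "LibraryLabel", islands = "GRanges",
                 lambdaWindow = "numeric", config = "MarkConfig"))

setValidity("IslandSet", function(object) {
  msg <- NULL
  need <- c("score", "chipCount", "inputScaled", "pvalue", "fdr")
  if (!all(need %in% names(mcols(object@islands))))
    msg <- c(msg, sprintf("islands must carry columns %s",
                          paste(need, collapse = ", ")))
  if (length(object@islands) > 1 && !all(diff(start(object@islands)) >= 0) &&
      length(unique(seqnames(object@islands))) == 1)
    msg <- c(msg, "islands must be sorted")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "IslandSet", function(object) {
  cat(sprintf("IslandSet: %d islands (FDR <= %g, lambda/window = %.4g)\n",
              length(object@islands), object@config@islandFdr,
              object@lambdaWindow))
  show(object@label)
})

#' Differential peak set for one contrast at one time point
#'
#' Significant sliding windows of a two-group comparison merged into
#' directional peaks. Metadata columns: \code{direction} (+1 = higher in
#' group A), \code{pvalue} (minimum member-window p), \code{rpmA},
#' \code{rpmB} (mean member-window fragments per million).
#'
#' @slot contrast character of length 2, group A then group B
#'   (e.g. \code{c("DT", "C")}).
#' @slot timepoint time point in hours.
#' @slot peaks a \code{GRanges} with the columns above.
#' @export
setClass("DiffPeakSet",
  representation(contrast = "character", timepoint = "numeric",
                 peaks = "GRanges"))

setValidity("DiffPeakSet", function(object) {
  msg <- NULL
  if (length(object@contrast) != 2L)
    msg <- c(msg, "contrast must name exactly two groups")
  need <- c("direction", "pvalue", "rpmA", "rpmB")
  if (!all(need %in% names(mcols(object@peaks))))
    msg <- c(msg, sprintf("peaks must carry columns %s",
                          paste(need, collapse = ", ")))
  if (length(object@peaks) &&
      !all(mcols(object@peaks)$direction %in% c(-1L, 1L)))
    msg <- c(msg, "direction must be +1 or -1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DiffPeakSet", function(object) {
  cat(sprintf("DiffPeakSet %s vs %s at %g h: %d peaks (%d up, %d down)\n",
              object@contrast[1], object@contrast[2], object@timepoint,
              length(object@peaks),
              sum(mcols(object@peaks)$direction == 1L),
              sum(mcols(object@peaks)$direction == -1L)))
})

#' Region universe across contrasts and time points
#'
#' Single-linkage merge of all differential peaks from all contrast/time
#' point comparisons, with a membership map recording, for every region and
#' every \code{contrast:timepoint} key, whether the region overlaps a
#' differential peak there and in which direction.
#'
#' @slot regions non-overlapping merged \code{GRanges}.
#' @slot isDiff logical matrix, regions x keys.
#' @slot direction integer matrix (+1/-1/0), regions x keys; 0 where not
#'   differential.
#' @export
setClass("RegionUniverse",
  representation(regions = "GRanges", isDiff = "matrix",
                 direction = "matrix"))

setValidity("RegionUniverse", function(object) {
  msg <- NULL
  n <- length(object@regions)
  if (nrow(object@isDiff) != n || nrow(object@direction) != n)
    msg <- c(msg, "membership matrices must have one row per region")
  if (!identical(colnames(object@isDiff), colnames(object@direction)))
    msg <- c(msg, "membership matrices must share column names")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RegionUniverse", function(object) {
  cat(sprintf("RegionUniverse: %d regions x %d contrast:timepoint keys\n",
              length(object@regions), ncol(object@isDiff)))
  if (ncol(object@isDiff))
    cat("  keys:", paste(colnames(object@isDiff), collapse = ", "), "\n")
})

#' Stress-responsive region set
#'
#' Regions satisfying one of the factorial time-course rules (drought,
#' combined drought-and-heat, or heat). Metadata columns:
#' \code{timepoints} (comma-separated supporting hours) and
#' \code{direction} (+1 gain / -1 loss at the earliest supporting time
#' point).
#'
#' @slot stressClass \code{"DT"}, \code{"DTHT"} or \code{"HT"}.
#' @slot regions a \code{GRanges} with the columns above.
#' @export
setClass("ResponsiveSet",
  representation(stressClass = "character", regions = "GRanges"))

setValidity("ResponsiveSet", function(object) {
  msg <- NULL
  if (!object@stressClass %in% c("DT", "DTHT", "HT"))
    msg <- c(msg, "stressClass must be DT, DTHT or HT")
  need <- c("timepoints", "direction")
  if (!all(need %in% names(mcols(object@regions))))
    msg <- c(msg, "regions must carry timepoints and direction columns")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ResponsiveSet", function(object) {
  cat(sprintf("ResponsiveSet[%s]: %d regions (%d gain, %d loss)\n",
              object@stressClass, length(object@regions),
              sum(mcols(object@regions)$direction == 1L),
              sum(mcols(object@regions)$direction == -1L)))
})

#' Gene annotation with sub-features and repeats
#'
#' Gene models with strand-aware TSS/TES, genic sub-features
#' (5'-UTR, CDS, intron, 3'-UTR) and a repeat track, as used for feature
#' classification, nearest-TSS distances and metaprofiles.
#'
#' @slot genes \code{GRanges} with metadata columns \code{gene_id},
#'   \code{tss}, \code{tes}.
#' @slot features \code{GRanges} with metadata columns \code{type} (one of
#'   \code{five_prime_UTR}, \code{CDS}, \code{intron},
#'   \code{three_prime_UTR}) and \code{gene_id}.
#' @slot repeats \code{GRanges} of repeat intervals.
#' @export
setClass("GeneAnnotation",
  representation(genes = "GRanges", features = "GRanges",
                 repeats = "GRanges"))

setValidity("GeneAnnotation", function(object) {
  msg <- NULL
  if (!all(c("gene_id", "tss", "tes") %in% names(mcols(object@genes))))
    msg <- c(msg, "genes must carry gene_id, tss, tes columns")
  if (!all(c("type", "gene_id") %in% names(mcols(object@features))))
    msg <- c(msg, "features must carry type and gene_id columns")
  ok <- c("five_prime_UTR", "CDS", "intron", "three_prime_UTR")
  if (length(object@features) && !all(mcols(object@features)$type %in% ok))
    msg <- c(msg, sprintf("feature type must be one of %s",
                          paste(ok, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes, %d sub-features, %d repeats\n",
              length(object@genes), length(object@features),
              length(object@repeats)))
})
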