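## Factorial time-course rules. A region (single-linkage merge of all
## differential peaks) is:
##  - DT-responsive  : not differential in DT vs C at 0 h, differential in
##    DT vs C at >= 1 of 72/96/120/144/168 h;
##  - DTHT-responsive: same template for DTHT vs C;
##  - HT-responsive  : not differential in DTHT vs DT at 0 h nor 72 h, and
##    differential in DTHT vs C at >= 1 of 96/120/144/168 h (heat is
##    imposed after 72 h of drought, so heat effects are read from the
##    combined arm).

.contrastKey <- function(contrast, timepoint)
  sprintf("%s.%s:%g", contrast[1], contrast[2], timepoint)

STRESS_RULES <- list(
  DT = list(baseline = list(contrast = c("DT", "C"), timepoints = 0),
            support = list(contrast = c("DT", "C"),
                           timepoints = c(72, 96, 120, 144, 168))),
  DTHT = list(baseline = list(contrast = c("DTHT", "C"), timepoints = 0),
              support = list(contrast = c("DTHT", "C"),
                             timepoints = c(72, 96, 120, 144, 168))),
  HT = list(baseline = list(contrast = c("DTHT", "DT"),
                            timepoints = c(0, 72)),
            support = list(contrast = c("DTHT", "C"),
                           timepoints = c(96, 120, 144, 168))))

#' Build the region universe from differential peak sets
#'
#' All differential peaks from every contrast/time point are merged by
#' single-linkage overlap (>= 1 bp) into non-overlapping regions; for each
#' region and each \code{contrast:timepoint} key, the membership map
#' records whether the region overlaps a differential peak there and the
#' direction of the smallest-p overlapping peak.
#'
#' "Not differential at a baseline time point" is later evaluated on the
#' merged region: the region must overlap no differential peak of that
#' contrast at that time point.
#'
#' @param peaksets list of \linkS4class{DiffPeakSet}.
#' @return A \linkS4class{RegionUniverse}.
#' @export
buildRegionUniverse <- function(peaksets) {
  if (!length(peaksets)) stop("no differential peak sets supplied")
  keys <- vapply(peaksets, function(ps)
    .contrastKey(ps@contrast, ps@timepoint), character(1))
  if (anyDuplicated(keys))
    stop("duplicate contrast:timepoint keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  allPeaks <- do.call(c, unname(lapply(peaksets, function(ps)
    granges(ps@peaks))))
  regions <- reduce(sort(allPeaks), min.gapwidth = 0L)
  isDiff <- matrix(FALSE, length(regions), length(keys),
                   dimnames = list(NULL, keys))
  direction <- matrix(0L, length(regions), length(keys),
                      dimnames = list(NULL, keys))
  for (j in seq_along(peaksets)) {
    pk <- peaksets[[j]]@peaks
    if (!length(pk)) next
    hits <- findOverlaps(regions, pk)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    isDiff[unique(qh), j] <- TRUE
    # direction of the smallest-p overlapping peak
    best <- tapply(seq_along(sh), qh, function(i)
      sh[i][which.min(mcols(pk)$pvalue[sh[i]])])
    direction[as.integer(names(best)), j] <-
      mcols(pk)$direction[unlist(best)]
  }
  new("RegionUniverse", regions = regions, isDiff = isDiff,
      direction = direction)
}

#' Classify stress-responsive regions
#'
#' Applies one of the three factorial rules to the membership map of a
#' \linkS4class{RegionUniverse}: the region must overlap no differential
#' peak of the rule's baseline contrast at its baseline time point(s) and
#' must be differential in the rule's support contrast at one or more of
#' its support time points. The region's direction is taken from the
#' earliest qualifying support time point.
#'
#' @param universe a \linkS4class{RegionUniverse} whose keys cover the
#'   contrasts/time points the rule requires (missing keys are a hard
#'   error naming what is absent).
#' @param stressClass \code{"DT"}, \code{"DTHT"} or \code{"HT"}.
#' @return A \linkS4class{ResponsiveSet}.
#' @export
classifyResponsive <- function(universe, stressClass = c("DT", "DTHT", "HT")) {
  stressClass <- match.arg(stressClass)
  rule <- STRESS_RULES[[stressClass]]
  baseKeys <- vapply(rule$baseline$timepoints, function(tp)
    .contrastKey(rule$baseline$contrast, tp), character(1))
  supKeys <- vapply(rule$support$timepoints, function(tp)
    .contrastKey(rule$support$contrast, tp), character(1))
  missing <- setdiff(c(baseKeys, supKeys), colnames(universe@isDiff))
  if (length(missing))
    stop("region universe lacks required contrast:timepoint keys: ",
         paste(missing, collapse = ", "))
  baseOk <- rowSums(universe@isDiff[, baseKeys, drop = FALSE]) == 0L
  supM <- universe@isDiff[, supKeys, drop = FALSE]
  hit <- baseOk & rowSums(supM) > 0L
  idx <- which(hit)
  regions <- universe@regions[idx]
  tps <- rule$support$timepoints
  suppStr <- vapply(idx, function(i)
    paste(tps[supM[i, ]], collapse = ","), character(1))
  firstKey <- vapply(idx, function(i) supKeys[which(supM[i, ])[1]],
                     character(1))
  dir <- vapply(seq_along(idx), function(k)
    universe@direction[idx[k], firstKey[k]], integer(1))
  mcols(regions)$timepoints <- suppStr
  mcols(regions)$direction <- dir
  new("ResponsiveSet", stressClass = stressClass, regions = regions)
}

#' Write a responsive region set to BED6+
#'
#' Columns: chrom, start, end, class, 0, direction (+/-), supporting time
#' points (comma-separated hours).
#'
#' @param x a \linkS4class{ResponsiveSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResponsiveBed <- function(x, path) {
  gr <- x@regions
  .writeBed6Plus(gr, path,
                 names = sprintf("%s_%d", x@stressClass, seq_along(gr)),
                 scores = 0L,
                 strands = ifelse(mcols(gr)$direction > 0, "+", "-"),
                 extra = data.frame(timepoints = mcols(gr)$timepoints))
}
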