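## Sliding-window differential detection between two pooled groups at one
## time point. The statistic is an exact conditional binomial test: given
## the window total t = countA + countB, countA ~ Binomial(t, nA/(nA+nB))
## under the null of equal per-million rates; the two-sided p-value sums
## all outcome probabilities no larger than the observed one (minimum-
## likelihood method). No multiple-testing correction is applied; calling
## uses the raw p < 0.01 cutoff.

#' Sliding-window fragment counts for two groups
#'
#' Windows of width \code{widthBp} are placed every \code{stepBp} along
#' each chromosome (overlapping when step < width); a fragment increments
#' every window it overlaps by at least 1 bp.
#'
#' @param fragsA,fragsB pooled \linkS4class{FragmentLibrary} for groups A
#'   and B.
#' @param genome named vector of chromosome lengths.
#' @param widthBp window width (default 200).
#' @param stepBp window step (default 100); must not exceed the width.
#' @return A window \code{GRanges} with columns \code{countA},
#'   \code{countB}; \code{metadata()} records \code{nA}, \code{nB}
#'   (library sizes) and the geometry.
#' @export
slidingWindowCounts <- function(fragsA, fragsB, genome, widthBp = 200L,
                                stepBp = 100L) {
  widthBp <- as.integer(widthBp); stepBp <- as.integer(stepBp)
  if (stepBp > widthBp)
    stop("stepBp > widthBp would leave uncovered gaps")
  if (!length(fragsA@fragments) || !length(fragsB@fragments))
    stop("both groups must contain fragments")
  sl <- .genomeLengths(genome)
  si <- .asSeqinfo(genome)
  win <- do.call(c, lapply(names(sl), function(chr) {
    s <- seq.int(1L, sl[[chr]], by = stepBp)
    GRanges(chr, IRanges(s, pmin(s + widthBp - 1L, sl[[chr]])), seqinfo = si)
  }))
  mcols(win)$countA <- countOverlaps(win, fragsA@fragments, minoverlap = 1L)
  mcols(win)$countB <- countOverlaps(win, fragsB@fragments, minoverlap = 1L)
  metadata(win) <- list(nA = length(fragsA@fragments),
                        nB = length(fragsB@fragments),
                        widthBp = widthBp, stepBp = stepBp)
  win
}

#' Exact conditional binomial window test
#'
#' Vectorised two-sided test of equal normalized rates in one window.
#' Conditional on t = countA + countB, countA is Binomial(t, nA/(nA+nB))
#' under the null; the p-value sums the probabilities of all outcomes at
#' most as likely as the observed count. Windows with t = 0 get p = 1 and
#' direction 0; otherwise direction is the sign of
#' countA/nA - countB/nB (0 when the normalized rates tie).
#'
#' @param countA,countB fragment counts (vectors of equal length).
#' @param nA,nB group library sizes (> 0).
#' @return A data.frame with columns \code{pvalue} and \code{direction}.
#' @export
testWindow <- function(countA, countB, nA, nB) {
  if (nA <= 0 || nB <= 0) stop("library sizes must be positive")
  countA <- as.integer(countA); countB <- as.integer(countB)
  t <- countA + countB
  pr <- nA / (nA + nB)
  p <- rep(1, length(t))
  nz <- which(t > 0L)
  if (length(nz)) {
    for (tt in unique(t[nz])) {
      d <- stats::dbinom(0:tt, tt, pr)
      # relative tolerance guards against FP noise in the <= comparison
      cum <- vapply(d, function(px) sum(d[d <= px * (1 + 1e-7)]), numeric(1))
      sel <- nz[t[nz] == tt]
      p[sel] <- pmin(1, cum[countA[sel] + 1L])
    }
  }
  dir <- sign(countA / nA - countB / nB)
  data.frame(pvalue = p, direction = as.integer(dir))
}

#' Merge significant windows into directional differential peaks
#'
#' Windows passing the p-value cutoff are partitioned by direction and
#' merged when overlapping or within \code{gapBp} of each other (gap 0
#' merges touching/overlapping windows only). Each peak takes the union
#' interval, the minimum member p-value, and the mean member RPM for each
#' group. Where peaks of opposite direction overlap (possible when step <
#' width), the contested overlap is assigned to the peak with the smaller
#' p-value and trimmed from the other; exact p ties split the overlap at
#' its midpoint.
#'
#' @param win window \code{GRanges} from [slidingWindowCounts()] with
#'   \code{pvalue} and \code{direction} columns added.
#' @param pCutoff raw p-value cutoff (default 0.01).
#' @param gapBp merge gap in bp (default 0).
#' @param contrast character of length 2 (group A, group B).
#' @param timepoint time point in hours.
#' @return A \linkS4class{DiffPeakSet}.
#' @export
mergeDifferential <- function(win, pCutoff = 0.01, gapBp = 0L,
                              contrast = c("A", "B"), timepoint = NA_real_) {
  nA <- metadata(win)$nA; nB <- metadata(win)$nB
  sig <- win[mcols(win)$pvalue < pCutoff & mcols(win)$direction != 0L]
  peakL <- lapply(c(1L, -1L), function(d) {
    w <- sig[mcols(sig)$direction == d]
    if (!length(w)) return(NULL)
    w <- sort(w)
    pk <- reduce(granges(w), min.gapwidth = gapBp + 1L)
    hits <- findOverlaps(pk, w)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    mcols(pk)$direction <- d
    mcols(pk)$pvalue <- as.numeric(
      tapply(mcols(w)$pvalue[sh], qh, min)[as.character(seq_along(pk))])
    mcols(pk)$rpmA <- as.numeric(
      tapply(mcols(w)$countA[sh] / nA * 1e6, qh, mean)[
        as.character(seq_along(pk))])
    mcols(pk)$rpmB <- as.numeric(
      tapply(mcols(w)$countB[sh] / nB * 1e6, qh, mean)[
        as.character(seq_along(pk))])
    pk
  })
  peakL <- peakL[!vapply(peakL, is.null, logical(1))]
  if (!length(peakL)) {
    pk <- GRanges(seqinfo = seqinfo(win))
    mcols(pk) <- DataFrame(direction = integer(0), pvalue = numeric(0),
                           rpmA = numeric(0), rpmB = numeric(0))
    return(new("DiffPeakSet", contrast = contrast,
               timepoint = as.numeric(timepoint), peaks = pk))
  }
  if (length(peakL) == 2L) {
    up <- peakL[[1]]; dn <- peakL[[2]]
    ov <- findOverlaps(up, dn)
    for (k in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[k]; j <- S4Vectors::subjectHits(ov)[k]
      os <- max(start(up)[i], start(dn)[j])
      oe <- min(end(up)[i], end(dn)[j])
      pu <- mcols(up)$pvalue[i]; pd <- mcols(dn)$pvalue[j]
      if (pu < pd) {                      # up wins the overlap
        if (start(dn)[j] >= os) start(dn)[j] <- oe + 1L else
          end(dn)[j] <- os - 1L
      } else if (pd < pu) {
        if (start(up)[i] >= os) start(up)[i] <- oe + 1L else
          end(up)[i] <- os - 1L
      } else {                            # tie: split at the midpoint
        mid <- (os + oe) %/% 2L
        if (start(up)[i] <= os && start(dn)[j] >= os) {
          end(up)[i] <- mid; start(dn)[j] <- mid + 1L
        } else if (start(dn)[j] <= os && start(up)[i] >= os) {
          end(dn)[j] <- mid; start(up)[i] <- mid + 1L
        }
      }
    }
    keepU <- width(up) > 0L & start(up) <= end(up)
    keepD <- width(dn) > 0L & start(dn) <= end(dn)
    peakL <- list(up[keepU], dn[keepD])
  }
  pk <- sort(do.call(c, peakL))
  new("DiffPeakSet", contrast = contrast, timepoint = as.numeric(timepoint),
      peaks = pk)
}

#' Differential peaks between two groups at one time point
#'
#' Convenience wrapper: pools each group's replicate fragment libraries,
#' counts sliding windows, applies the exact conditional binomial test,
#' and merges significant windows into directional peaks.
#'
#' @param libsA,libsB lists of \linkS4class{FragmentLibrary} (the
#'   replicates of group A and group B).
#' @param genome named vector of chromosome lengths.
#' @param config a \linkS4class{MarkConfig}.
#' @param contrast character of length 2 naming the groups.
#' @param timepoint time point in hours.
#' @return A \linkS4class{DiffPeakSet}.
#' @export
callDifferential <- function(libsA, libsB, genome, config = markConfig(),
                             contrast = c("A", "B"),
                             timepoint = NA_real_) {
  poolA <- poolFragments(libsA)
  poolB <- poolFragments(libsB)
  win <- slidingWindowCounts(poolA, poolB, genome,
                             config@diffWindowBp, config@diffStepBp)
  res <- testWindow(mcols(win)$countA, mcols(win)$countB,
                    metadata(win)$nA, metadata(win)$nB)
  mcols(win)$pvalue <- res$pvalue
  mcols(win)$direction <- res$direction
  mergeDifferential(win, config@diffPCutoff, config@diffGapBp,
                    contrast, timepoint)
}

#' Write differential peaks to BED6+
#'
#' Columns: chrom, start, end, contrast:timepoint, -log10(p), direction
#' (+/-), RPM A, RPM B.
#'
#' @param x a \linkS4class{DiffPeakSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDiffPeaksBed <- function(x, path) {
  gr <- x@peaks
  tag <- sprintf("%s.%s:%g", x@contrast[1], x@contrast[2], x@timepoint)
  .writeBed6Plus(gr, path, names = tag,
                 scores = round(-log10(pmax(mcols(gr)$pvalue, 1e-300)), 4),
                 strands = ifelse(mcols(gr)$direction > 0, "+", "-"),
                 extra = data.frame(rpmA = round(mcols(gr)$rpmA, 4),
                                    rpmB = round(mcols(gr)$rpmB, 4)))
}
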