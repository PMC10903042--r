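## Poisson island-based enrichment calling: tile the genome into
## fixed-width windows, flag windows whose fragment count is improbable
## under a uniform background, cluster flagged windows across short gaps,
## and test the resulting islands against the scaled input control.

#' Tile the genome and count fragments per window
#'
#' Each chromosome is tiled with non-overlapping windows of width
#' \code{windowBp} (the last window may be shorter). A fragment is counted
#' in every window it overlaps by at least 1 bp, so island counts are
#' additive over member windows. The uniform background rate per full
#' window is \eqn{\lambda_w = N W / (L f)} with N the library size, L the
#' total genome length and f the effective (mappable) genome fraction;
#' short edge windows get a proportionally scaled rate.
#'
#' @param frags a \linkS4class{FragmentLibrary}.
#' @param genome named vector of chromosome lengths.
#' @param windowBp window width in bp.
#' @param effectiveGenomeFraction mappable genome fraction in (0, 1].
#' @return A \code{GRanges} of windows with metadata columns \code{count}
#'   and \code{lambda}; \code{metadata()} records \code{librarySize},
#'   \code{windowBp} and \code{lambdaWindow} (the full-window rate).
#' @export
windowCounts <- function(frags, genome, windowBp = 200L,
                         effectiveGenomeFraction = 0.7) {
  windowBp <- as.integer(windowBp)
  if (windowBp < 1L) stop("windowBp must be >= 1")
  sl <- .genomeLengths(genome)
  if (!length(sl)) stop("empty genome map")
  si <- .asSeqinfo(genome)
  tiles <- lapply(names(sl), function(chr) {
    s <- seq.int(1L, sl[[chr]], by = windowBp)
    GRanges(chr, IRanges(s, pmin(s + windowBp - 1L, sl[[chr]])),
            seqinfo = si)
  })
  win <- do.call(c, tiles)
  n <- length(frags@fragments)
  L <- sum(sl)
  lamW <- n * windowBp / (L * effectiveGenomeFraction)
  mcols(win)$count <- countOverlaps(win, frags@fragments, minoverlap = 1L)
  mcols(win)$lambda <- lamW * width(win) / windowBp
  metadata(win) <- list(librarySize = n, windowBp = windowBp,
                        lambdaWindow = lamW)
  win
}

## smallest integer c0 with P(X >= c0; lambda) < p0, by direct evaluation
.poissonThreshold <- function(lambda, p0) {
  vapply(lambda, function(l) {
    if (l <= 0) return(1L)
    c0 <- 1L
    while (stats::ppois(c0 - 1L, l, lower.tail = FALSE) >= p0)
      c0 <- c0 + 1L
    c0
  }, integer(1))
}

#' Flag windows eligible to seed an island
#'
#' A window is eligible iff its count reaches \eqn{c_0}, the smallest
#' integer whose Poisson upper-tail probability under the background rate
#' falls below \code{p0} (boundary inclusive: count == c0 is eligible).
#'
#' @param track window \code{GRanges} from [windowCounts()].
#' @param p0 per-window probability threshold (default 0.2).
#' @return \code{track} with added logical column \code{eligible}.
#' @export
eligibleWindows <- function(track, p0 = 0.2) {
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
  lam <- mcols(track)$lambda
  if (all(lam <= 0))
    stop("background rate is zero (empty library): no calling possible")
  ulam <- unique(lam)
  c0 <- .poissonThreshold(ulam, p0)[match(lam, ulam)]
  mcols(track)$eligible <- mcols(track)$count >= c0
  track
}

#' Cluster eligible windows into candidate islands
#'
#' Maximal runs of eligible windows are joined across at most
#' \code{gapBp / windowBp} consecutive ineligible windows; each run becomes
#' one candidate interval spanning from its first to its last eligible
#' window.
#'
#' @param track window \code{GRanges} with an \code{eligible} column.
#' @param gapBp gap size in bp; must be a multiple of the window width.
#' @return A \code{GRanges} of candidate islands.
#' @export
clusterIslands <- function(track, gapBp = 200L) {
  W <- metadata(track)$windowBp
  gapBp <- as.integer(gapBp)
  if (gapBp %% W != 0L)
    stop("gapBp (", gapBp, ") must be a multiple of the window width (",
         W, ")")
  g <- gapBp %/% W
  out <- list()
  for (chr in unique(as.character(seqnames(track)))) {
    w <- track[seqnames(track) == chr]
    idx <- which(mcols(w)$eligible)
    if (!length(idx)) next
    brk <- which(diff(idx) - 1L > g)
    runStart <- idx[c(1L, brk + 1L)]
    runEnd <- idx[c(brk, length(idx))]
    out[[chr]] <- GRanges(chr, IRanges(start(w)[runStart], end(w)[runEnd]),
                          seqinfo = seqinfo(track))
  }
  if (!length(out)) return(GRanges(seqinfo = seqinfo(track)))
  sort(do.call(c, unname(out)))
}

#' Score candidate islands
#'
#' The island score aggregates the improbability of its eligible member
#' windows: \eqn{score = \sum -\ln P(X = count; \lambda_w)} over eligible
#' windows, evaluated under the Poisson background model. Ineligible
#' windows bridged by the gap rule contribute nothing.
#'
#' @param candidates island \code{GRanges} from [clusterIslands()].
#' @param track window \code{GRanges} with \code{eligible} flags.
#' @return \code{candidates} with an added \code{score} column.
#' @export
scoreIslands <- function(candidates, track) {
  elig <- track[mcols(track)$eligible]
  sc <- -stats::dpois(mcols(elig)$count, mcols(elig)$lambda, log = TRUE)
  hits <- findOverlaps(candidates, elig)
  tot <- rep(0, length(candidates))
  agg <- tapply(sc[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  mcols(candidates)$score <- tot
  candidates
}

#' Call enrichment islands against an input control
#'
#' Full island-calling pass for one ChIP library: windows are counted and
#' flagged under the Poisson background, clustered across gaps, scored,
#' and each candidate island is then tested against the input control: the
#' island's ChIP fragment count is compared to a Poisson expectation equal
#' to the input count scaled by the ChIP/input library-size ratio, floored
#' at the genome-background expectation for the island's width.
#' Benjamini-Hochberg correction is applied across islands and those at or
#' below the configured FDR are returned.
#'
#' @param chip ChIP \linkS4class{FragmentLibrary}.
#' @param input input-control \linkS4class{FragmentLibrary}.
#' @param genome named vector of chromosome lengths.
#' @param config a \linkS4class{MarkConfig}.
#' @return An \linkS4class{IslandSet}.
#' @export
callIslands <- function(chip, input, genome, config = markConfig()) {
  if (!length(chip@fragments)) stop("empty ChIP library")
  if (!length(input@fragments))
    stop("empty input control: island calling requires an input library ",
         "for the condition")
  track <- windowCounts(chip, genome, config@windowBp,
                        config@effectiveGenomeFraction)
  track <- eligibleWindows(track, config@eligibleWindowP)
  cand <- clusterIslands(track, config@gapBp)
  lamW <- metadata(track)$lambdaWindow
  if (!length(cand)) {
    empty <- GRanges(seqinfo = .asSeqinfo(genome))
    mcols(empty) <- DataFrame(score = numeric(0), chipCount = integer(0),
                              inputScaled = numeric(0), pvalue = numeric(0),
                              fdr = numeric(0))
    return(new("IslandSet", label = chip@label, islands = empty,
               lambdaWindow = lamW, config = config))
  }
  cand <- scoreIslands(cand, track)
  chipCount <- countOverlaps(cand, chip@fragments, minoverlap = 1L)
  inputCount <- countOverlaps(cand, input@fragments, minoverlap = 1L)
  ratio <- length(chip@fragments) / length(input@fragments)
  lambdaBp <- lamW / config@windowBp
  expected <- pmax(inputCount * ratio, lambdaBp * width(cand))
  p <- stats::ppois(chipCount - 1L, expected, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  keep <- fdr <= config@islandFdr
  isl <- cand[keep]
  mcols(isl) <- DataFrame(score = mcols(cand)$score[keep],
                          chipCount = chipCount[keep],
                          inputScaled = (inputCount * ratio)[keep],
                          pvalue = p[keep], fdr = fdr[keep])
  new("IslandSet", label = chip@label, islands = sort(isl),
      lambdaWindow = lamW, config = config)
}

#' Write an island set to BED6+
#'
#' Columns: chrom, start, end, island id, score, ".", ChIP count, scaled
#' input count, p-value, FDR.
#'
#' @param x an \linkS4class{IslandSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIslandsBed <- function(x, path) {
  gr <- x@islands
  .writeBed6Plus(gr, path,
                 names = sprintf("island%d", seq_along(gr)),
                 scores = round(mcols(gr)$score, 4),
                 extra = data.frame(chip = mcols(gr)$chipCount,
                                    input = round(mcols(gr)$inputScaled, 3),
                                    p = signif(mcols(gr)$pvalue, 6),
                                    fdr = signif(mcols(gr)$fdr, 6)))
}
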