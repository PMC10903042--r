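## End-to-end convenience: differential calling over all contrasts/time
## points the factorial rules require, region universe construction, and
## classification of the three stress classes.

.groupLibs <- function(libs, condition, timepoint) {
  sel <- vapply(libs, function(x)
    x@label@role == "chip" && x@label@condition == condition &&
      !is.na(x@label@timepoint) && x@label@timepoint == timepoint,
    logical(1))
  libs[sel]
}

#' Contrast/time point grid required by the factorial rules
#'
#' DT vs C and DTHT vs C at every time point, DTHT vs DT at the 0- and
#' 72-h baselines of the heat rule.
#'
#' @return A data.frame with columns \code{A}, \code{B}, \code{timepoint}.
#' @export
requiredContrasts <- function() {
  rbind(data.frame(A = "DT", B = "C", timepoint = STRESS_TIMEPOINTS),
        data.frame(A = "DTHT", B = "C", timepoint = STRESS_TIMEPOINTS),
        data.frame(A = "DTHT", B = "DT", timepoint = c(0, 72)))
}

#' Run differential calling and stress classification
#'
#' Pools replicates per (condition, time point), calls differential peaks
#' for every required contrast, merges all peaks into the region universe,
#' and applies the three factorial rules.
#'
#' @param libs named list of \linkS4class{FragmentLibrary} (e.g. from
#'   [loadExperiment()] or [simulateExperiment()]).
#' @param genome named vector of chromosome lengths.
#' @param config a \linkS4class{MarkConfig}.
#' @param contrasts data.frame as from [requiredContrasts()].
#' @return A list with \code{peaksets} (list of
#'   \linkS4class{DiffPeakSet}), \code{universe}
#'   (\linkS4class{RegionUniverse}) and \code{responsive} (named list of
#'   \linkS4class{ResponsiveSet}).
#' @export
runStressPipeline <- function(libs, genome, config = markConfig(),
                              contrasts = requiredContrasts()) {
  peaksets <- lapply(seq_len(nrow(contrasts)), function(i) {
    A <- contrasts$A[i]; B <- contrasts$B[i]; tp <- contrasts$timepoint[i]
    libsA <- .groupLibs(libs, A, tp)
    libsB <- .groupLibs(libs, B, tp)
    if (!length(libsA) || !length(libsB))
      stop("no libraries for contrast ", A, " vs ", B, " at ", tp, " h")
    callDifferential(libsA, libsB, genome, config, c(A, B), tp)
  })
  universe <- buildRegionUniverse(peaksets)
  responsive <- lapply(c(DT = "DT", DTHT = "DTHT", HT = "HT"),
                       function(cls) classifyResponsive(universe, cls))
  list(peaksets = peaksets, universe = universe, responsive = responsive)
}
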