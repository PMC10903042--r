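## Relative expression by the 2^-ddCT method with a constitutive reference
## gene (cons7 in this assay): dCT = CT_gene - CT_reference within each
## condition, ddCT = dCT_sample - dCT_calibrator, fold = 2^-ddCT.

.ctFor <- function(ct, gene, sample) {
  rows <- ct[ct$gene == gene & ct$sample == sample, , drop = FALSE]
  rows[order(rows$replicate), , drop = FALSE]
}

#' Relative expression by 2^-ddCT
#'
#' Computes per-replicate fold changes of a target gene in a sample
#' relative to a calibrator condition, normalized to a reference gene
#' measured in the same conditions. Replicates are paired by replicate
#' index between sample and calibrator; the gene and the reference must be
#' measured for the same replicate indices in both conditions. The
#' standard error is computed on the per-replicate fold changes
#' (sd / sqrt(n)).
#'
#' @param ct data.frame with columns \code{gene}, \code{sample},
#'   \code{replicate}, \code{ct}.
#' @param gene target gene id.
#' @param sample sample (condition) label to quantify.
#' @param calibrator calibrator sample label (the baseline condition).
#' @param reference reference gene id (default \code{"cons7"}).
#' @return A list with \code{fold} (per-replicate fold changes),
#'   \code{mean}, \code{se}, and \code{ddct} (per-replicate ddCT values).
#' @examples
#' ct <- data.frame(
#'   gene = rep(c("geneX", "cons7"), each = 2),
#'   sample = rep(c("DT96", "C0"), 2),
#'   replicate = 1, ct = c(24, 26, 22, 22))
#' relativeExpression(ct, "geneX", "DT96", "C0")$mean  # 4
#' @export
relativeExpression <- function(ct, gene, sample, calibrator,
                               reference = "cons7") {
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("CT table must have columns ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0)) stop("CT values must be positive")
  pieces <- list(geneS = .ctFor(ct, gene, sample),
                 refS = .ctFor(ct, reference, sample),
                 geneC = .ctFor(ct, gene, calibrator),
                 refC = .ctFor(ct, reference, calibrator))
  if (!nrow(pieces$refS) || !nrow(pieces$refC))
    stop("reference gene '", reference, "' missing for sample or calibrator")
  if (!nrow(pieces$geneS) || !nrow(pieces$geneC))
    stop("gene '", gene, "' not measured in both sample and calibrator")
  reps <- lapply(pieces, function(p) p$replicate)
  if (!all(vapply(reps[-1], identical, logical(1), reps[[1]])))
    stop("replicate indices differ between gene/reference or ",
         "sample/calibrator; cannot pair replicates")
  dctS <- pieces$geneS$ct - pieces$refS$ct
  dctC <- pieces$geneC$ct - pieces$refC$ct
  ddct <- dctS - dctC
  fold <- 2^(-ddct)
  n <- length(fold)
  se <- if (n > 1) stats::sd(fold) / sqrt(n) else NA_real_
  list(fold = fold, mean = mean(fold), se = se, ddct = ddct)
}

#' Relative expression for every gene/sample combination
#'
#' Applies [relativeExpression()] to each non-reference gene and each
#' non-calibrator sample in a CT table.
#'
#' @inheritParams relativeExpression
#' @return A data.frame with columns \code{gene}, \code{sample},
#'   \code{mean}, \code{se}.
#' @export
relativeExpressionTable <- function(ct, calibrator, reference = "cons7") {
  genes <- setdiff(unique(ct$gene), reference)
  samples <- setdiff(unique(ct$sample), calibrator)
  rows <- lapply(genes, function(g) {
    do.call(rbind, lapply(samples, function(s) {
      r <- relativeExpression(ct, g, s, calibrator, reference)
      data.frame(gene = g, sample = s, mean = r$mean, se = r$se,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
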