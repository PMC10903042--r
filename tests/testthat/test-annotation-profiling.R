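baseAnn <- function() {
  # + strand gene 10001..14000 with 5'UTR/CDS/intron/3'UTR, - strand gene
  # 30001..34000; one repeat overlapping the first CDS
  genes <- data.frame(start = c(10001, 30001), end = c(14000, 34000),
                      strand = c("+", "-"), gene_id = c("gA", "gB"))
  features <- data.frame(
    start = c(10001, 10301, 11501, 13501, 33501, 30001),
    end = c(10300, 11200, 13500, 14000, 34000, 30500),
    strand = c("+", "+", "+", "+", "-", "-"),
    type = c("five_prime_UTR", "CDS", "intron", "three_prime_UTR",
             "five_prime_UTR", "three_prime_UTR"),
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB"))
  repeats <- data.frame(start = c(10500, 60001), end = c(10800, 62000))
  mkAnnotation(100000, genes, features, repeats)
}

peakAt <- function(mid, w = 200) {
  GRanges("chr1", IRanges(mid - w / 2, mid + w / 2 - 1),
          seqinfo = GenomeInfoDb::Seqinfo("chr1", 100000))
}

test_that("feature classification follows the precedence order", {
  ann <- baseAnn()
  # midpoint inside both a CDS and a repeat: the genic class wins
  expect_equal(as.character(classifyFeature(peakAt(10600), ann)), "CDS")
  expect_equal(as.character(classifyFeature(peakAt(10100), ann)),
               "five_prime_UTR")
  expect_equal(as.character(classifyFeature(peakAt(12000), ann)), "intron")
  expect_equal(as.character(classifyFeature(peakAt(13700), ann)),
               "three_prime_UTR")
  # 1,500 bp 5' of the + strand TSS, no other overlap: upstream
  expect_equal(as.character(classifyFeature(peakAt(10001 - 1500), ann)),
               "upstream")
  # strand-aware: upstream of the - strand gene lies right of its end
  expect_equal(as.character(classifyFeature(peakAt(34000 + 1500), ann)),
               "upstream")
  expect_equal(as.character(classifyFeature(peakAt(14000 + 1500), ann)),
               "downstream")
  expect_equal(as.character(classifyFeature(peakAt(30001 - 1500), ann)),
               "downstream")
  expect_equal(as.character(classifyFeature(peakAt(61000), ann)),
               "repeat")
  expect_equal(as.character(classifyFeature(peakAt(80000), ann)),
               "intergenic")
  expect_error(classifyFeature(GRanges("chrZ", IRanges(1, 10)), ann),
               "unknown")
})

test_that("every peak receives exactly one label", {
  set.seed(8)
  ann <- baseAnn()
  mids <- sample.int(99000, 300)
  labs <- classifyFeature(peakAt(mids), ann)
  expect_equal(length(labs), 300L)
  expect_false(anyNA(labs))
})

test_that("feature summaries reproduce the printed contrast tables", {
  for (contrast in names(TABLE2)) {
    fs <- summarizeFeatures(TABLE2[[contrast]])
    expect_equal(sum(fs$count), unname(TABLE2_TOTALS[contrast]))
    expect_equal(sum(fs$percent), 100, tolerance = 0.05)
  }
  dt <- summarizeFeatures(TABLE2[["DT.C"]])
  expect_equal(dt$percent[dt$feature == "CDS"], 9.81)
  expect_equal(dt$percent[dt$feature == "repeat"], 54.86)
  hd <- summarizeFeatures(TABLE2[["DTHT.DT"]])
  expect_equal(hd$percent[hd$feature == "CDS"], 11.66)
  # degenerate one-class input
  one <- summarizeFeatures(factor("CDS", levels = levels(
    classifyFeature(peakAt(10600), baseAnn()))))
  expect_equal(one$percent[one$feature == "CDS"], 100)
  expect_error(summarizeFeatures(character(0)), "summarize")
})

test_that("nearest-TSS distances are signed by transcription orientation", {
  ann <- baseAnn()
  pointAt <- function(pos)
    GRanges("chr1", IRanges(pos, pos),
            seqinfo = GenomeInfoDb::Seqinfo("chr1", 100000))
  expect_equal(nearestTssDistance(pointAt(10001), ann)$distance, 0)
  d <- nearestTssDistance(pointAt(10501), ann)
  expect_equal(d$distance, 500)
  expect_equal(d$gene_id, "gA")
  # minus strand: midpoint 500 bp left of the TSS is downstream (+500)
  expect_equal(nearestTssDistance(pointAt(33500), ann)$distance, 500)
  expect_equal(nearestTssDistance(pointAt(34500), ann)$distance, -500)
  # equidistant genes break ties lexicographically
  genes <- data.frame(start = c(1000, 3000), end = c(1999, 3999),
                      strand = "+", gene_id = c("gZ", "gA"))
  ann2 <- mkAnnotation(10000, genes)
  tie <- nearestTssDistance(pointAt(2000), ann2)
  expect_equal(tie$gene_id, "gA")
})

test_that("the TSS metaprofile is orientation-aligned and in RPM", {
  ann <- baseAnn()
  si <- GenomeInfoDb::Seqinfo("chr1", 100000)
  empty <- new("FragmentLibrary", label = libraryLabel("C", 0, 1),
               fragments = GRanges(seqinfo = si))
  expect_true(all(tssMetaprofile(empty, ann)$rpm == 0))
  # one fragment 100..400 bp downstream of each TSS (both strands)
  fr <- new("FragmentLibrary", label = libraryLabel("C", 0, 1),
            fragments = GRanges("chr1",
              IRanges(c(10101, 33601), c(10400, 33900)), seqinfo = si))
  prof <- tssMetaprofile(fr, ann, flankBp = 2000, binBp = 100)
  expect_equal(nrow(prof), 40L)
  up <- prof$rpm[prof$offset < 0]
  expect_true(all(up == 0))
  # bins [100,200),[200,300),[300,400) each see both fragments:
  # 2 fragments / 2 genes * 1e6 / 2 fragments = 5e5 RPM
  hot <- prof$rpm[prof$offset %in% c(100, 200, 300)]
  expect_equal(hot, rep(5e5, 3))
  expect_error(tssMetaprofile(fr, ann, flankBp = 2050, binBp = 100),
               "multiple")
})

test_that("gene overlap honors the 2-kb flank and counts asymmetry", {
  ann <- baseAnn()
  # region 500 bp past the + gene end: linked through the flank
  r1 <- peakAt(14000 + 500, w = 100)
  expect_equal(nrow(overlapWithGenes(r1, ann)$links), 1L)
  # region 2,500 bp past the gene end: outside the flank
  r2 <- GRanges("chr1", IRanges(16501, 16700),
                seqinfo = GenomeInfoDb::Seqinfo("chr1", 100000))
  expect_equal(nrow(overlapWithGenes(r2, ann)$links), 0L)
  # two regions over one gene: 2 links, 2 regions, 1 gene
  both <- c(peakAt(10500), peakAt(12500))
  ov <- overlapWithGenes(both, ann)
  expect_equal(nrow(ov$links), 2L)
  expect_equal(ov$nRegions, 2L)
  expect_equal(ov$nGenes, 1L)
})

test_that("chromosome densities and ratios are computed per Mb", {
  genome <- c(chr1 = 1e6, chr2 = 1e6)
  si <- GenomeInfoDb::Seqinfo(c("chr1", "chr2"), c(1e6, 1e6))
  none <- GRanges(seqinfo = si)
  expect_true(all(chromosomeDensity(none, genome)$density == 0))
  peaks <- GRanges(rep(c("chr1", "chr2"), c(8, 2)),
                   IRanges(seq(1, by = 1000, length.out = 10),
                           width = 100), seqinfo = si)
  cd <- chromosomeDensity(peaks, genome)
  expect_equal(cd$ratio, c(1.6, 0.4))
  expect_equal(cd$density, c(8, 2))
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  pop <- sprintf("g%02d", 1:20)
  res <- hypergeomEnrichment(pop[1:5], pop,
                             list(term1 = pop[1:5], all = pop))
  t1 <- res[res$term == "term1", ]
  expect_equal(t1$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(t1$fold, 4)
  allRow <- res[res$term == "all", ]
  expect_equal(allRow$fold, 1)
  expect_equal(allRow$pvalue, 1)
  expect_false(allRow$significant)
  expect_error(hypergeomEnrichment(c(pop[1], "ghost"), pop,
                                   list(a = pop)), "subset")
})

test_that("enrichment p-values equal brute-force tail enumeration", {
  # small populations: sum the hypergeometric pmf directly
  set.seed(12)
  pop <- sprintf("g%02d", 1:25)
  for (rep in 1:20) {
    study <- sample(pop, sample(3:10, 1))
    term <- sample(pop, sample(2:12, 1))
    res <- hypergeomEnrichment(study, pop, list(t = term))
    k <- length(intersect(study, term)); K <- length(term)
    n <- length(study); N <- length(pop)
    brute <- sum(vapply(k:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
    expect_equal(res$pvalue, brute, tolerance = 1e-9)
  }
})

test_that("both significance conditions are required", {
  # fold > 1.3 with weak p: not significant
  pop <- sprintf("g%03d", 1:200)
  term <- pop[1:100]
  study <- c(pop[1:7], pop[101:105])   # fold = (7/12)/(100/200) = 1.17
  res <- hypergeomEnrichment(study, pop, list(t = term))
  expect_false(res$significant)
})

test_that("the MapMan matrix encodes direction with the {0,1,-1} scheme", {
  genes <- c("g1", "g2", "g3", "g4")
  links <- data.frame(gene_id = c("g2", "g3", "g3"),
                      direction = c(1L, 1L, -1L),
                      pvalue = c(1e-3, 1e-6, 1e-3))
  mm <- mapmanExport(list(DT = links), genes)
  expect_equal(mm$DT, c(0L, 1L, 1L, 0L))  # conflict: smaller p wins
  lossy <- data.frame(gene_id = "g4", direction = -1L, pvalue = 1e-2)
  mm2 <- mapmanExport(list(HT = lossy), genes)
  expect_equal(mm2$HT, c(0L, 0L, 0L, -1L))
  dir <- tempfile()
  paths <- writeMapman(mm, dir)
  expect_true(file.exists(file.path(dir, "mapman_DT.txt")))
  tab <- read.table(file.path(dir, "mapman_DT.txt"), header = TRUE)
  expect_equal(tab$VALUE, c(0L, 1L, 1L, 0L))
})
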