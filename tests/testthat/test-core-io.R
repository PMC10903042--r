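genome <- c(chr1 = 100000)

writeBedLines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

test_that("BED reads are reduced to strand-aware 5' ends", {
  path <- writeBedLines(c("chr1\t100\t250\tr1\t0\t-",
                          "chr1\t500\t800\tr2\t0\t+",
                          "chr1\t900\t1200\tr3\t0\t+"))
  lib <- readBedReads(path, genome)
  expect_equal(length(lib@reads), 3L)
  minus <- lib@reads[as.character(strand(lib@reads)) == "-"]
  # record chr1 100 250 on "-": 5' end at 0-based 249 = 1-based 250
  expect_equal(start(minus), 250L)
  plus <- lib@reads[as.character(strand(lib@reads)) == "+"]
  expect_equal(start(plus), c(501L, 901L))
})

test_that("BED reading rejects bad inputs", {
  p1 <- writeBedLines("chrZ\t10\t20\tr1\t0\t+")
  expect_error(readBedReads(p1, genome), "chrZ")
  p2 <- writeBedLines("chr1\t10\t20")
  expect_error(readBedReads(p2, genome), "strand")
  p3 <- writeBedLines("chr1\t10")
  expect_error(readBedReads(p3, genome), "line 1")
  expect_error(readBedReads(tempfile(), genome), "no such")
})

test_that("BED round-trip preserves positions and strands", {
  set.seed(31)
  p5 <- sample.int(99000, 50)
  str <- sample(c("+", "-"), 50, replace = TRUE)
  si <- GenomeInfoDb::Seqinfo("chr1", 100000)
  lib <- new("ReadLibrary", label = libraryLabel("DT", 96, 2),
             reads = sort(GRanges("chr1", IRanges(p5, width = 1),
                                  strand = str, seqinfo = si)))
  path <- tempfile(fileext = ".bed")
  writeReadsBed(lib, path)
  back <- readBedReads(path, genome, lib@label)
  expect_identical(start(back@reads), start(lib@reads))
  expect_identical(as.character(strand(back@reads)),
                   as.character(strand(lib@reads)))
})

gffFixture <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 100000",
    "chr1\ttest\tgene\t5001\t6000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tmRNA\t5001\t6000\t.\t+\t.\tID=geneA.1;Parent=geneA",
    "chr1\ttest\texon\t5001\t5200\t.\t+\t.\tParent=geneA.1",
    "chr1\ttest\texon\t5401\t6000\t.\t+\t.\tParent=geneA.1",
    "chr1\ttest\tCDS\t5001\t5200\t.\t+\t.\tParent=geneA.1",
    "chr1\ttest\tCDS\t5401\t6000\t.\t+\t.\tParent=geneA.1",
    "chr1\ttest\tgene\t8001\t9000\t.\t-\t.\tID=geneB",
    "chr1\ttest\tmRNA\t8001\t9000\t.\t-\t.\tID=geneB.1;Parent=geneB",
    "chr1\ttest\texon\t8001\t9000\t.\t-\t.\tParent=geneB.1",
    "chr1\ttest\tfive_prime_UTR\t8801\t9000\t.\t-\t.\tParent=geneB.1"),
    path)
  path
}

test_that("GFF3 gene models convert coordinates and derive structure", {
  ann <- readGff3Genes(gffFixture(), genome = genome)
  g <- ann@genes
  a <- g[mcols(g)$gene_id == "geneA"]
  # 1-based closed 5001..6000 spans 1000 bp; TSS at the + strand start
  expect_equal(c(start(a), end(a), width(a)), c(5001L, 6000L, 1000L))
  expect_equal(mcols(a)$tss, 5001)
  b <- g[mcols(g)$gene_id == "geneB"]
  expect_equal(mcols(b)$tss, 9000)      # minus strand: TSS at gene end
  expect_equal(mcols(b)$tes, 8001)
  # intron between exons 5001..5200 and 5401..6000
  intr <- ann@features[mcols(ann@features)$type == "intron"]
  expect_equal(length(intr), 1L)
  expect_equal(c(start(intr), end(intr)), c(5201L, 5400L))
  # widths match GFF3 end - start + 1 for every sub-feature
  cds <- ann@features[mcols(ann@features)$type == "CDS"]
  expect_equal(sort(width(cds)), c(200L, 600L))
})

test_that("orphan children are skipped with a warning", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t100\t400\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t100\t400\t.\t+\t.\tID=g1.1;Parent=g1",
               "chr1\tt\texon\t100\t400\t.\t+\t.\tParent=g1.1",
               "chr1\tt\texon\t500\t700\t.\t+\t.\tParent=ghost.1"),
             path)
  expect_warning(ann <- readGff3Genes(path, genome = genome),
                 "resolvable")
  expect_equal(length(ann@genes), 1L)
})

test_that("deduplication keeps at most the threshold per position", {
  si <- GenomeInfoDb::Seqinfo("chr1", 100000)
  dup <- GRanges("chr1", IRanges(rep(500L, 5), width = 1), strand = "+",
                 seqinfo = si)
  lib <- new("ReadLibrary", label = libraryLabel("C", 0, 1), reads = dup)
  expect_equal(length(deduplicateReads(lib, 1)@reads), 1L)
  expect_equal(length(deduplicateReads(lib, 3)@reads), 3L)
  # distinct positions, or the same position on opposite strands, survive
  mix <- GRanges("chr1", IRanges(c(500L, 500L, 900L), width = 1),
                 strand = c("+", "-", "+"), seqinfo = si)
  lib2 <- new("ReadLibrary", label = libraryLabel("C", 0, 1), reads = mix)
  expect_equal(length(deduplicateReads(lib2, 1)@reads), 3L)
  # idempotent and order-independent
  set.seed(11)
  pos <- sample.int(1000, 200, replace = TRUE)
  shuf <- sample(200)
  libA <- new("ReadLibrary", label = libraryLabel("C", 0, 1),
              reads = GRanges("chr1", IRanges(pos, width = 1),
                              strand = "+", seqinfo = si))
  libB <- new("ReadLibrary", label = libraryLabel("C", 0, 1),
              reads = GRanges("chr1", IRanges(pos[shuf], width = 1),
                              strand = "+", seqinfo = si))
  d1 <- deduplicateReads(libA, 1)
  expect_identical(granges(deduplicateReads(d1, 1)@reads),
                   granges(d1@reads))
  expect_identical(start(deduplicateReads(libB, 1)@reads), start(d1@reads))
})

test_that("fragment extension is strand-mirrored and clipped", {
  si <- GenomeInfoDb::Seqinfo("chr1", 100000)
  reads <- GRanges("chr1", IRanges(c(1001L, 1001L), width = 1),
                   strand = c("+", "-"), seqinfo = si)
  lib <- new("ReadLibrary", label = libraryLabel("C", 0, 1), reads = reads)
  fr <- extendReads(lib, 300)@fragments
  plus <- fr[as.character(strand(fr)) == "+"]
  minus <- fr[as.character(strand(fr)) == "-"]
  # 0-based: + read at 1000 -> [1000,1300); - read at 1000 -> [701,1001)
  expect_equal(c(start(plus), end(plus)), c(1001L, 1300L))
  expect_equal(c(start(minus), end(minus)), c(702L, 1001L))
  # clipping at the chromosome edge keeps the fragment count
  siShort <- GenomeInfoDb::Seqinfo("chr1", 200)
  near <- new("ReadLibrary", label = libraryLabel("C", 0, 1),
              reads = GRanges("chr1", IRanges(11L, width = 1),
                              strand = "+", seqinfo = siShort))
  clipped <- extendReads(near, 300)@fragments
  expect_equal(length(clipped), 1L)
  expect_equal(c(start(clipped), end(clipped)), c(11L, 200L))
})

test_that("manifest-driven loading reproduces simulated fragments", {
  dir <- tempfile()
  sp <- truthSpec(genome = c(chrA = 50000), nGenes = 8,
                  islandsPerClass = c(DT = 1L, DTHT = 1L, HT = 1L,
                                      constitutive = 1L),
                  islandWidthBp = 800, seed = 3)
  sim <- simulateExperiment(sp, dir)
  manifest <- readManifest(file.path(dir, "manifest.tsv"))
  libs <- loadExperiment(manifest[1:4, ], c(chrA = 50000))
  for (i in 1:4) {
    orig <- sim$libraries[[names(libs)[i]]]@fragments
    expect_identical(granges(libs[[i]]@fragments), granges(orig))
  }
})
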