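mkPeakSet <- function(contrast, tp, starts, ends, dirs = 1L,
                      pvals = 1e-4, genomeLen = 100000) {
  si <- GenomeInfoDb::Seqinfo("chr1", genomeLen)
  pk <- GRanges("chr1", IRanges(starts, ends), seqinfo = si)
  mcols(pk)$direction <- as.integer(rep_len(dirs, length(pk)))
  mcols(pk)$pvalue <- rep_len(pvals, length(pk))
  mcols(pk)$rpmA <- 1; mcols(pk)$rpmB <- 1
  new("DiffPeakSet", contrast = contrast, timepoint = tp, peaks = pk)
}

test_that("the region universe merges peaks by single linkage", {
  one <- buildRegionUniverse(list(mkPeakSet(c("DT", "C"), 96, 100, 299)))
  expect_equal(length(one@regions), 1L)
  expect_true(one@isDiff[1, ctKey("DT", "C", 96)])
  # overlapping peaks from different time points become one region
  two <- buildRegionUniverse(list(
    mkPeakSet(c("DT", "C"), 96, 101, 300),
    mkPeakSet(c("DT", "C"), 120, 251, 500)))
  expect_equal(length(two@regions), 1L)
  expect_equal(c(start(two@regions), end(two@regions)), c(101L, 500L))
  expect_true(all(two@isDiff[1, ]))
  # transitive chain merges into a single region
  chain <- buildRegionUniverse(list(
    mkPeakSet(c("DT", "C"), 96, c(1, 151, 301), c(200, 350, 500))))
  expect_equal(length(chain@regions), 1L)
  expect_equal(end(chain@regions), 500L)
  # touching but non-overlapping peaks stay separate regions
  apart <- buildRegionUniverse(list(
    mkPeakSet(c("DT", "C"), 96, c(1, 201), c(200, 400))))
  expect_equal(length(apart@regions), 2L)
})

test_that("membership direction comes from the smallest-p overlapping peak", {
  ps1 <- mkPeakSet(c("DT", "C"), 96, 100, 300, dirs = 1L, pvals = 1e-3)
  ps2 <- mkPeakSet(c("DT", "C"), 120, c(100, 250), c(220, 400),
                   dirs = c(1L, -1L), pvals = c(1e-2, 1e-6))
  u <- buildRegionUniverse(list(ps1, ps2))
  expect_equal(length(u@regions), 1L)
  expect_equal(unname(u@direction[1, ctKey("DT", "C", 120)]), -1L)
  expect_equal(unname(u@direction[1, ctKey("DT", "C", 96)]), 1L)
})

## brute-force rule evaluation on a membership pattern
bruteRule <- function(cls, pattern) {
  # pattern: named logical over the keys the rule inspects
  if (cls == "DT") {
    base <- pattern[ctKey("DT", "C", 0)]
    sup <- pattern[vapply(c(72, 96, 120, 144, 168), function(tp)
      ctKey("DT", "C", tp), character(1))]
  } else if (cls == "DTHT") {
    base <- pattern[ctKey("DTHT", "C", 0)]
    sup <- pattern[vapply(c(72, 96, 120, 144, 168), function(tp)
      ctKey("DTHT", "C", tp), character(1))]
  } else {
    base <- pattern[ctKey("DTHT", "DT", 0)] |
      pattern[ctKey("DTHT", "DT", 72)]
    sup <- pattern[vapply(c(96, 120, 144, 168), function(tp)
      ctKey("DTHT", "C", tp), character(1))]
  }
  !any(base) && any(sup)
}

allKeys <- c(vapply(c(0, 72, 96, 120, 144, 168), function(tp)
               ctKey("DT", "C", tp), character(1)),
             vapply(c(0, 72, 96, 120, 144, 168), function(tp)
               ctKey("DTHT", "C", tp), character(1)),
             ctKey("DTHT", "DT", 0), ctKey("DTHT", "DT", 72))

test_that("DT and DTHT classifications match exhaustive enumeration", {
  for (cls in c("DT", "DTHT")) {
    keys <- vapply(c(0, 72, 96, 120, 144, 168), function(tp)
      ctKey(cls, "C", tp), character(1))
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))
    isDiff <- matrix(FALSE, nrow(grid), length(allKeys),
                     dimnames = list(NULL, allKeys))
    isDiff[, keys] <- grid
    u <- mkUniverse(isDiff)
    got <- overlapsAny(u@regions, classifyResponsive(u, cls)@regions)
    want <- apply(isDiff, 1, function(p) bruteRule(cls, p))
    expect_identical(got, unname(want))
  }
})

test_that("HT classification matches exhaustive enumeration", {
  baseKeys <- c(ctKey("DTHT", "DT", 0), ctKey("DTHT", "DT", 72))
  supKeys <- vapply(c(96, 120, 144, 168), function(tp)
    ctKey("DTHT", "C", tp), character(1))
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))
  isDiff <- matrix(FALSE, nrow(grid), length(allKeys),
                   dimnames = list(NULL, allKeys))
  isDiff[, c(baseKeys, supKeys)] <- grid
  # DTHT.C at 72 h varies too: it must not influence the HT rule
  isDiff[, ctKey("DTHT", "C", 72)] <- rep(c(FALSE, TRUE),
                                          length.out = nrow(grid))
  u <- mkUniverse(isDiff)
  got <- overlapsAny(u@regions, classifyResponsive(u, "HT")@regions)
  want <- apply(isDiff, 1, function(p) bruteRule("HT", p))
  expect_identical(got, unname(want))
})

test_that("rule examples behave as stated", {
  keysDT <- vapply(c(0, 72, 96, 120, 144, 168), function(tp)
    ctKey("DT", "C", tp), character(1))
  isDiff <- matrix(FALSE, 3, length(allKeys),
                   dimnames = list(NULL, allKeys))
  # region 1: differential at 0 h and 96 h -> excluded by the baseline
  isDiff[1, c(keysDT[1], keysDT[3])] <- TRUE
  # region 2: differential only at 96 h -> DT-responsive
  isDiff[2, keysDT[3]] <- TRUE
  # region 3: never differential -> no class
  u <- mkUniverse(isDiff)
  dt <- classifyResponsive(u, "DT")
  expect_identical(unname(overlapsAny(u@regions, dt@regions)),
                   c(FALSE, TRUE, FALSE))
  expect_equal(length(classifyResponsive(u, "DTHT")@regions), 0L)
  expect_equal(length(classifyResponsive(u, "HT")@regions), 0L)
  # HT example: clean DTHT-vs-DT baseline, DTHT-vs-C support at 120 h
  isDiff2 <- matrix(FALSE, 1, length(allKeys),
                    dimnames = list(NULL, allKeys))
  isDiff2[1, ctKey("DTHT", "C", 120)] <- TRUE
  u2 <- mkUniverse(isDiff2)
  expect_equal(length(classifyResponsive(u2, "HT")@regions), 1L)
})

test_that("direction and supporting time points are recorded", {
  keysDT <- vapply(c(0, 72, 96, 120, 144, 168), function(tp)
    ctKey("DT", "C", tp), character(1))
  isDiff <- matrix(FALSE, 1, length(allKeys),
                   dimnames = list(NULL, allKeys))
  isDiff[1, keysDT[c(3, 5)]] <- TRUE       # 96 h and 144 h
  direction <- matrix(0L, 1, length(allKeys),
                      dimnames = list(NULL, allKeys))
  direction[1, keysDT[3]] <- -1L
  direction[1, keysDT[5]] <- 1L
  u <- mkUniverse(isDiff, direction)
  dt <- classifyResponsive(u, "DT")
  expect_equal(mcols(dt@regions)$timepoints, "96,144")
  expect_equal(mcols(dt@regions)$direction, -1L)  # earliest support wins
})

test_that("a universe missing required keys is a hard error", {
  isDiff <- matrix(FALSE, 1, 2,
                   dimnames = list(NULL, c(ctKey("DT", "C", 0),
                                           ctKey("DT", "C", 96))))
  u <- mkUniverse(isDiff)
  expect_error(classifyResponsive(u, "DT"), "DT.C:72")
  expect_error(classifyResponsive(u, "HT"), "DTHT")
})
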