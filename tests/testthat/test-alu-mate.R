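model <- gaussianInsertModel(400, 50)

test_that("improper pairs are flagged by mate, chromosome, orientation and size", {
  proper <- makePair(start1 = 1000, end1 = 1100, start2 = 1300, end2 = 1400)
  expect_false(isImproperPair(proper, model))
  ## insert 900 exceeds the 0.995 quantile (~529) of N(400, 50)
  long <- makePair(start1 = 1000, end1 = 1100, start2 = 1800, end2 = 1900)
  expect_true(isImproperPair(long, model))
  short <- makePair(start1 = 1000, end1 = 1100, start2 = 1050, end2 = 1150)
  expect_true(isImproperPair(short, model))
  unm <- makePair(mapped2 = FALSE, start2 = NA, end2 = NA, isize = NA)
  expect_true(isImproperPair(unm, model))
  diffChrom <- makePair(chrom2 = "sim2", isize = NA)
  expect_true(isImproperPair(diffChrom, model))
  sameStrand <- makePair(strand2 = "+")
  expect_true(isImproperPair(sameStrand, model))
})

test_that("the scan emits one labelled mate per anchored Alu end", {
  set.seed(20)
  lib <- syntheticAluLibrary(2, 300)
  aluRead <- substr(as.character(lib@sequences[[1]]), 51, 150)
  pairs <- makePairs(
    makePair(start1 = 500, end1 = 600, start2 = 800, end2 = 900),  # proper
    makePair(start1 = 10000, end1 = 10100, strand1 = "+",
             mapped2 = FALSE, start2 = NA, end2 = NA, strand2 = "-",
             b2 = NA_integer_, seq2 = aluRead, isize = NA),        # l mate
    makePair(start1 = 20000, end1 = 20100, strand1 = "-",
             mapped2 = FALSE, start2 = NA, end2 = NA, strand2 = "+",
             b2 = NA_integer_, seq2 = aluRead, isize = NA))        # r mate
  res <- scanAluMates(pairs, lib, model)
  m <- aluMates(res)
  expect_equal(nrow(m), 2L)
  expect_equal(m$label[m$start == 10000], "l")
  expect_equal(m$label[m$start == 20000], "r")
  expect_equal(m$at, c(50L, 50L))
  expect_equal(m$alu, rep(names(lib@sequences)[1], 2))
  cnt <- mateCounts(res)
  expect_equal(cnt[["readsSeen"]], 2L * nrow(pairs))
  expect_equal(cnt[["improperPairs"]], 2L)
  expect_lte(cnt[["aluMates"]], cnt[["improperPairs"]])
})

test_that("pairs without a unique anchor or with two Alu ends emit nothing", {
  set.seed(21)
  lib <- syntheticAluLibrary(1, 300)
  aluRead <- substr(as.character(lib@sequences[[1]]), 1, 100)
  bothAlu <- makePairs(
    makePair(mapped1 = FALSE, start1 = NA, end1 = NA, b1 = NA_integer_,
             seq1 = aluRead, mapped2 = FALSE, start2 = NA, end2 = NA,
             b2 = NA_integer_, seq2 = aluRead, isize = NA))
  expect_equal(nrow(aluMates(scanAluMates(bothAlu, lib, model))), 0L)
  multiAnchor <- makePairs(
    makePair(start1 = 1000, end1 = 1100, b1 = 4L, mapped2 = FALSE,
             start2 = NA, end2 = NA, b2 = NA_integer_, seq2 = aluRead,
             isize = NA))
  expect_equal(nrow(aluMates(scanAluMates(multiAnchor, lib, model))), 0L)
})

test_that("unsorted input is rejected naming the offending record", {
  set.seed(22)
  lib <- syntheticAluLibrary(1, 100)
  pairs <- rbind(makePair(pairId = 1L, start1 = 5000, end1 = 5100,
                          start2 = 5300, end2 = 5400),
                 makePair(pairId = 2L, start1 = 1000, end1 = 1100,
                          start2 = 1300, end2 = 1400))
  expect_error(scanAluMates(pairs, lib, model), "record 2")
})

test_that("scanning is deterministic and roughly linear in input size", {
  sim <- smallSim()
  pairs <- simulateIndividualReads(sim, c(1L, 2L), target = "insertion",
                                   ind = "ind01")
  m <- estimateInsertModel(pairs)
  r1 <- scanAluMates(pairs, simLibrary(sim), m)
  r2 <- scanAluMates(pairs, simLibrary(sim), m)
  expect_identical(aluMates(r1), aluMates(r2))
  expect_identical(mateCounts(r1), mateCounts(r2))
  ## no-worse-than-linear empirically: 4x the records in well under 16x time
  half <- pairs[pairs$pairId %% 4L == 0L, ]
  t1 <- system.time(for (i in 1:3) scanAluMates(half, simLibrary(sim), m))[3]
  t4 <- system.time(for (i in 1:3) scanAluMates(pairs, simLibrary(sim), m))[3]
  expect_lt(t4, 16 * max(t1, 0.02))
})

test_that("mates round-trip through the TSV writer", {
  sim <- smallSim()
  pairs <- simulateIndividualReads(sim, c(1L, 2L), target = "insertion",
                                   ind = "ind01")
  m <- estimateInsertModel(pairs)
  res <- scanAluMates(pairs, simLibrary(sim), m)
  path <- tempfile(fileext = ".tsv")
  writeAluMates(res, path)
  back <- readAluMates(path)
  expect_equal(back$start, aluMates(res)$start)
  expect_equal(back$label, aluMates(res)$label)
  bed <- tempfile(fileext = ".bed")
  writeAluMateBed(res, bed)
  expect_gt(length(readLines(bed)), 0L)
})
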