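test_that("planting respects counts, spacing and frequency assignment", {
  sim <- smallSim()
  sites <- simSites(sim)
  cfg <- sim@config
  expect_equal(nrow(sites), cfg$nFamilies * cfg$sitesPerFamily)
  qHi <- qnorm(1 - cfg$epsilon, cfg$insertMean, cfg$insertSd)
  expect_true(all(diff(sites$pos) >= 2 * qHi + cfg$aluLength))
  ## each family gets every ladder frequency exactly once
  for (a in unique(sites$alu))
    expect_setequal(sites$freq[sites$alu == a], cfg$frequencies)
  ## planted copies are mutated consensi of consensus length
  expect_true(all(sites$len == cfg$aluLength))
  cons <- as.character(simLibrary(sim)@sequences[sites$alu])
  ident <- mapply(function(a, b)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]), sites$seq, cons)
  expect_true(all(ident > 0.9) && all(ident < 1))
})

test_that("zero mutation keeps planted copies identical to the consensus", {
  set.seed(60)
  cfg <- simulationConfig(referenceLength = 3e5, nHaploids = 4L,
                          nFamilies = 1L, sitesPerFamily = 2L,
                          frequencies = c(0.5, 0.9), mutationRate = 0)
  sim <- simulateCohort(cfg)
  cons <- as.character(simLibrary(sim)@sequences[[1]])
  expect_true(all(simSites(sim)$seq == cons))
})

test_that("carrier draws follow the assigned frequencies", {
  set.seed(61)
  cfg <- simulationConfig(referenceLength = 2e6, nHaploids = 400L)
  sim <- simulateCohort(cfg)
  car <- simCarriers(sim)
  freq <- simSites(sim)$freq
  ## binomial goodness of fit across the 50 sites
  z <- (colSums(car) - 400 * freq) / sqrt(400 * freq * (1 - freq))
  pval <- pchisq(sum(z^2), df = length(z), lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- simulationConfig(referenceLength = 3e5, nHaploids = 4L,
                          nFamilies = 1L, sitesPerFamily = 2L,
                          frequencies = c(0.5, 0.9))
  set.seed(62); a <- simulateCohort(cfg)
  set.seed(62); b <- simulateCohort(cfg)
  expect_identical(as.character(simReference(a)), as.character(simReference(b)))
  expect_identical(simSites(a), simSites(b))
  expect_identical(simCarriers(a), simCarriers(b))
  set.seed(63); pa <- simulateHaploidReads(a, 1L, "insertion")
  set.seed(63); pb <- simulateHaploidReads(b, 1L, "insertion")
  expect_identical(pa, pb)
})

test_that("read simulation honours count, coverage and insert model", {
  sim <- smallSim()
  set.seed(64)
  pairs <- simulateHaploidReads(sim, rep(FALSE, nrow(simSites(sim))),
                                target = "insertion")
  cfg <- sim@config
  expect_equal(nrow(pairs),
               round(cfg$coverage * cfg$referenceLength /
                       (2 * cfg$readLength)))
  ## no planted elements carried: every read maps
  expect_true(all(pairs$mapped1) && all(pairs$mapped2))
  ## CLT bound: the mean outer insert of >= 1e4 pairs sits within ~1.5 bp
  expect_lt(abs(mean(pairs$isize) - cfg$insertMean), 1.5)
  expect_false(is.unsorted(pairs$start1[pairs$mapped1]))
})

test_that("error-free unmapped reads are exact haplotype substrings", {
  sim <- smallSim()
  set.seed(65)
  carried <- simCarriers(sim)[1, ]
  pairs <- simulateHaploidReads(sim, carried, target = "insertion",
                                errorRate = 0)
  unm <- pairs[!pairs$mapped2 & !is.na(pairs$seq2), ][1:5, ]
  hap <- AluPolyScan:::.haplotypeSeq(sim, carried)
  lib <- simLibrary(sim)
  cls <- classifyAluRead(unm$seq2, lib)
  ## unmapped reads overlap planted copies, most classify as Alu
  expect_gte(sum(cls$isAlu), 1L)
  ## with 2% error reads differ from the haplotype but classify similarly
  set.seed(65)
  withErr <- simulateHaploidReads(sim, carried, target = "insertion",
                                  errorRate = 0.02)
  expect_equal(nrow(withErr), nrow(pairs))
})

test_that("deletion-target mapping shifts pairs across missing elements", {
  sim <- smallSim()
  set.seed(66)
  nSites <- nrow(simSites(sim))
  none <- rep(FALSE, nSites)
  pairs <- simulateHaploidReads(sim, none, target = "deletion")
  ar <- allAluReference(sim)
  ann <- ar$annotations
  ## pairs spanning a missing element show the elongated insert
  spans <- pairs$mapped1 & pairs$mapped2 &
    pairs$end1 <= ann$start[1] & pairs$start2 >= ann$end[1]
  expect_gt(sum(spans, na.rm = TRUE), 0)
  expect_gt(mean(pairs$isize[spans], na.rm = TRUE), 600)
  ## a full carrier maps everything without elongation
  all <- rep(TRUE, nSites)
  pairsAll <- simulateHaploidReads(sim, all, target = "deletion")
  expect_true(all(pairsAll$mapped1 & pairsAll$mapped2))
  expect_lt(abs(mean(pairsAll$isize) - 400), 3)
})

test_that("sequential pairing and trios satisfy their invariants", {
  sim <- smallSim()
  pop <- buildPopulation(sim)
  expect_equal(nrow(pop), nrow(simCarriers(sim)) / 2)
  expect_equal(pop$hap1, seq(1, nrow(simCarriers(sim)), by = 2))
  set.seed(67)
  trio <- buildTrios(sim, 5L)
  ped <- trio$pedigree
  expect_equal(nrow(ped), 15L)
  for (tr in 1:5) {
    child <- ped[ped$trio == tr & ped$member == "child", ]
    father <- ped[ped$trio == tr & ped$member == "father", ]
    mother <- ped[ped$trio == tr & ped$member == "mother", ]
    ## each child haplotype indexes (hence exactly copies) a parental one
    expect_true(child$hap1 %in% c(father$hap1, father$hap2))
    expect_true(child$hap2 %in% c(mother$hap1, mother$hap2))
  }
})

test_that("the all-element reference contains each planted copy in place", {
  sim <- smallSim()
  ar <- allAluReference(sim)
  sites <- simSites(sim)
  ann <- ar$annotations
  expect_equal(nchar(ar$seq), length(simReference(sim)) + sum(sites$len))
  for (i in seq_len(nrow(ann)))
    expect_identical(substr(ar$seq, ann$start[i] + 1, ann$end[i]),
                     sites$seq[i])
})

test_that("an odd haploid count cannot be paired", {
  sim <- smallSim()
  simOdd <- sim
  simOdd@carriers <- sim@carriers[1:9, ]
  expect_error(buildPopulation(simOdd), "odd")
})
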