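test_that("cover intervals follow the covering inequalities", {
  expect_equal(unname(coverInterval(1000, "l", 200, 600, 100)[1, ]),
               c(1100, 1600))
  expect_equal(unname(coverInterval(2000, "r", 200, 600, 100)[1, ]),
               c(1400, 1900))
  ## degenerate quantiles leave a read-length-wide interval
  deg <- coverInterval(1000, "l", 400, 400, 100)
  expect_equal(unname(deg[1, "hi"] - deg[1, "lo"]), 100)
})

test_that("three co-coverable reads are covered rather than error-labelled", {
  inst <- data.frame(lo = c(1200, 1300, 1400), hi = c(1500, 1600, 1700))
  sol <- solveCoverSingle(inst, k = 3)
  expect_length(coverPositions(sol), 1L)
  expect_length(coverErrors(sol), 0L)
  expect_equal(coverObjective(sol), 3)
  expect_true(coverPositions(sol) >= 1400 && coverPositions(sol) <= 1500)
  expect_true(isTRUE(verifyCoverSolution(inst, sol)))
})

test_that("two reads are cheaper as errors at k = 3", {
  inst <- data.frame(lo = c(1200, 1300), hi = c(1500, 1600))
  sol <- solveCoverSingle(inst, k = 3)
  expect_length(coverPositions(sol), 0L)
  expect_equal(sort(coverErrors(sol)), 1:2)
  expect_equal(coverObjective(sol), 2)
})

test_that("the dynamic program matches exhaustive enumeration", {
  set.seed(40)
  for (trial in 1:250) {
    n <- sample(1:12, 1)
    lo <- round(runif(n, 0, 500))
    hi <- lo + round(runif(n, 10, 300))
    k <- sample(c(2, 3, 4), 1)
    inst <- data.frame(lo = lo, hi = hi)
    sol <- solveCoverSingle(inst, k = k)
    expect_true(isTRUE(verifyCoverSolution(inst, sol)))
    expect_equal(coverObjective(sol), bruteForceCoverObjective(inst, k))
  }
})

test_that("raising k never decreases the number of error reads", {
  set.seed(41)
  for (trial in 1:30) {
    n <- sample(2:10, 1)
    lo <- round(runif(n, 0, 400))
    inst <- data.frame(lo = lo, hi = lo + round(runif(n, 20, 250)))
    prev <- -1L
    for (k in c(1, 2, 3, 5, 8)) {
      ne <- length(coverErrors(solveCoverSingle(inst, k = k)))
      expect_gte(ne, prev)
      prev <- ne
    }
  }
})

test_that("the sweep finds flanked positions and separates distant sites", {
  model <- gaussianInsertModel(400, 50)
  qHi <- insertQuantiles(model)[["qHi"]]
  mk <- function(start, label) data.frame(chrom = "sim1", start = start,
                                          end = start + 100, label = label,
                                          weight = 1)
  mates <- rbind(mk(9700, "l"), mk(9750, "l"), mk(9800, "l"),
                 mk(10150, "r"), mk(10200, "r"), mk(10250, "r"))
  win <- sweepCandidateRegions(mates, model, threshold = 3)
  expect_gte(nrow(win), 1L)
  expect_true(any(win$start <= 10000 & win$end >= 10000))
  ## two sites further apart than twice the window cannot share a region
  far <- rbind(mates, within(mates, start <- start + 2 * qHi + 2000))
  far$end <- far$start + 100
  win2 <- sweepCandidateRegions(far, model, threshold = 3)
  expect_gte(nrow(win2), 2L)
  none <- sweepCandidateRegions(mates[0, ], model)
  expect_equal(nrow(none), 0L)
})

test_that("sweep weights fractional evidence by the mapping count", {
  model <- gaussianInsertModel(400, 50)
  mates <- data.frame(chrom = "sim1",
                      start = c(9700, 9750, 9800),
                      end = c(9800, 9850, 9900),
                      label = "l", weight = c(0.5, 0.5, 0.5))
  expect_equal(nrow(sweepCandidateRegions(mates, model, threshold = 3)), 0L)
  expect_gte(nrow(sweepCandidateRegions(mates, model, threshold = 1.5)), 1L)
})

test_that("multi-individual heuristic covers supported sites and prices them", {
  model <- gaussianInsertModel(400, 50)
  mkInst <- function(centers, ind) {
    data.frame(lo = centers - 150, hi = centers + 150,
               pos = centers, kind = "l", weight = 1, ind = ind)
  }
  instances <- setNames(lapply(1:5, function(i)
    mkInst(c(10000, 10040), paste0("ind", i))), paste0("ind", 1:5))
  sol <- solveCoverMulti(instances, k1 = 2, k2 = 2, mergeDist = 529)
  expect_length(coverPositions(sol), 1L)
  expect_equal(lengths(coverAssignments(sol)), 5L)
  expect_equal(coverObjective(sol), 2 + 2 * 5)
  all <- do.call(rbind, instances)
  expect_true(isTRUE(verifyCoverSolution(all, sol)))
})

test_that("a single read in one individual is error-labelled, not assigned", {
  instances <- list(
    a = data.frame(lo = c(9850, 9900), hi = c(10150, 10200), pos = 10000,
                   kind = "l", weight = 1, ind = "a"),
    b = data.frame(lo = 9870, hi = 10170, pos = 10020, kind = "l",
                   weight = 1, ind = "b"))
  sol <- solveCoverMulti(instances, mergeDist = 529)
  expect_length(coverPositions(sol), 1L)
  expect_equal(coverAssignments(sol)[[1]], "a")
  expect_equal(length(coverErrors(sol)), 1L)
  expect_equal(coverObjective(sol), 1 + 2 + 2)
})

test_that("nearby per-individual sites merge into one position", {
  instances <- list(
    a = data.frame(lo = c(9850, 9860), hi = c(10150, 10160),
                   pos = 10000, kind = "l", weight = 1, ind = "a"),
    b = data.frame(lo = c(9880, 9890), hi = c(10180, 10190),
                   pos = 10030, kind = "l", weight = 1, ind = "b"))
  sol <- solveCoverMulti(instances, mergeDist = 529)
  expect_length(coverPositions(sol), 1L)
  expect_setequal(coverAssignments(sol)[[1]], c("a", "b"))
})

test_that("the heuristic objective dominates the pooled single optimum", {
  set.seed(42)
  for (trial in 1:10) {
    n <- sample(2:8, 1)
    lo <- round(runif(n, 0, 600))
    inst <- data.frame(lo = lo, hi = lo + 300, pos = lo + 150, kind = "l",
                       weight = 1, ind = "a")
    multi <- solveCoverMulti(list(a = inst), k1 = 2, k2 = 2,
                             mergeDist = 300)
    single <- solveCoverSingle(inst, k = 4)
    expect_gte(coverObjective(multi), coverObjective(single) - 1e-9)
  }
})
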