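test_that("offset estimators reproduce the worked arithmetic", {
  ## one left support: d = 200, lambda = 400 - 200 - 120 = 80
  one <- estimateLambda(data.frame(ct = 4800, at = 120, mt = 400, st = 50),
                        pAlu = 5000)
  expect_equal(one$estimate, 80)
  expect_equal(one$se, 50)
  ## per-read estimates 80 and 40: equal-weight mean
  two <- estimateLambda(data.frame(ct = c(4800, 4760), at = c(120, 120),
                                   mt = 400, st = 50), 5000)
  expect_equal(two$estimate, 60)
  ## inverse-variance weighting: (80/2500 + 40/10000) / (1/2500 + 1/10000)
  ivw <- estimateLambda(data.frame(ct = c(4800, 4760), at = 120, mt = 400,
                                   st = c(50, 100)), 5000)
  expect_equal(ivw$estimate, 72)
  ## right side: at' = 300 - 250 = 50, d = 200, rho = 400 - 200 - 50 = 150
  r <- estimateRho(data.frame(ct = 5200, at = 250, mt = 400, st = 50),
                   pAlu = 5000, lAlu = 300)
  expect_equal(r$estimate, 150)
  ## no supports flagged undefined
  none <- estimateLambda(data.frame(), 5000)
  expect_equal(none$estimate, 0)
  expect_equal(none$se, Inf)
})

test_that("offset estimators equal the naive weighted-mean loops", {
  set.seed(50)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    sup <- data.frame(ct = runif(n, 4000, 5000), at = sample(0:250, n, TRUE),
                      mt = 400, st = runif(n, 20, 90))
    lam <- estimateLambda(sup, 5000)
    manual <- 0; wsum <- 0
    for (i in seq_len(n)) {
      est <- sup$mt[i] - (5000 - sup$ct[i]) - sup$at[i]
      manual <- manual + est / sup$st[i]^2
      wsum <- wsum + 1 / sup$st[i]^2
    }
    expect_equal(lam$estimate, manual / wsum, tolerance = 1e-10)
    expect_equal(lam$se, 1 / sqrt(wsum), tolerance = 1e-12)
  }
})

test_that("position re-estimation inverts the offset equations", {
  ## the lambda example read with lambda fixed at 80 recovers p = 5000
  p <- reestimatePosition(left = data.frame(ct = 4800, at = 120, mt = 400,
                                            st = 50),
                          right = data.frame(), lambda = 80, rho = 0,
                          lAlu = 300)
  expect_equal(p$estimate, 4800 + 400 - 120 - 80)
  two <- reestimatePosition(left = data.frame(ct = c(4520, 4530), at = 0,
                                              mt = 480, st = 50),
                            right = data.frame(), 0, 0, 300)
  expect_equal(two$estimate, 5005)
  expect_error(reestimatePosition(data.frame(), data.frame(), 0, 0, 300),
               "support")
})

test_that("offset recovery stays within three standard errors", {
  set.seed(51)
  nrep <- 300L
  ok <- 0L
  for (rep in seq_len(nrep)) {
    lamStar <- runif(1, -40, 40)
    n <- sample(3:10, 1)
    at <- sample(0:150, n, TRUE)
    ## observed anchor position implied by a Gaussian start-to-start distance
    dist <- rnorm(n, 300, 50)
    ct <- 5000 - (dist - lamStar - at)
    est <- estimateLambda(data.frame(ct = ct, at = at, mt = 300, st = 50),
                          5000)
    if (abs(est$estimate - lamStar) <= 3 * est$se) ok <- ok + 1L
  }
  expect_gte(ok / nrep, 0.95)
})

test_that("refinement converges on clean supports and recovers the site", {
  set.seed(52)
  pStar <- 20000
  mkSup <- function(n, side) {
    at <- sample(0:180, n, TRUE)
    dist <- rnorm(n, 300, 50)
    if (side == "l") {
      ct <- pStar - (dist - at)        # lambda* = 0
      data.frame(label = "l", start = ct, end = ct + 100, at = at,
                 mt = 300, st = 50)
    } else {
      ct <- pStar + (dist - (300 - at))  # rho* = 0
      data.frame(label = "r", start = ct, end = ct + 100, at = at,
                 mt = 300, st = 50)
    }
  }
  sup <- rbind(mkSup(6, "l"), mkSup(6, "r"))
  cand <- refineCandidate(20300, sup, lAlu = 300)
  expect_true(cand@converged)
  expect_lte(cand@iterations, 3L)
  se <- 50 / sqrt(nrow(sup))
  expect_lt(abs(cand@position - pStar), 3 * se + 1)
  expect_lt(abs(cand@lambda), 60)
  expect_lt(abs(cand@rho), 60)
})

test_that("a single support converges immediately in closed form", {
  sup <- data.frame(label = "l", start = 4800, end = 4900, at = 120,
                    mt = 400, st = 50)
  cand <- refineCandidate(5100, sup, lAlu = 300)
  expect_true(cand@converged)
  expect_equal(cand@position, 4800 + 400 - 120, tolerance = 1e-6)
})

test_that("in-silico insertion splices, shifts and round-trips", {
  set.seed(53)
  ref <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  cons <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  ins <- insertInSilico(ref, 5000, cons)
  expect_equal(nchar(ins$seq), 10300)
  expect_equal(ins$map(4999), 4999)
  expect_equal(ins$map(5000), 5300)
  expect_equal(substr(ins$seq, 1, 5000), substr(ref, 1, 5000))
  expect_equal(substr(ins$seq, 5001, 5300), cons)
  ## deleting the inserted interval recovers the input exactly
  back <- paste0(substr(ins$seq, 1, 5000),
                 substr(ins$seq, 5301, nchar(ins$seq)))
  expect_identical(back, ref)
  ## negative left offset trims the consensus
  trim <- insertInSilico(ref, 5000, cons, lambda = -20)
  expect_equal(trim$length, 280)
  expect_equal(substr(trim$seq, 5001, 5280), substr(cons, 21, 300))
  ## positive offsets pad with consensus flank copies
  pad <- insertInSilico(ref, 5000, cons, lambda = 10, rho = 5)
  expect_equal(pad$length, 315)
  expect_error(insertInSilico(ref, 5000, cons, lambda = -200, rho = -150),
               "positive")
})

test_that("insertion genotyping by reduction recovers simulated genotypes", {
  sim <- smallSim()
  car <- simCarriers(sim)
  sites <- simSites(sim)
  set.seed(54)
  pop <- buildPopulation(sim)
  ## pick a site with both het and hom carriers among the diploids
  copies <- vapply(seq_len(nrow(pop)), function(i)
    car[pop$hap1[i], ] + car[pop$hap2[i], ], numeric(nrow(sites)))
  site <- which.max(apply(copies, 1, function(x) min(sum(x == 1), 1) +
                            min(sum(x == 2), 1) + min(sum(x == 0), 1)))
  pairsOf <- list(); matesOf <- list(); models <- list()
  for (i in seq_len(nrow(pop))) {
    pr <- simulateIndividualReads(sim, c(pop$hap1[i], pop$hap2[i]),
                                  target = "insertion", ind = pop$ind[i])
    models[[pop$ind[i]]] <- estimateInsertModel(pr)
    sc <- scanAluMates(pr, simLibrary(sim), models[[pop$ind[i]]])
    pairsOf[[pop$ind[i]]] <- pr
    matesOf[[pop$ind[i]]] <- aluMates(sc)
  }
  cand <- new("CandidateInsertion", chrom = "sim1",
              position = sites$pos[site], alu = sites$alu[site],
              family = sites$family[site], lAlu = 300, lambda = 0, rho = 0,
              lambdaSE = 10, rhoSE = 10, supports = data.frame(),
              converged = TRUE, iterations = 1L)
  gt <- genotypeInsertion(cand, pairsOf, matesOf, models,
                          individuals = pop$ind)
  expect_equal(gt$perInd$copies, unname(copies[site, ]))
  ## carriers present implies a significant population LRT
  if (any(copies[site, ] > 0)) expect_lt(gt$lrt$pvalue, 0.01)
})
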