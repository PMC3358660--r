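model <- gaussianInsertModel(400, 50)

test_that("single-pair genotype likelihoods match direct pdf evaluation", {
  g0 <- genotypeDeletion(gaussianSpanning(400), model, 300)
  expect_equal(exp(g0$ll0), dnorm(400, 400, 50), tolerance = 1e-9)
  expect_equal(exp(g0$ll0), 0.0079788, tolerance = 1e-4)
  expect_equal(exp(g0$ll1), dnorm(400, 400, 50) * 2 / 3 +
                 dnorm(400, 700, 50) / 3, tolerance = 1e-9)
  expect_equal(exp(g0$ll2), dnorm(400, 700, 50), tolerance = 1e-12)
  expect_equal(g0$g, 0L)
  ## mirror case: an insert of mean + lAlu supports the deletion
  g2 <- genotypeDeletion(gaussianSpanning(700), model, 300)
  expect_equal(exp(g2$ll2), 0.0079788, tolerance = 1e-4)
  expect_equal(g2$g, 2L)
})

test_that("mixed evidence calls a heterozygote with the exact mixture product", {
  gl <- genotypeDeletion(gaussianSpanning(c(400, 700)), model, 300)
  ## independent oracle: recompute each factor with plain pdf arithmetic
  y <- dnorm(c(400, 700), 400, 50)
  z <- dnorm(c(400, 700), 700, 50)
  expect_equal(gl$ll1, sum(log(z / 3 + 2 * y / 3)), tolerance = 1e-9)
  expect_equal(gl$ll0, sum(log(pmax(y, 1e-300))), tolerance = 1e-6)
  expect_gt(gl$ll1, gl$ll0)
  expect_gt(gl$ll1, gl$ll2)
  expect_equal(gl$g, 1L)
})

test_that("heterozygote likelihood equals the per-read mixture for random T", {
  set.seed(30)
  for (rep in 1:20) {
    t <- runif(sample(1:8, 1), 250, 850)
    lAlu <- sample(250:350, 1)
    gl <- genotypeDeletion(gaussianSpanning(t), model, lAlu)
    manual <- 0
    for (ti in t)
      manual <- manual + log(dnorm(ti, 400 + lAlu, 50) / 3 +
                               2 * dnorm(ti, 400, 50) / 3)
    expect_equal(gl$ll1, manual, tolerance = 1e-9)
  }
})

test_that("no informative pairs yields zero log-likelihoods and no call", {
  gl <- genotypeDeletion(gaussianSpanning(numeric()), model, 300)
  expect_identical(c(gl$ll0, gl$ll1, gl$ll2), c(0, 0, 0))
  expect_true(is.na(gl$g))
})

test_that("appending a Z-mean read never decreases the deletion evidence", {
  set.seed(31)
  for (rep in 1:10) {
    t <- runif(5, 300, 800)
    g1 <- genotypeDeletion(gaussianSpanning(t), model, 300)
    g2 <- genotypeDeletion(gaussianSpanning(c(t, 700)), model, 300)
    expect_gte(g2$ll2 - g2$ll0, g1$ll2 - g1$ll0)
  }
})

test_that("read weights scale the log-likelihood factors when enabled", {
  sp <- list(t = c(400, 700), w = c(0.5, 1), n = 2L)
  gl <- genotypeDeletion(sp, model, 300, useWeights = TRUE)
  expect_equal(gl$ll0, 0.5 * log(dnorm(400, 400, 50)) +
                 log(pmax(dnorm(700, 400, 50), 1e-300)), tolerance = 1e-9)
  glu <- genotypeDeletion(sp, model, 300, useWeights = FALSE)
  expect_equal(glu$ll0, sum(log(pmax(dnorm(c(400, 700), 400, 50), 1e-300))),
               tolerance = 1e-9)
})

test_that("the spanning set keeps element-overlapping window pairs only", {
  locus <- data.frame(chrom = "sim1", start = 5000, end = 5300)
  pairs <- makePairs(
    makePair(start1 = 4700, end1 = 4800, start2 = 5400, end2 = 5500),  # spans
    makePair(start1 = 4500, end1 = 4600, start2 = 4800, end2 = 4900),  # left of locus
    makePair(start1 = 4700, end1 = 4800, chrom2 = "sim9",
             start2 = 99000, end2 = 99100, isize = NA),                # one-ended
    makePair(start1 = 3000, end1 = 3100, start2 = 3300, end2 = 3400))  # outside window
  sp <- collectSpanningSet(locus, pairs, model)
  expect_equal(sp$n, 1L)
  expect_equal(sp$t, 800)
  expect_error(collectSpanningSet(locus, pairs, model, refLen = 4000),
               "outside")
})

test_that("window Alu mates are realigned into the locus element", {
  locus <- data.frame(chrom = "sim1", start = 5000, end = 5300)
  mates <- data.frame(chrom = "sim1", start = 4700, end = 4800,
                      label = "l", alu = "AluYa5", family = "AluY",
                      at = 40L, aluLen = 100L, b = 1L, weight = 1,
                      ind = "ind01")
  sp <- collectSpanningSet(locus, makePairs(makePair(start1 = 1, end1 = 2,
                                                     start2 = 3, end2 = 4)),
                           model, mates = mates)
  ## insert = (locus start + at + read length) - anchor start
  expect_equal(sp$t, (5000 + 40 + 100) - 4700)
})

test_that("the boundary LRT optimum matches its closed form", {
  lik <- data.frame(ll0 = log(1e-10), ll1 = log(1e-6), ll2 = log(1e-2))
  res <- populationLrt(lik, hwe = TRUE)
  expect_equal(res$p, 1)
  expect_equal(res$stat, 2 * log(1e8), tolerance = 1e-6)
  expect_equal(res$pvalue, pchisq(2 * log(1e8), 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("null data sit at the boundary with statistic zero", {
  lik <- data.frame(ll0 = rep(0, 8), ll1 = rep(-5, 8), ll2 = rep(-40, 8))
  res <- populationLrt(lik, hwe = TRUE)
  expect_equal(res$p, 0)
  expect_equal(res$stat, 0)
  expect_equal(res$pvalue, 1)
})

test_that("the LRT statistic is order-invariant and non-negative", {
  set.seed(32)
  for (rep in 1:10) {
    lik <- data.frame(ll0 = rnorm(6, -10, 4), ll1 = rnorm(6, -10, 4),
                      ll2 = rnorm(6, -10, 4))
    r1 <- populationLrt(lik)
    r2 <- populationLrt(lik[sample(6), ])
    expect_gte(r1$stat, 0)
    expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
  }
})

test_that("the 2-df simplex fit never beats HWE by less than zero", {
  set.seed(33)
  lik <- data.frame(ll0 = rnorm(10, -8, 3), ll1 = rnorm(10, -8, 3),
                    ll2 = rnorm(10, -8, 3))
  free <- populationLrt(lik, hwe = FALSE)
  hwe <- populationLrt(lik, hwe = TRUE)
  expect_equal(sum(free$f), 1, tolerance = 1e-9)
  expect_equal(free$df, 2L)
  ## the simplex contains every HWE triple
  expect_gte(free$loglik, hwe$loglik - 1e-4)
})

test_that("allele-frequency MLE recovers the truth on simulated cohorts", {
  set.seed(34)
  model <- gaussianInsertModel(400, 50)
  nrep <- 60L
  m <- 40L
  ok <- 0L
  for (rep in seq_len(nrep)) {
    pstar <- runif(1, 0.1, 0.9)
    g <- rbinom(m, 2, pstar)
    lik <- t(vapply(g, function(gi) {
      ## reads per haplotype ~ Y from element-bearing, Z from deleted
      t <- c(rnorm(sample(2:5, 1) * (2 - gi), 400, 50),
             rnorm(sample(2:5, 1) * gi, 700, 50))
      unlist(genotypeDeletion(gaussianSpanning(t), model,
                              300)[c("ll0", "ll1", "ll2")])
    }, numeric(3)))
    colnames(lik) <- c("ll0", "ll1", "ll2")
    fit <- populationLrt(as.data.frame(lik), hwe = TRUE)
    se <- sqrt(pstar * (1 - pstar) / (2 * m))
    if (abs(fit$p - pstar) <= 3 * se) ok <- ok + 1L
  }
  expect_gte(ok / nrep, 0.9)
})

test_that("scanDeletions flags polymorphic loci and reports element copies", {
  sim <- smallSim()
  ar <- allAluReference(sim)
  pop <- buildPopulation(sim)[1:3, ]
  pairsOf <- list()
  models <- list()
  set.seed(35)
  for (i in seq_len(nrow(pop))) {
    pr <- simulateIndividualReads(sim, c(pop$hap1[i], pop$hap2[i]),
                                  target = "deletion", ind = pop$ind[i])
    pairsOf[[pop$ind[i]]] <- pr
    models[[pop$ind[i]]] <- estimateInsertModel(pr)
  }
  cs <- scanDeletions(ar$annotations, pairsOf, models)
  expect_s4_class(cs, "AluCallSet")
  geno <- genotypeMatrix(cs)
  truth <- t(vapply(seq_len(nrow(pop)), function(i)
    simCarriers(sim)[pop$hap1[i], ] + simCarriers(sim)[pop$hap2[i], ],
    numeric(ncol(simCarriers(sim)))))
  expect_gte(mean(geno == truth, na.rm = TRUE), 0.95)
  ## loci where every sampled individual is a full carrier must not be flagged
  allCarrier <- apply(truth, 2, function(x) all(x == 2))
  if (any(allCarrier))
    expect_false(any(callsTable(cs)$flagged[allCarrier]))
  expect_equal(nrow(callsTable(cs)), 0L + nrow(ar$annotations))
  empty <- scanDeletions(ar$annotations[0, ], pairsOf, models)
  expect_equal(nrow(callsTable(empty)), 0L)
})
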