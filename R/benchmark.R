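#' Insertion-detection benchmark on a simulated cohort
#'
#' Pairs the cohort's haploids into diploids, simulates reads per individual
#' against the element-free reference, runs the per-individual insertion
#' pipeline and scores detected events against the truth table.  An expected
#' event is an (individual, site) pair where at least one haplotype carries
#' the planted element; it counts as found when the individual has a call
#' within \code{matchTol} bp of the true insertion point.  A call matching no
#' true carried site of that individual is a false positive.
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @param errorRate Per-base read error (default: the config's).
#' @param sweepThreshold,k Discovery parameters (defaults 3, 3).
#' @param matchTol Matching tolerance in bp (default 150).
#' @param genotype Also genotype each call in silico (default TRUE).
#' @param verbose Print per-individual progress.
#' @return A list: \code{sensitivity} (percent), \code{expected},
#'   \code{found}, \code{falsePositives}, \code{calls} (per-individual call
#'   table), \code{evidence} (per-individual mates and models, reusable by
#'   \code{\link{zeroFalsePositiveSensitivity}}).
#' @export
runInsertionBenchmark <- function(sim, errorRate = NULL, sweepThreshold = 3,
                                  k = 3, matchTol = 150, genotype = TRUE,
                                  verbose = FALSE) {
  pop <- buildPopulation(sim)
  lib <- sim@library
  readLen <- sim@config$readLength
  calls <- list()
  evidence <- list()
  for (i in seq_len(nrow(pop))) {
    ind <- pop$ind[i]
    pairs <- simulateIndividualReads(sim, c(pop$hap1[i], pop$hap2[i]),
                                     target = "insertion",
                                     errorRate = errorRate, ind = ind)
    res <- findInsertionsIndividual(pairs, lib, readLen = readLen,
                                    sweepThreshold = sweepThreshold, k = k,
                                    genotype = genotype)
    if (nrow(res$calls)) {
      res$calls$ind <- ind
      calls[[length(calls) + 1L]] <- res$calls
    }
    evidence[[ind]] <- list(mates = aluMates(res$mates), model = res$model)
    if (verbose) message(ind, ": ", nrow(res$calls), " calls")
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), pos = numeric(), ind = character())
  sc <- .scoreInsertionCalls(sim, pop, calls, matchTol)
  c(sc, list(calls = calls, evidence = evidence, population = pop,
             readLen = readLen))
}

.scoreInsertionCalls <- function(sim, pop, calls, matchTol) {
  sites <- sim@sites
  car <- sim@carriers
  expected <- 0L
  found <- 0L
  fp <- 0L
  for (i in seq_len(nrow(pop))) {
    ind <- pop$ind[i]
    has <- car[pop$hap1[i], ] | car[pop$hap2[i], ]
    cp <- calls$pos[calls$ind == ind]
    expected <- expected + sum(has)
    for (s in which(has))
      if (any(abs(cp - sites$pos[s]) <= matchTol)) found <- found + 1L
    for (p in cp)
      if (!any(abs(p - sites$pos[has]) <= matchTol)) fp <- fp + 1L
  }
  list(sensitivity = 100 * found / expected, expected = expected,
       found = found, falsePositives = fp)
}

#' Insertion sensitivity at the zero-false-positive operating point
#'
#' Raises the discovery thresholds (sweep indicator and covering cost
#' together) on cached per-individual evidence until no call falls outside
#' the truth windows, then reports the sensitivity retained at that
#' operating point.
#'
#' @param bench Result of \code{\link{runInsertionBenchmark}}.
#' @param sim The same \linkS4class{AluSimulation}.
#' @param thresholds Increasing sequence of sweep thresholds to try
#'   (default 3:12).
#' @param matchTol Matching tolerance (default 150).
#' @return A list: \code{sensitivity}, \code{threshold},
#'   \code{falsePositives} at the chosen point (NA sensitivity when no
#'   threshold removes all false positives).
#' @export
zeroFalsePositiveSensitivity <- function(bench, sim, thresholds = 3:12,
                                         matchTol = 150) {
  pop <- bench$population
  for (th in thresholds) {
    calls <- list()
    for (ind in names(bench$evidence)) {
      ev <- bench$evidence[[ind]]
      res <- .discoverFromMates(ev$mates, ev$model, bench$readLen,
                                sweepThreshold = th, k = max(3, th),
                                library = sim@library)
      if (nrow(res$calls)) {
        res$calls$ind <- ind
        calls[[length(calls) + 1L]] <- res$calls
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(chrom = character(), pos = numeric(), ind = character())
    sc <- .scoreInsertionCalls(sim, pop, calls, matchTol)
    if (sc$falsePositives == 0L)
      return(list(sensitivity = sc$sensitivity, threshold = th,
                  falsePositives = 0L, found = sc$found,
                  expected = sc$expected))
  }
  list(sensitivity = NA_real_, threshold = NA_integer_,
       falsePositives = NA_integer_)
}

#' Deletion-genotyping benchmark against the all-element reference
#'
#' Simulates reads per individual against the reference containing every
#' planted element, genotypes all annotated loci per individual, combines
#' individuals with the HWE likelihood-ratio test, and scores deletion
#' events against truth.  An expected event is an (individual, site) pair
#' with at least one haplotype lacking the element; it is found when the
#' called genotype has at least one deleted haplotype.
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @param errorRate Per-base read error (default: config's; sequences are
#'   only emitted for unmappable reads, which do not arise on this target).
#' @param population Optional population data.frame (default
#'   \code{buildPopulation(sim)}); supply a trio pedigree's rows to genotype
#'   trio members.
#' @param carriers Optional carrier matrix matching \code{population} row
#'   indices (default the cohort's).
#' @param alpha,adjust LRT flagging parameters.
#' @return A list: \code{sensitivity}, \code{expected}, \code{found},
#'   \code{genotypes} (individuals x sites copy numbers), \code{callset}
#'   (an \linkS4class{AluCallSet}), \code{truthCopies}.
#' @export
runDeletionBenchmark <- function(sim, errorRate = NULL, population = NULL,
                                 carriers = NULL, alpha = 0.05,
                                 adjust = "bonferroni") {
  if (is.null(population)) population <- buildPopulation(sim)
  if (is.null(carriers)) carriers <- sim@carriers
  allRef <- allAluReference(sim)
  ann <- allRef$annotations
  nL <- nrow(ann)
  nI <- nrow(population)
  inds <- population$ind
  likList <- lapply(seq_len(nL), function(l)
    data.frame(ind = inds, ll0 = 0, ll1 = 0, ll2 = 0, g = NA_integer_,
               n = 0L))
  for (i in seq_len(nI)) {
    pairs <- simulateIndividualReads(
      sim, c(population$hap1[i], population$hap2[i]), target = "deletion",
      errorRate = errorRate, ind = inds[i], carriers = carriers)
    model <- estimateInsertModel(pairs)
    for (l in seq_len(nL)) {
      sp <- collectSpanningSet(ann[l, ], pairs, model)
      gl <- genotypeDeletion(sp, model, ann$end[l] - ann$start[l])
      likList[[l]][i, c("ll0", "ll1", "ll2")] <- gl[, c("ll0", "ll1", "ll2")]
      likList[[l]]$g[i] <- gl$g
      likList[[l]]$n[i] <- gl$n
    }
  }
  calls <- ann
  calls$locus <- seq_len(nL)
  calls$lAlu <- ann$end - ann$start
  calls$p <- rep(NA_real_, nL)
  calls$stat <- rep(NA_real_, nL)
  calls$pvalue <- rep(NA_real_, nL)
  geno <- matrix(NA_integer_, nI, nL, dimnames = list(inds, NULL))
  for (l in seq_len(nL)) {
    lrt <- populationLrt(likList[[l]], hwe = TRUE)
    calls$p[l] <- lrt$p
    calls$stat[l] <- lrt$stat
    calls$pvalue[l] <- lrt$pvalue
    geno[, l] <- 2L - likList[[l]]$g
  }
  calls$padj <- stats::p.adjust(calls$pvalue, method = adjust)
  calls$flagged <- calls$padj <= alpha
  cs <- new("AluCallSet", calls = calls, genotypes = geno,
            likelihoods = likList, type = "deletion")
  ## truth: copies carried per individual and site
  truthCopies <- matrix(0L, nI, nL, dimnames = list(inds, NULL))
  for (i in seq_len(nI))
    truthCopies[i, ] <- carriers[population$hap1[i], ] +
      carriers[population$hap2[i], ]
  isEvent <- truthCopies < 2L            # >= 1 haplotype lacks the element
  called <- !is.na(geno) & geno < 2L     # called with >= 1 deleted haplotype
  expected <- sum(isEvent)
  found <- sum(isEvent & called)
  list(sensitivity = 100 * found / expected, expected = expected,
       found = found, genotypes = geno, callset = cs,
       truthCopies = truthCopies)
}

#' Trio concordance benchmark
#'
#' Simulates trios, genotypes every member at all annotated loci against the
#' all-element reference, and measures Mendelian consistency of the child's
#' calls with the parents': a homozygote-deleted child call is consistent
#' when both parents carry at least one deleted haplotype; a heterozygote
#' call when one parent can transmit a deleted and the other a non-deleted
#' haplotype.
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @param nTrios Number of trios (default 10).
#' @param errorRate Per-base read error.
#' @return A list: \code{homConcordance}, \code{hetConcordance} (percent),
#'   \code{homFound}, \code{hetFound}, \code{genotypes}, \code{pedigree}.
#' @export
runTrioBenchmark <- function(sim, nTrios = 10L, errorRate = NULL) {
  trio <- buildTrios(sim, nTrios)
  ped <- trio$pedigree
  del <- runDeletionBenchmark(sim, errorRate = errorRate,
                              population = ped, carriers = trio$carriers)
  geno <- del$genotypes            # copies of the element
  nL <- ncol(geno)
  homN <- 0L; homOk <- 0L
  hetN <- 0L; hetOk <- 0L
  for (tr in seq_len(nTrios)) {
    rows <- ped$trio == tr
    f <- geno[ped$ind[rows & ped$member == "father"], ]
    m <- geno[ped$ind[rows & ped$member == "mother"], ]
    c2 <- geno[ped$ind[rows & ped$member == "child"], ]
    for (l in seq_len(nL)) {
      if (is.na(c2[l]) || is.na(f[l]) || is.na(m[l])) next
      if (c2[l] == 0L) {           # homozygote deleted (0 element copies)
        homN <- homN + 1L
        if (f[l] <= 1L && m[l] <= 1L) homOk <- homOk + 1L
      } else if (c2[l] == 1L) {    # heterozygote
        hetN <- hetN + 1L
        if ((f[l] <= 1L && m[l] >= 1L) || (m[l] <= 1L && f[l] >= 1L))
          hetOk <- hetOk + 1L
      }
    }
  }
  list(homConcordance = 100 * homOk / homN,
       hetConcordance = 100 * hetOk / hetN,
       homFound = homN, hetFound = hetN,
       genotypes = geno, pedigree = ped, deletion = del)
}
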