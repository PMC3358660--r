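# Shared fixtures, built in code.

# One pair row with sensible defaults; override any field.
makePair <- function(pairId = 1L, ind = "ind01", chrom = "sim1",
                     start1 = 1000, end1 = 1100, strand1 = "+",
                     mapped1 = TRUE, b1 = 1L, seq1 = NA_character_,
                     chrom2 = chrom, start2 = start1 + 300,
                     end2 = start1 + 400, strand2 = "-", mapped2 = TRUE,
                     b2 = 1L, seq2 = NA_character_, isize = NULL) {
  if (is.null(isize))
    isize <- if (mapped1 && mapped2 && chrom == chrom2)
      max(end1, end2, na.rm = TRUE) - min(start1, start2, na.rm = TRUE)
    else NA_real_
  data.frame(pairId = pairId, ind = ind,
             chrom1 = chrom, start1 = start1, end1 = end1,
             strand1 = strand1, mapped1 = mapped1, b1 = b1, seq1 = seq1,
             chrom2 = chrom2, start2 = start2, end2 = end2,
             strand2 = strand2, mapped2 = mapped2, b2 = b2, seq2 = seq2,
             isize = isize)
}

makePairs <- function(...) {
  pairs <- do.call(rbind, list(...))
  pairs$pairId <- seq_len(nrow(pairs))
  pairs[order(AluPolyScan:::.pairsSortKey(pairs)), , drop = FALSE]
}

# A small planted cohort reused across tests (built once per test run).
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(424)
      cfg <- simulationConfig(referenceLength = 4e5, nHaploids = 10L,
                              nFamilies = 2L, sitesPerFamily = 3L,
                              frequencies = c(0.2, 0.5, 0.9))
      cache <<- simulateCohort(cfg)
    }
    cache
  }
})

# Exhaustive covering oracle over all subsets of candidate right endpoints
# (any stabbing point slides right to a covered interval's right endpoint
# without losing coverage, so these candidates suffice).  Bitmask
# enumeration keeps 1000 x 12-read instances fast; n must be <= 12.
pcTable <- vapply(0:4095, function(x)
  sum(bitwAnd(bitwShiftR(x, 0:11), 1L)), integer(1))

bruteForceCoverObjective <- function(instance, k) {
  n <- nrow(instance)
  if (n == 0L) return(0)
  stopifnot(n <= 12L)
  cand <- sort(unique(instance$hi))
  M <- length(cand)
  candMask <- vapply(seq_len(M), function(j)
    sum(bitwShiftL(1L, which(instance$lo <= cand[j] &
                               cand[j] <= instance$hi) - 1L)),
    integer(1))
  nSub <- bitwShiftL(1L, M)
  orMask <- integer(nSub)
  sizes <- integer(nSub)
  best <- n  # all reads error-labelled
  for (m in seq_len(nSub - 1L)) {
    low <- bitwAnd(m, -m)
    j <- as.integer(round(log2(low))) + 1L
    prev <- m - low
    orMask[m + 1L] <- bitwOr(orMask[prev + 1L], candMask[j])
    sizes[m + 1L] <- sizes[prev + 1L] + 1L
    obj <- (n - pcTable[orMask[m + 1L] + 1L]) + k * sizes[m + 1L]
    if (obj < best) best <- obj
  }
  best
}

# Gaussian spanning evidence for genotyping tests.
gaussianSpanning <- function(t) list(t = t, w = rep(1, length(t)),
                                     n = length(t))
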