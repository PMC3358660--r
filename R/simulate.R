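#' Configuration of the population simulator
#'
#' Defines the study conditions for the built-in benchmark: a synthetic
#' reference chromosome into which mutated consensus copies are planted at a
#' ladder of population frequencies across haploid chromosomes that are then
#' paired into diploid individuals (or combined into trios), with paired-end
#' reads drawn per haploid.
#'
#' @param referenceLength Reference length in bp (default 2e6).
#' @param chrom Reference sequence name.
#' @param nHaploids Number of haploid chromosomes (default 100; paired
#'   sequentially into 50 diploids).
#' @param nFamilies Number of consensus entries planted (default 5).
#' @param sitesPerFamily Planted sites per consensus (default 10).
#' @param aluLength Consensus length in bp (default 300).
#' @param mutationRate Per-base substitution rate applied independently to
#'   each planted copy (default 0.03).
#' @param frequencies Ladder of site population frequencies; each frequency
#'   is used once per family (default 2, 4, 5, 10, 20, 80, 90, 94, 96, 98
#'   percent).
#' @param coverage Mean read coverage per haploid chromosome (default 5).
#' @param readLength Read length in bp (default 100).
#' @param insertMean,insertSd Outer insert-length distribution (default
#'   Gaussian 400/50).
#' @param errorRate Per-base substitution error applied to emitted read
#'   sequences (default 0; the benchmark also uses 0.02).
#' @param epsilon Tail mass for the insert window (default 0.005).
#' @return A validated named list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(referenceLength = 2e6, chrom = "sim1",
                             nHaploids = 100L, nFamilies = 5L,
                             sitesPerFamily = 10L, aluLength = 300L,
                             mutationRate = 0.03,
                             frequencies = c(2, 4, 5, 10, 20,
                                             80, 90, 94, 96, 98) / 100,
                             coverage = 5, readLength = 100L,
                             insertMean = 400, insertSd = 50,
                             errorRate = 0, epsilon = 0.005) {
  stopifnot(referenceLength > 0, nHaploids > 0, nFamilies > 0,
            sitesPerFamily > 0, aluLength > 0,
            mutationRate >= 0, mutationRate < 1,
            all(frequencies > 0), all(frequencies < 1),
            coverage > 0, readLength > 0, insertSd > 0,
            errorRate >= 0, errorRate < 1,
            epsilon > 0, epsilon < 0.5,
            length(frequencies) == sitesPerFamily)
  structure(list(referenceLength = as.integer(referenceLength),
                 chrom = chrom, nHaploids = as.integer(nHaploids),
                 nFamilies = as.integer(nFamilies),
                 sitesPerFamily = as.integer(sitesPerFamily),
                 aluLength = as.integer(aluLength),
                 mutationRate = mutationRate, frequencies = frequencies,
                 coverage = coverage, readLength = as.integer(readLength),
                 insertMean = insertMean, insertSd = insertSd,
                 errorRate = errorRate, epsilon = epsilon),
            class = c("SimulationConfig", "list"))
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence by uniform substitution
#'
#' @param seq Character scalar.
#' @param rate Per-base substitution probability; substituted bases are drawn
#'   uniformly from the other three nucleotides.
#' @return The mutated sequence.
#' @export
mutateSequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a reference population with planted polymorphic elements
#'
#' Generates (or accepts) a reference chromosome and a consensus library,
#' plants each consensus at \code{sitesPerFamily} random admissible
#' positions (each copy independently mutated at \code{mutationRate}; no two
#' sites closer than twice the insert-window quantile plus the element
#' length; at most 1\% N within the surrounding window when a real reference
#' is supplied), assigns every ladder frequency once per family, and draws
#' the per-haploid carrier status of every site independently with its
#' frequency.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param reference Optional reference sequence (character or DNAString);
#'   defaults to a random sequence of \code{referenceLength}.
#' @param library Optional \linkS4class{AluLibrary}; defaults to a synthetic
#'   library of \code{nFamilies} entries.
#' @param maxTries Attempts at drawing an admissible site layout (default
#'   200).
#' @return An \linkS4class{AluSimulation}.  Consumes the current RNG stream;
#'   call \code{set.seed} beforehand for reproducibility.
#' @export
simulateCohort <- function(config = simulationConfig(), reference = NULL,
                           library = NULL, maxTries = 200L) {
  if (is.null(reference)) reference <- .randomDna(config$referenceLength)
  reference <- as.character(reference)
  refLen <- nchar(reference)
  if (is.null(library))
    library <- syntheticAluLibrary(config$nFamilies, config$aluLength)
  qHi <- qnorm(1 - config$epsilon, config$insertMean, config$insertSd)
  nSites <- config$nFamilies * config$sitesPerFamily
  minSep <- 2 * qHi + config$aluLength
  margin <- ceiling(qHi + config$aluLength)
  if (refLen < 100 * qHi)
    stop("reference too short: need at least 100 x the insert quantile (",
         ceiling(100 * qHi), " bp)")
  lo <- margin
  hi <- refLen - margin
  pos <- NULL
  for (try in seq_len(maxTries)) {
    cand <- sort(floor(runif(nSites, lo, hi)))
    if (all(diff(cand) >= minSep) && .lowNContent(reference, cand, qHi)) {
      pos <- cand
      break
    }
  }
  if (is.null(pos))
    stop("could not place ", nSites, " sites with minimum separation ",
         round(minSep), " bp in ", maxTries, " tries")
  famIdx <- sample(rep(seq_len(config$nFamilies), config$sitesPerFamily))
  freq <- numeric(nSites)
  for (f in seq_len(config$nFamilies))
    freq[famIdx == f] <- sample(config$frequencies)
  consensi <- as.character(library@sequences)
  seqs <- vapply(seq_len(nSites), function(i)
    mutateSequence(consensi[famIdx[i]], config$mutationRate), character(1))
  sites <- data.frame(pos = pos,
                      alu = names(library@sequences)[famIdx],
                      family = library@family[famIdx],
                      freq = freq, len = nchar(seqs), seq = seqs)
  carriers <- matrix(runif(config$nHaploids * nSites) <
                       rep(freq, each = config$nHaploids),
                     nrow = config$nHaploids, ncol = nSites)
  new("AluSimulation", reference = Biostrings::DNAString(reference),
      chrom = config$chrom, library = library, sites = sites,
      carriers = carriers, config = unclass(config))
}

.lowNContent <- function(reference, pos, qHi, maxFrac = 0.01) {
  ## synthetic references carry no N; scan windows only when one might
  if (!grepl("N", reference, fixed = TRUE)) return(TRUE)
  w <- ceiling(qHi)
  for (p in pos) {
    win <- substr(reference, max(1, p - w), min(nchar(reference), p + w))
    if (lengths(regmatches(win, gregexpr("N", win))) / nchar(win) > maxFrac)
      return(FALSE)
  }
  TRUE
}

#' Pair haploid chromosomes into diploid individuals
#'
#' Haploids are paired sequentially (1+2, 3+4, ...).
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @return data.frame: \code{ind}, \code{hap1}, \code{hap2}.
#' @export
buildPopulation <- function(sim) {
  nH <- nrow(sim@carriers)
  if (nH %% 2L != 0L)
    stop("odd number of haploid chromosomes (", nH, ") cannot be paired")
  data.frame(ind = sprintf("ind%02d", seq_len(nH / 2L)),
             hap1 = seq(1L, nH, by = 2L), hap2 = seq(2L, nH, by = 2L))
}

#' Simulate trios
#'
#' For each trio, four fresh parental haploids are drawn from the site
#' frequencies; the child receives one uniformly chosen haploid from each
#' parent (an exact copy, so child haplotypes match a parental haplotype by
#' construction).
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @param nTrios Number of trios.
#' @return A list: \code{carriers} (4 parental haploid rows per trio) and
#'   \code{pedigree} data.frame with one row per member (\code{trio},
#'   \code{member}, \code{ind}, \code{hap1}, \code{hap2} indexing carrier
#'   rows).
#' @export
buildTrios <- function(sim, nTrios) {
  nSites <- nrow(sim@sites)
  freq <- sim@sites$freq
  carriers <- matrix(runif(4L * nTrios * nSites) <
                       rep(freq, each = 4L * nTrios),
                     nrow = 4L * nTrios, ncol = nSites)
  ped <- vector("list", nTrios)
  for (tr in seq_len(nTrios)) {
    r <- (tr - 1L) * 4L
    fromF <- r + sample(1:2, 1L)
    fromM <- r + 2L + sample(1:2, 1L)
    ped[[tr]] <- data.frame(
      trio = tr,
      member = c("father", "mother", "child"),
      ind = sprintf("t%02d_%s", tr, c("f", "m", "c")),
      hap1 = c(r + 1L, r + 3L, fromF),
      hap2 = c(r + 2L, r + 4L, fromM))
  }
  list(carriers = carriers, pedigree = do.call(rbind, ped))
}

#' The reference containing every planted element
#'
#' Splices all planted copies into the reference; the result is the
#' "all-Alu" benchmark reference against which deletions are genotyped, with
#' one annotation per planted element (coordinates in the spliced sequence).
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @return A list: \code{seq} (character), \code{annotations} data.frame
#'   (\code{chrom}, \code{start}, \code{end}, \code{family}, \code{alu},
#'   0-based half-open) and \code{offsets} (per-site cumulative shift).
#' @export
allAluReference <- function(sim) {
  ref <- as.character(sim@reference)
  sites <- sim@sites
  n <- nrow(sites)
  shift <- c(0, cumsum(sites$len))[seq_len(n)]
  starts <- sites$pos + shift
  pieces <- character(2L * n + 1L)
  prev <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substr(ref, prev + 1L, sites$pos[i])
    pieces[2L * i] <- sites$seq[i]
    prev <- sites$pos[i]
  }
  pieces[2L * n + 1L] <- substr(ref, prev + 1L, nchar(ref))
  list(seq = paste(pieces, collapse = ""),
       annotations = data.frame(chrom = sim@chrom, start = starts,
                                end = starts + sites$len,
                                family = sites$family, alu = sites$alu),
       offsets = shift)
}

## Haplotype sequence for one carrier profile (logical vector over sites).
.haplotypeSeq <- function(sim, carried) {
  ref <- as.character(sim@reference)
  sites <- sim@sites[carried, , drop = FALSE]
  n <- nrow(sites)
  if (n == 0L) return(ref)
  pieces <- character(2L * n + 1L)
  prev <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substr(ref, prev + 1L, sites$pos[i])
    pieces[2L * i] <- sites$seq[i]
    prev <- sites$pos[i]
  }
  pieces[2L * n + 1L] <- substr(ref, prev + 1L, nchar(ref))
  paste(pieces, collapse = "")
}

#' Simulate paired-end reads for one haploid chromosome
#'
#' Draws fragments uniformly along the haplotype (count = coverage x length
#' / (2 x read length), outer insert Gaussian), and emits the truth
#' alignment of every read against the chosen target reference by
#' construction, bypassing an external aligner: reads lying entirely in
#' sequence present in the target map uniquely at their projected
#' coordinates; reads overlapping sequence absent from the target (planted
#' elements when mapping to the element-free reference) are emitted unmapped
#' with their sequence, to be classified against the consensus library;
#' reads crossing a junction absent from the target (a deleted element's
#' breakpoint) are split and emitted unmapped without sequence.  Substitution
#' errors at \code{errorRate} are applied to emitted sequences (the truth
#' alignment of a mappable read is unchanged by the ~2 errors a 100 bp read
#' acquires at 2\%).
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @param carried Logical vector over sites (a carrier-matrix row), or a
#'   haploid row index.
#' @param target "insertion" (map against the element-free reference) or
#'   "deletion" (map against the all-element reference).
#' @param errorRate Per-base substitution error; defaults to the config.
#' @param ind Individual label for the emitted pairs.
#' @param carriers Optional carrier matrix to index with a row number
#'   (defaults to \code{simCarriers(sim)}; used for trio cohorts).
#' @return A \link{pairsTable} (data.frame), coordinate-sorted.
#' @export
simulateHaploidReads <- function(sim, carried,
                                 target = c("insertion", "deletion"),
                                 errorRate = NULL, ind = "ind01",
                                 carriers = NULL) {
  target <- match.arg(target)
  cfg <- sim@config
  if (is.null(errorRate)) errorRate <- cfg$errorRate
  if (length(carried) == 1L && is.numeric(carried)) {
    if (is.null(carriers)) carriers <- sim@carriers
    carried <- carriers[carried, ]
  }
  sites <- sim@sites
  refLen <- length(sim@reference)
  L <- cfg$readLength
  carLen <- sites$len[carried]
  carPos <- sites$pos[carried]
  csum <- cumsum(carLen)
  hapLen <- refLen + sum(carLen)
  elemStart <- carPos + c(0, head(csum, -1L))
  elemEnd <- elemStart + carLen

  nFrag <- round(cfg$coverage * hapLen / (2 * L))
  ins <- pmax(2L * L, round(rnorm(nFrag, cfg$insertMean, cfg$insertSd)))
  fs <- floor(runif(nFrag) * (hapLen - ins))
  s1 <- fs; e1 <- fs + L
  s2 <- fs + ins - L; e2 <- fs + ins

  if (target == "insertion") {
    ## breakpoints delimit planted elements; even regions are reference
    B <- as.numeric(rbind(elemStart, elemEnd))
    regOf <- function(s, e) {
      rs <- findInterval(s, B)
      re <- findInterval(pmax(s, e - 1L), B)
      ok <- rs == re & rs %% 2L == 0L
      list(ok = ok, reg = rs)
    }
    offsets <- c(0, csum)          # cumulative element length per region pair
    mapPos <- function(s, reg) s - offsets[reg / 2L + 1L]
    needSeqIfUnmapped <- TRUE
  } else {
    ## breakpoints are the haplotype coordinates of sites NOT carried: a read
    ## crossing one is junction-split; mapped positions shift right by the
    ## lengths of missing elements to the left
    missPos <- sites$pos[!carried]
    missLen <- sites$len[!carried]
    shiftBefore <- vapply(missPos, function(p) sum(carLen[carPos < p]),
                          numeric(1))
    missHap <- missPos + shiftBefore
    missCsum <- cumsum(missLen)
    regOf <- function(s, e) {
      ## a junction point p with s < p < e splits the read; a read starting
      ## exactly at p maps entirely to the right side
      rs <- findInterval(s, missHap)
      re <- findInterval(pmax(s, e - 1L), missHap)
      ok <- rs == re
      list(ok = ok, reg = rs)
    }
    mapPos <- function(s, reg) s + c(0, missCsum)[reg + 1L]
    needSeqIfUnmapped <- FALSE
  }

  r1 <- regOf(s1, e1)
  r2 <- regOf(s2, e2)
  mapped1 <- r1$ok
  mapped2 <- r2$ok
  ms1 <- ifelse(mapped1, mapPos(s1, r1$reg), NA_real_)
  ms2 <- ifelse(mapped2, mapPos(s2, r2$reg), NA_real_)
  me1 <- ms1 + L
  me2 <- ms2 + L
  isize <- ifelse(mapped1 & mapped2,
                  pmax(me1, me2) - pmin(ms1, ms2), NA_real_)

  seq1 <- rep(NA_character_, nFrag)
  seq2 <- rep(NA_character_, nFrag)
  if (needSeqIfUnmapped && (any(!mapped1) || any(!mapped2))) {
    hap <- .haplotypeSeq(sim, carried)
    i1 <- which(!mapped1)
    i2 <- which(!mapped2)
    seq1[i1] <- .applyErrors(substring(hap, s1[i1] + 1L, e1[i1]), errorRate)
    ## second read is sequenced from the - strand
    seq2[i2] <- .applyErrors(.revcomp(substring(hap, s2[i2] + 1L, e2[i2])),
                             errorRate)
  }

  pairs <- data.frame(
    pairId = seq_len(nFrag), ind = ind,
    chrom1 = sim@chrom, start1 = ms1, end1 = me1, strand1 = "+",
    mapped1 = mapped1, b1 = ifelse(mapped1, 1L, NA_integer_), seq1 = seq1,
    chrom2 = sim@chrom, start2 = ms2, end2 = me2, strand2 = "-",
    mapped2 = mapped2, b2 = ifelse(mapped2, 1L, NA_integer_), seq2 = seq2,
    isize = isize)
  pairs[order(.pairsSortKey(pairs)), , drop = FALSE]
}

#' Simulate reads for a diploid individual
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @param haps Integer vector of two haploid row indices (or a list of two
#'   logical carrier vectors).
#' @inheritParams simulateHaploidReads
#' @return A coordinate-sorted \link{pairsTable} with unique pair ids.
#' @export
simulateIndividualReads <- function(sim, haps,
                                    target = c("insertion", "deletion"),
                                    errorRate = NULL, ind = "ind01",
                                    carriers = NULL) {
  target <- match.arg(target)
  p1 <- simulateHaploidReads(sim, haps[[1L]], target, errorRate, ind,
                             carriers)
  p2 <- simulateHaploidReads(sim, haps[[2L]], target, errorRate, ind,
                             carriers)
  p2$pairId <- p2$pairId + max(p1$pairId)
  pairs <- rbind(p1, p2)
  pairs <- pairs[order(.pairsSortKey(pairs)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.applyErrors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Mean number of planted elements per haploid chromosome
#'
#' @param sim An \linkS4class{AluSimulation}.
#' @return A list: \code{mean}, \code{min}, \code{max} of per-haploid
#'   planted-site counts.
#' @export
plantedPerHaploid <- function(sim) {
  counts <- rowSums(sim@carriers)
  list(mean = mean(counts), min = min(counts), max = max(counts),
       counts = counts)
}
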