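#' Inverse-variance estimation of the element length offsets
#'
#' The true length of an inserted element is modelled as
#' \code{lAlu + lambda + rho}: the matched consensus length plus signed left
#' and right offsets.  Each supporting read pair t gives a per-read estimate
#' with standard deviation \code{st} (the individual's insert sd):
#' for left supports (anchor left of the insertion point \code{pAlu}),
#' \code{lambda^t = mt - dt - at} with \code{dt = pAlu - ct}; for right
#' supports, \code{rho^t = mt - dt - at'} with \code{dt = ct - pAlu} and
#' \code{at' = lAlu - at}.  Here \code{ct} is the anchor read start,
#' \code{at} the Alu read's offset within the consensus and \code{mt} the
#' individual's mean anchor-to-mate start-to-start distance (outer insert
#' mean minus the read length).  The maximum-likelihood combination is the
#' inverse-variance weighted mean; its standard error is
#' \code{(sum 1/st^2)^(-1/2)}.  Per-read estimates may be negative.
#'
#' @param supports data.frame with columns \code{ct}, \code{at}, \code{mt},
#'   \code{st} (one row per supporting pair on the relevant side).
#' @param pAlu Current insertion point estimate (bp).
#' @param lAlu Consensus length (bp; \code{estimateRho} only).
#' @return A list \code{list(estimate, se, n)}; with no supports the
#'   estimate is flagged undefined (\code{estimate = 0, se = Inf, n = 0}).
#' @examples
#' estimateLambda(data.frame(ct = 4800, at = 120, mt = 400, st = 50), 5000)
#' @export
estimateLambda <- function(supports, pAlu) {
  if (NROW(supports) == 0L)
    return(list(estimate = 0, se = Inf, n = 0L))
  dt <- pAlu - supports$ct
  est <- supports$mt - dt - supports$at
  .ivw(est, supports$st)
}

#' @rdname estimateLambda
#' @export
estimateRho <- function(supports, pAlu, lAlu) {
  if (NROW(supports) == 0L)
    return(list(estimate = 0, se = Inf, n = 0L))
  dt <- supports$ct - pAlu
  atMinus <- lAlu - supports$at
  est <- supports$mt - dt - atMinus
  .ivw(est, supports$st)
}

.ivw <- function(est, st) {
  w <- 1 / st^2
  list(estimate = sum(w * est) / sum(w), se = 1 / sqrt(sum(w)),
       n = length(est))
}

#' Re-estimate the insertion point from all supports
#'
#' Isolates \code{pAlu} from the per-read length equations given the current
#' offsets: left supports give \code{pAlu^t = ct + mt - at - lambda}, right
#' supports \code{pAlu^t = ct - mt + (lAlu - at) + rho}; the joint estimate
#' is the inverse-variance weighted mean over both sides.
#'
#' @param left,right Support data.frames (columns \code{ct}, \code{at},
#'   \code{mt}, \code{st}); either may be empty.
#' @param lambda,rho Current offset estimates.
#' @param lAlu Consensus length (bp).
#' @return A list \code{list(estimate, se, n)}.
#' @export
reestimatePosition <- function(left, right, lambda, rho, lAlu) {
  est <- numeric()
  st <- numeric()
  if (NROW(left)) {
    est <- c(est, left$ct + left$mt - left$at - lambda)
    st <- c(st, left$st)
  }
  if (NROW(right)) {
    est <- c(est, right$ct - right$mt + (lAlu - right$at) + rho)
    st <- c(st, right$st)
  }
  if (!length(est)) stop("position re-estimation needs at least one support")
  .ivw(est, st)
}

#' Refine a candidate insertion by coordinate ascent
#'
#' Alternates length-offset estimation (lambda from left supports, rho from
#' right supports) and position re-estimation until the position moves less
#' than \code{tol} bp or \code{maxIter} iterations are reached.  Supports are
#' Alu mates: l-labelled mates are left supports, r-labelled right supports;
#' a support whose anchor sits exactly at the insertion point is treated as
#' left (deterministic tie-break).
#'
#' @param position Initial insertion point (bp), e.g. a cover solution
#'   position.
#' @param supports data.frame of supporting mates with columns \code{label},
#'   \code{start}, \code{end} (anchor, 0-based half-open), \code{at},
#'   \code{mt}, \code{st}, and optionally \code{alu}, \code{family},
#'   \code{chrom}.
#' @param lAlu Matched consensus length (bp).
#' @param maxIter Maximum iterations (default 10).
#' @param tol Position convergence tolerance in bp (default 1).
#' @return A \linkS4class{CandidateInsertion}.
#' @export
refineCandidate <- function(position, supports, lAlu, maxIter = 10L,
                            tol = 1) {
  stopifnot(NROW(supports) >= 1L)
  supports$ct <- supports$start
  chrom <- if (!is.null(supports$chrom)) supports$chrom[1L] else "chr"
  aluName <- if (!is.null(supports$alu))
    names(sort(table(supports$alu), decreasing = TRUE))[1L] else NA_character_
  fam <- if (!is.null(supports$family))
    names(sort(table(supports$family), decreasing = TRUE))[1L] else NA_character_
  lambda <- 0
  rho <- 0
  lamSE <- NA_real_
  rhoSE <- NA_real_
  p <- position
  converged <- FALSE
  it <- 0L
  isLeft <- supports$label == "l"
  ## The per-read equations only identify p + lambda and p - rho jointly, so
  ## estimating the offsets first would freeze p at its seed value.  Seed the
  ## loop with the position implied by the supports under lambda = rho = 0.
  p <- reestimatePosition(supports[isLeft, , drop = FALSE],
                          supports[!isLeft, , drop = FALSE],
                          0, 0, lAlu)$estimate
  for (it in seq_len(maxIter)) {
    left <- supports[isLeft, , drop = FALSE]
    right <- supports[!isLeft, , drop = FALSE]
    lam <- estimateLambda(left, p)
    rh <- estimateRho(right, p, lAlu)
    lambda <- lam$estimate
    rho <- rh$estimate
    lamSE <- if (lam$n) lam$se else NA_real_
    rhoSE <- if (rh$n) rh$se else NA_real_
    newP <- reestimatePosition(left, right, lambda, rho, lAlu)$estimate
    if (abs(newP - p) < tol) {
      p <- newP
      converged <- TRUE
      break
    }
    p <- newP
  }
  new("CandidateInsertion", chrom = as.character(chrom), position = p,
      alu = aluName, family = fam, lAlu = as.numeric(lAlu),
      lambda = lambda, rho = rho, lambdaSE = lamSE, rhoSE = rhoSE,
      supports = supports, converged = converged, iterations = it)
}

#' Splice an element into a reference sequence in silico
#'
#' Builds the in-silico haplotype carrying the candidate insertion: the
#' matched consensus, trimmed (negative offset) or padded with copies of its
#' own flank (positive offset) on each side, spliced at the insertion point.
#' Original coordinates at or beyond the insertion point shift right by the
#' inserted length.
#'
#' @param reference A \link[Biostrings]{DNAString} or character scalar.
#' @param position Insertion point (0-based bp).
#' @param consensus Consensus sequence (character or DNAString).
#' @param lambda,rho Signed length offsets (bp, rounded to integers).
#' @return A list: \code{seq} (character), \code{position}, \code{length}
#'   (inserted length), \code{insert} (the inserted sequence) and \code{map},
#'   a function translating original coordinates to in-silico coordinates.
#' @export
insertInSilico <- function(reference, position, consensus, lambda = 0,
                           rho = 0) {
  ref <- as.character(reference)
  cons <- as.character(consensus)
  lambda <- round(lambda)
  rho <- round(rho)
  lAlu <- nchar(cons)
  total <- lAlu + lambda + rho
  if (total <= 0)
    stop("estimated element length ", total, " is not positive")
  position <- round(position)
  if (position < 0 || position > nchar(ref))
    stop("insertion point outside the reference")
  ins <- cons
  if (lambda < 0) ins <- substr(ins, 1L - lambda, nchar(ins))
  if (rho < 0) ins <- substr(ins, 1L, nchar(ins) + rho)
  if (lambda > 0)
    ins <- paste0(substr(cons, 1L, lambda), ins)
  if (rho > 0)
    ins <- paste0(ins, substr(cons, lAlu - rho + 1L, lAlu))
  stopifnot(nchar(ins) == total)
  seq <- paste0(substr(ref, 1L, position), ins,
                substr(ref, position + 1L, nchar(ref)))
  list(seq = seq, position = position, length = total, insert = ins,
       map = function(x) ifelse(x >= position, x + total, x))
}

#' Genotype a candidate insertion by reduction to the deletion model
#'
#' After the in-silico insertion the element is present in the (modified)
#' reference, so each individual can be genotyped with the deletion
#' algorithm.  The spanning set is assembled in in-silico coordinates:
#' mapped pairs near the site keep their insert (adding the element length
#' when their inner gap straddles the insertion point; pairs whose reads
#' overlap the point itself are junction-split and ignored), and the
#' individual's Alu mates at the site are realigned into the inserted
#' element via their consensus offsets.  Copies of the element carried =
#' \code{2 - g} where g is the called deletion genotype: an individual
#' carrying the insertion on both haplotypes matches the in-silico reference
#' (g = 0), a non-carrier has it deleted on both (g = 2).
#'
#' @param candidate A refined \linkS4class{CandidateInsertion}.
#' @param pairsOf Named list of \link{pairsTable}s or a function
#'   \code{function(ind)}.
#' @param matesOf Named list of mates data.frames (or
#'   \linkS4class{AluMateSet}s), one per individual.
#' @param models Named list of per-individual models, or one model.
#' @param individuals Individual ids.
#' @param hwe,useWeights Passed to the deletion machinery.
#' @return A list: \code{perInd} data.frame (ind, ll0, ll1, ll2, g, copies,
#'   n) and \code{lrt} (the \code{\link{populationLrt}} result).
#' @export
genotypeInsertion <- function(candidate, pairsOf, matesOf, models,
                              individuals = NULL, hwe = TRUE,
                              useWeights = TRUE) {
  if (is.null(individuals))
    individuals <- if (is.function(pairsOf)) names(matesOf) else names(pairsOf)
  getPairs <- if (is.function(pairsOf)) pairsOf else function(i) pairsOf[[i]]
  getModel <- if (is(models, "InsertSizeModel")) function(i) models else
    function(i) models[[i]]
  lambda <- if (is.finite(candidate@lambda)) candidate@lambda else 0
  rho <- if (is.finite(candidate@rho)) candidate@rho else 0
  len <- round(candidate@lAlu + lambda + rho)
  if (len <= 0) stop("candidate has non-positive estimated length")
  p <- round(candidate@position)
  lik <- vector("list", length(individuals))
  for (i in seq_along(individuals)) {
    ind <- individuals[i]
    mod <- getModel(ind)
    sp <- insertionSpanningSet(candidate, getPairs(ind), matesOf[[ind]],
                               mod, p, len, lambda)
    gl <- genotypeDeletion(sp, mod, len, useWeights = useWeights)
    gl$ind <- ind
    lik[[i]] <- gl
  }
  lik <- do.call(rbind, lik)
  lik$copies <- 2L - lik$g
  lrt <- populationLrt(lik, hwe = hwe)
  list(perInd = lik[, c("ind", "ll0", "ll1", "ll2", "g", "copies", "n")],
       lrt = lrt)
}

## Spanning set for an in-silico inserted element, in in-silico coordinates.
insertionSpanningSet <- function(candidate, pairs, mates, model, p, len,
                                 lambda) {
  q <- insertQuantiles(model)[["qHi"]]
  ## window in original coordinates: [p - qHi, p + qHi); in-silico inserts
  ## element [p, p + len)
  t <- numeric()
  w <- numeric()
  if (NROW(pairs)) {
    onChrom <- pairs$mapped1 & pairs$mapped2 &
      pairs$chrom1 == candidate@chrom & pairs$chrom2 == candidate@chrom
    s <- pmin(pairs$start1, pairs$start2)
    e <- pmax(pairs$end1, pairs$end2)
    inner0 <- pmin(pairs$end1, pairs$end2)    # leftmost read end
    inner1 <- pmax(pairs$start1, pairs$start2) # rightmost read start
    inWin <- onChrom & s >= p - q & e <= p + q & !is.na(pairs$isize)
    ## only pairs whose inner gap straddles the insertion point overlap the
    ## in-silico element; pairs wholly on one side are uninformative and
    ## reads crossing the point itself are junction-split
    straddle <- inWin & inner0 <= p & inner1 >= p
    t <- c(t, pairs$isize[straddle] + len)
    w <- c(w, 1 / pmax(pairs$b1, pairs$b2)[straddle])
  }
  if (!is.null(mates)) {
    df <- if (is(mates, "AluMateSet")) aluMates(mates) else mates
    df <- df[df$chrom == candidate@chrom & df$start >= p - q &
               df$end <= p + q + len, , drop = FALSE]
    if (nrow(df)) {
      aluStart <- p + lambda + df$at  # in-silico position of the Alu read
      tm <- ifelse(df$label == "l",
                   aluStart + df$aluLen - df$start,
                   (df$end + len) - aluStart)
      t <- c(t, tm)
      w <- c(w, df$weight)
    }
  }
  list(t = as.numeric(t), w = as.numeric(w), n = length(t))
}
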