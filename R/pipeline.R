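#' Discover, refine and genotype insertions in one individual
#'
#' The single-individual insertion pipeline: scan the alignments for Alu
#' mates, sweep for candidate regions, solve the covering problem in each
#' region (cost k per introduced element), refine every accepted position by
#' the length/position coordinate ascent, and genotype the individual against
#' the in-silico insertion.
#'
#' @param pairs A coordinate-sorted \link{pairsTable} for the individual.
#' @param library An \linkS4class{AluLibrary}.
#' @param model The individual's \linkS4class{InsertSizeModel} (estimated
#'   from \code{pairs} when NULL).
#' @param readLen Read length (bp); inferred from the first available
#'   sequence when NULL.
#' @param sweepThreshold Sweep indicator threshold (default 3).
#' @param k Covering cost per element (default 3).
#' @param thresholds Alu-read classification thresholds.
#' @param mates Optional precomputed \linkS4class{AluMateSet} (skips the
#'   scan).
#' @param genotype Genotype each call via in-silico insertion (default
#'   TRUE).
#' @return A list: \code{calls} data.frame (chrom, pos, alu, family, len,
#'   lambda, rho, converged, nSupport, g, copies), \code{mates}, \code{model},
#'   \code{cover} (list of \linkS4class{CoverSolution}s per window).
#' @export
findInsertionsIndividual <- function(pairs, library, model = NULL,
                                     readLen = NULL, sweepThreshold = 3,
                                     k = 3, thresholds = aluReadThresholds(),
                                     mates = NULL, genotype = TRUE) {
  if (is.null(model)) model <- estimateInsertModel(pairs)
  if (is.null(mates)) mates <- scanAluMates(pairs, library, model, thresholds)
  if (is.null(readLen)) {
    sq <- c(pairs$seq1[!is.na(pairs$seq1)], pairs$seq2[!is.na(pairs$seq2)])
    readLen <- if (length(sq)) nchar(sq[1L]) else
      round(stats::median(pairs$end1 - pairs$start1, na.rm = TRUE))
  }
  res <- .discoverFromMates(mates, model, readLen, sweepThreshold, k,
                            library = library)
  calls <- res$calls
  if (genotype && nrow(calls)) {
    ind <- as.character(pairs$ind[1L])
    g <- integer(nrow(calls))
    copies <- integer(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      cand <- res$candidates[[i]]
      gt <- genotypeInsertion(cand,
                              pairsOf = setNames(list(pairs), ind),
                              matesOf = setNames(list(aluMates(mates)), ind),
                              models = model, individuals = ind)
      g[i] <- gt$perInd$g[1L]
      copies[i] <- gt$perInd$copies[1L]
    }
    calls$g <- g
    calls$copies <- copies
  } else if (nrow(calls)) {
    calls$g <- NA_integer_
    calls$copies <- NA_integer_
  }
  list(calls = calls, mates = mates, model = model, cover = res$cover)
}

## Discovery from a mate set only (no sequences needed): sweep + cover +
## refine.  Used by the pipeline and by threshold re-tuning.
.discoverFromMates <- function(mates, model, readLen, sweepThreshold, k,
                               library = NULL) {
  df <- if (is(mates, "AluMateSet")) aluMates(mates) else mates
  q <- insertQuantiles(model)[["qHi"]]
  emptyCalls <- data.frame(chrom = character(), pos = numeric(),
                           alu = character(), family = character(),
                           len = numeric(), lambda = numeric(),
                           rho = numeric(), converged = logical(),
                           nSupport = integer())
  if (!nrow(df))
    return(list(calls = emptyCalls, candidates = list(), cover = list()))
  windows <- sweepCandidateRegions(df, model, threshold = sweepThreshold)
  if (!nrow(windows))
    return(list(calls = emptyCalls, candidates = list(), cover = list()))
  inst <- coverInstance(df, model, readLen)
  lib <- NULL
  calls <- list()
  candidates <- list()
  covers <- list()
  for (wi in seq_len(nrow(windows))) {
    w <- windows[wi, ]
    sel <- which(df$chrom == w$chrom & inst$hi >= w$start - q &
                   inst$lo <= w$end + q)
    if (!length(sel)) next
    sol <- solveCoverSingle(inst[sel, , drop = FALSE], k = k)
    covers[[length(covers) + 1L]] <- sol
    for (a in seq_along(coverPositions(sol))) {
      supIdx <- sel[sol@support[[a]]]
      sup <- df[supIdx, , drop = FALSE]
      sup$mt <- insertMean(model) -
        ifelse(sup$label == "l", sup$aluLen, sup$end - sup$start)
      sup$st <- insertSd(model)
      cand <- refineCandidate(coverPositions(sol)[a], sup,
                              lAlu = .majorityConsensusLen(library, sup),
                              tol = 1)
      candidates[[length(candidates) + 1L]] <- cand
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = cand@chrom, pos = cand@position, alu = cand@alu,
        family = cand@family,
        len = cand@lAlu + .finiteOr(cand@lambda, 0) + .finiteOr(cand@rho, 0),
        lambda = cand@lambda, rho = cand@rho,
        converged = cand@converged, nSupport = nrow(sup))
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else emptyCalls
  ## deduplicate candidates closer than the insert window (keep best support)
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos)
    calls <- calls[o, , drop = FALSE]
    candidates <- candidates[o]
    keep <- rep(TRUE, nrow(calls))
    i <- 1L
    while (i < nrow(calls)) {
      j <- i + 1L
      if (keep[i] && keep[j] && calls$chrom[i] == calls$chrom[j] &&
          calls$pos[j] - calls$pos[i] < q) {
        drop <- if (calls$nSupport[i] >= calls$nSupport[j]) j else i
        keep[drop] <- FALSE
      }
      i <- i + 1L
    }
    calls <- calls[keep, , drop = FALSE]
    candidates <- candidates[keep]
  }
  rownames(calls) <- NULL
  list(calls = calls, candidates = candidates, cover = covers)
}

## length of the consensus most often matched by the supports; median Alu
## read span stands in when no library entry is identifiable
.majorityConsensusLen <- function(library, sup) {
  nm <- names(sort(table(sup$alu), decreasing = TRUE))[1L]
  if (!is.null(library) && !is.null(nm) &&
      nm %in% names(library@sequences))
    return(Biostrings::width(library@sequences)[
      match(nm, names(library@sequences))])
  stats::median(sup$aluLen) * 3
}

.finiteOr <- function(x, alt) if (is.finite(x)) x else alt

#' Discover insertions across individuals
#'
#' Runs the per-individual scan, pools the per-individual evidence with the
#' population covering heuristic (costs k1 per element in the population, k2
#' per individual assignment), refines each merged position and genotypes
#' every individual by in-silico reduction to the deletion model.
#'
#' @param pairsOf Named list of \link{pairsTable}s or a function
#'   \code{function(ind)}.
#' @param library An \linkS4class{AluLibrary}.
#' @param models Named list of models (estimated per individual when NULL
#'   and \code{pairsOf} is a list).
#' @param individuals Individual ids.
#' @param readLen Read length (bp).
#' @param k1,k2 Population covering costs (default 2, 2).
#' @param thresholds Classification thresholds.
#' @return A list: \code{calls} (merged positions with per-individual
#'   genotypes), \code{solution} (the \linkS4class{CoverSolution}),
#'   \code{matesOf}, \code{models}.
#' @export
findInsertions <- function(pairsOf, library, models = NULL,
                           individuals = NULL, readLen = 100L, k1 = 2,
                           k2 = 2, thresholds = aluReadThresholds()) {
  if (is.null(individuals))
    individuals <- if (is.function(pairsOf)) names(models) else names(pairsOf)
  getPairs <- if (is.function(pairsOf)) pairsOf else function(i) pairsOf[[i]]
  matesOf <- list()
  instOf <- list()
  if (is.null(models)) models <- list()
  for (ind in individuals) {
    pr <- getPairs(ind)
    if (is.null(models[[ind]])) models[[ind]] <- estimateInsertModel(pr)
    m <- scanAluMates(pr, library, models[[ind]], thresholds)
    matesOf[[ind]] <- aluMates(m)
    instOf[[ind]] <- coverInstance(m, models[[ind]], readLen)
  }
  sol <- solveCoverMulti(instOf, k1 = k1, k2 = k2,
                         model = models[[individuals[1L]]])
  calls <- list()
  for (a in seq_along(coverPositions(sol))) {
    pos <- coverPositions(sol)[a]
    inds <- sol@individuals[[a]]
    allMates <- do.call(rbind, matesOf[inds])
    q <- insertQuantiles(models[[inds[1L]]])[["qHi"]]
    sup <- allMates[abs(ifelse(allMates$label == "l", allMates$end,
                               allMates$start) - pos) <= 2 * q, ,
                    drop = FALSE]
    if (!nrow(sup)) next
    sup$mt <- vapply(seq_len(nrow(sup)), function(i)
      insertMean(models[[sup$ind[i]]]) -
        if (sup$label[i] == "l") sup$aluLen[i] else
          sup$end[i] - sup$start[i], numeric(1))
    sup$st <- vapply(sup$ind, function(i) insertSd(models[[i]]), numeric(1))
    cand <- refineCandidate(pos, sup,
                            lAlu = .majorityConsensusLen(library, sup))
    gt <- genotypeInsertion(cand, pairsOf, matesOf, models,
                            individuals = individuals)
    calls[[length(calls) + 1L]] <- list(candidate = cand, genotypes = gt)
  }
  list(calls = calls, solution = sol, matesOf = matesOf, models = models)
}

#' Assemble insertion calls into an AluCallSet
#'
#' Converts the output of \code{\link{findInsertions}} into an
#' \linkS4class{AluCallSet} (type "insertion") suitable for
#' \code{\link{writeCalls}}: one locus per merged candidate, per-individual
#' element copy numbers, and the population LRT per locus.
#'
#' @param found Result of \code{\link{findInsertions}}.
#' @param individuals Individual ids (defaults to those genotyped).
#' @param alpha,adjust Flagging parameters as in \code{\link{scanDeletions}}.
#' @return An \linkS4class{AluCallSet}.
#' @export
insertionCallSet <- function(found, individuals = NULL, alpha = 0.05,
                             adjust = "bonferroni") {
  calls <- found$calls
  n <- length(calls)
  if (is.null(individuals) && n)
    individuals <- calls[[1L]]$genotypes$perInd$ind
  nI <- length(individuals)
  df <- data.frame(chrom = character(n), start = numeric(n),
                   end = numeric(n), family = character(n),
                   alu = character(n), lAlu = numeric(n),
                   locus = seq_len(n), p = numeric(n), stat = numeric(n),
                   pvalue = numeric(n))
  geno <- matrix(NA_integer_, nI, n, dimnames = list(individuals, NULL))
  lik <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- calls[[i]]$candidate
    gt <- calls[[i]]$genotypes
    len <- round(cand@lAlu + .finiteOr(cand@lambda, 0) +
                   .finiteOr(cand@rho, 0))
    df$chrom[i] <- cand@chrom
    df$start[i] <- round(cand@position)
    df$end[i] <- round(cand@position) + len
    df$family[i] <- cand@family
    df$alu[i] <- cand@alu
    df$lAlu[i] <- len
    df$p[i] <- gt$lrt$p
    df$stat[i] <- gt$lrt$stat
    df$pvalue[i] <- gt$lrt$pvalue
    geno[match(gt$perInd$ind, individuals), i] <- gt$perInd$copies
    lik[[i]] <- gt$perInd
  }
  df$padj <- stats::p.adjust(df$pvalue, method = adjust)
  df$flagged <- df$padj <= alpha
  new("AluCallSet", calls = df, genotypes = geno, likelihoods = lik,
      type = "insertion")
}
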