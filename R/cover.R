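#' Interval of element positions covering an l or r read
#'
#' An element position alpha covers an l read (anchor to the left of the
#' implied element) when \code{lr + qLo <= alpha + L} and
#' \code{lr + qHi >= alpha}, where \code{lr} is the anchor's right endpoint;
#' symmetrically for r reads with left endpoint \code{rl}.  \code{qLo}/
#' \code{qHi} are the epsilon-quantiles of the anchor-to-mate spacing
#' distribution (the pipeline passes the mate-gap quantiles, i.e. outer
#' insert quantiles minus twice the read length, so that the interval width
#' \code{qHi - qLo + L} spans an element plus insert noise).
#'
#' @param pos Anchor endpoint: right endpoint \code{lr} for l reads, left
#'   endpoint \code{rl} for r reads (bp).
#' @param kind "l" or "r" (vectorised).
#' @param qLo,qHi Spacing quantiles (bp), \code{qLo < qHi}.
#' @param readLen Read length L (bp).
#' @return A two-column matrix \code{cbind(lo, hi)} of interval bounds.
#' @examples
#' coverInterval(1000, "l", 200, 600, 100)  # [1100, 1600]
#' coverInterval(2000, "r", 200, 600, 100)  # [1400, 1900]
#' @export
coverInterval <- function(pos, kind, qLo, qHi, readLen) {
  stopifnot(qLo <= qHi)
  lo <- ifelse(kind == "l", pos + qLo - readLen, pos - qHi)
  hi <- ifelse(kind == "l", pos + qHi, pos - qLo + readLen)
  cbind(lo = lo, hi = hi)
}

#' Build a covering instance from Alu mates
#'
#' @param mates An \linkS4class{AluMateSet} or mates data.frame (one
#'   chromosome).
#' @param model The individual's \linkS4class{InsertSizeModel}.
#' @param readLen Read length (bp).
#' @return A data.frame with columns \code{lo}, \code{hi} (cover interval),
#'   \code{pos} (anchor endpoint), \code{kind}, \code{weight}.
#' @export
coverInstance <- function(mates, model, readLen) {
  df <- if (is(mates, "AluMateSet")) aluMates(mates) else mates
  gq <- gapQuantiles(model, readLen)
  pos <- ifelse(df$label == "l", df$end, df$start)
  iv <- coverInterval(pos, df$label, gq[["qLo"]], gq[["qHi"]], readLen)
  data.frame(lo = iv[, "lo"], hi = iv[, "hi"], pos = pos,
             kind = df$label, weight = df$weight,
             ind = if (!is.null(df$ind)) df$ind else NA_character_)
}

#' Optimal single-individual covering by dynamic programming
#'
#' Solves the interval-stabbing-with-outliers problem: choose element
#' positions A and error reads E minimising \code{|E| + k |A|}, every read
#' either covered by a chosen position inside its cover interval or declared
#' an error.  Candidate positions are restricted to interval right endpoints
#' (standard interval-stabbing argument; preserves optimality).  Ties between
#' equal-cost solutions are broken toward fewer errors, then leftmost
#' positions.
#'
#' @param instance data.frame with columns \code{lo}, \code{hi} (one row per
#'   read), e.g. from \code{\link{coverInstance}}.
#' @param k Cost of introducing an element position (default 3).
#' @return A \linkS4class{CoverSolution}.
#' @export
solveCoverSingle <- function(instance, k = 3) {
  stopifnot(k > 0)
  n <- nrow(instance)
  if (n == 0L)
    return(new("CoverSolution", positions = numeric(), errors = integer(),
               support = list(), individuals = list(), objective = 0,
               k = k))
  lo <- instance$lo
  hi <- instance$hi
  ## right endpoints suffice: any stabbing point slides right to the nearest
  ## covered interval's right endpoint without losing coverage
  cand <- sort(unique(hi))
  M <- length(cand)
  ## covers[[j]]: reads covered by candidate j (interval sets are contiguous
  ## runs over the sorted candidates)
  covers <- lapply(seq_len(M), function(j)
    which(lo <= cand[j] & cand[j] <= hi))
  covN <- lengths(covers)
  ## G[j]: best (covered - k * |A|) over solutions whose rightmost chosen
  ## position is cand[j]; cov2[j1, j2] overlap handled pairwise because each
  ## interval covers a contiguous candidate run.
  G <- rep(-Inf, M)
  Gcov <- rep(0L, M)      # covered count of the tracked solution
  back <- rep(0L, M)
  for (j in seq_len(M)) {
    bestVal <- covN[j] - k
    bestCov <- covN[j]
    bestBack <- 0L
    if (j > 1L) for (jp in seq_len(j - 1L)) {
      ov <- sum(lo[covers[[j]]] <= cand[jp] & cand[jp] <= hi[covers[[j]]])
      val <- G[jp] + covN[j] - ov - k
      cv <- Gcov[jp] + covN[j] - ov
      if (val > bestVal + 1e-9 ||
          (abs(val - bestVal) <= 1e-9 && cv > bestCov)) {
        bestVal <- val
        bestCov <- cv
        bestBack <- jp
      }
    }
    G[j] <- bestVal
    Gcov[j] <- bestCov
    back[j] <- bestBack
  }
  ## bestJ = 0 is the empty solution (value 0, nothing covered); prefer more
  ## coverage (= fewer errors) among equal-value solutions.
  bestJ <- 0L
  bestVal <- 0
  bestCov <- 0L
  for (j in seq_len(M)) {
    if (G[j] > bestVal + 1e-9 ||
        (abs(G[j] - bestVal) <= 1e-9 && Gcov[j] > bestCov)) {
      bestJ <- j
      bestVal <- G[j]
      bestCov <- Gcov[j]
    }
  }
  positions <- numeric()
  j <- bestJ
  while (j != 0L) {
    positions <- c(cand[j], positions)
    j <- back[j]
  }
  covered <- logical(n)
  support <- vector("list", length(positions))
  for (a in seq_along(positions)) {
    s <- which(lo <= positions[a] & positions[a] <= hi)
    support[[a]] <- s
    covered[s] <- TRUE
  }
  errors <- which(!covered)
  new("CoverSolution", positions = positions, errors = as.integer(errors),
      support = support,
      individuals = rep(list(character()), length(positions)),
      objective = length(errors) + k * length(positions), k = k)
}

#' Verify feasibility and objective of a cover solution
#'
#' Independent checker: every read must be covered by a chosen position
#' inside its interval (with its individual assigned there, for
#' multi-individual solutions) or listed as an error, and the recorded
#' objective must match \code{|E| + k|A|} (or
#' \code{|E| + k1 |A| + k2 sum_j |A_j|}).
#'
#' @param instance The instance data.frame (\code{lo}, \code{hi}, optionally
#'   \code{ind}).
#' @param solution A \linkS4class{CoverSolution}.
#' @return TRUE, or a character description of the violation.
#' @export
verifyCoverSolution <- function(instance, solution) {
  n <- nrow(instance)
  covered <- logical(n)
  multi <- any(lengths(solution@individuals) > 0)
  for (a in seq_along(solution@positions)) {
    al <- solution@positions[a]
    hit <- instance$lo <= al & al <= instance$hi
    if (multi)
      hit <- hit & instance$ind %in% solution@individuals[[a]]
    covered[hit] <- TRUE
  }
  covered[solution@errors] <- TRUE
  if (!all(covered))
    return(paste("uncovered reads:",
                 paste(which(!covered), collapse = ",")))
  obj <- if (multi)
    length(solution@errors) + solution@k[1L] * length(solution@positions) +
      solution@k[2L] * sum(lengths(solution@individuals))
  else
    length(solution@errors) + solution@k[1L] * length(solution@positions)
  if (abs(obj - solution@objective) > 1e-9)
    return(sprintf("objective mismatch: recorded %g, recomputed %g",
                   solution@objective, obj))
  TRUE
}

#' Sweep for candidate insertion regions
#'
#' Single left-to-right pass: at a position p the indicator is the (1/b-
#' weighted) number of l-read anchors with right endpoint in
#' \code{[p - qHi, p]} plus r-read anchors with left endpoint in
#' \code{[p, p + qHi]}.  The indicator is piecewise constant between read
#' endpoints, so it is evaluated only there; maximal runs with indicator >=
#' \code{threshold} become candidate windows.
#'
#' @param mates An \linkS4class{AluMateSet} or mates data.frame.
#' @param model An \linkS4class{InsertSizeModel}.
#' @param threshold Minimum indicator value (default 3, mirroring k).
#' @param qHi Window size; defaults to the model's outer \code{qHi}.
#' @return data.frame of windows: \code{chrom}, \code{start}, \code{end},
#'   \code{score} (maximum indicator inside).
#' @export
sweepCandidateRegions <- function(mates, model, threshold = 3, qHi = NULL) {
  df <- if (is(mates, "AluMateSet")) aluMates(mates) else mates
  if (is.null(qHi)) qHi <- insertQuantiles(model)[["qHi"]]
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    lpos <- d$end[d$label == "l"]
    lw <- d$weight[d$label == "l"]
    rpos <- d$start[d$label == "r"]
    rw <- d$weight[d$label == "r"]
    evals <- sort(unique(c(lpos, lpos + qHi, rpos, rpos - qHi)))
    if (!length(evals)) next
    score <- vapply(evals, function(p)
      sum(lw[lpos >= p - qHi & lpos <= p]) +
        sum(rw[rpos >= p & rpos <= p + qHi]), numeric(1))
    above <- score >= threshold
    if (!any(above)) next
    runs <- rle(above)
    idx <- cumsum(runs$lengths)
    startIdx <- c(1L, head(idx, -1L) + 1L)
    for (rr in which(runs$values)) {
      i0 <- startIdx[rr]
      i1 <- idx[rr]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = evals[i0], end = evals[i1],
        score = max(score[i0:i1]))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric()))
  do.call(rbind, out)
}

#' Heuristic multi-individual covering
#'
#' Implements the population heuristic: (i) within each individual, cluster
#' l/r reads whose cover intervals are mutually close (within a window of
#' twice the spacing quantile) and keep clusters with at least two reads;
#' (ii) merge candidate positions across individuals when within
#' \code{mergeDist}; (iii) assign an individual to a merged position when it
#' contributes at least two covering reads there, otherwise its reads are
#' error-labelled.  Objective: \code{|E| + k1 |A| + k2 sum_j |A_j|}.
#'
#' @param instances Named list (per individual) of instance data.frames from
#'   \code{\link{coverInstance}}.
#' @param k1,k2 Population and per-individual element costs (default 2 and
#'   2).
#' @param mergeDist Merge distance across individuals (default: the outer
#'   \code{qHi} of \code{model}).
#' @param model Optional \linkS4class{InsertSizeModel} used for the default
#'   \code{mergeDist}.
#' @param minReads Reads required per individual (default 2).
#' @return A \linkS4class{CoverSolution}; read indices refer to
#'   \code{do.call(rbind, instances)} row order.
#' @export
solveCoverMulti <- function(instances, k1 = 2, k2 = 2, mergeDist = NULL,
                            model = NULL, minReads = 2L) {
  if (is.null(mergeDist)) {
    if (is.null(model)) stop("provide mergeDist or model")
    mergeDist <- insertQuantiles(model)[["qHi"]]
  }
  inds <- names(instances)
  all <- do.call(rbind, instances)
  all$indIdx <- rep(inds, vapply(instances, nrow, integer(1)))
  n <- nrow(all)
  ## (i) per-individual candidate positions
  candPos <- numeric()
  for (ind in inds) {
    inst <- instances[[ind]]
    if (!nrow(inst)) next
    mid <- (inst$lo + inst$hi) / 2
    o <- order(mid)
    mid <- mid[o]
    grp <- cumsum(c(1, diff(mid) > 2 * mergeDist))
    for (gi in unique(grp)) {
      sel <- mid[grp == gi]
      if (length(sel) >= minReads)
        candPos <- c(candPos, median(sel))
    }
  }
  if (!length(candPos)) {
    sol <- new("CoverSolution", positions = numeric(), errors = seq_len(n),
               support = list(), individuals = list(),
               objective = n, k = c(k1, k2))
    return(sol)
  }
  ## (ii) merge across individuals
  candPos <- sort(candPos)
  grp <- cumsum(c(1, diff(candPos) > mergeDist))
  merged <- vapply(split(candPos, grp), median, numeric(1))
  ## (iii) assign individuals
  positions <- numeric()
  support <- list()
  assigned <- list()
  covered <- logical(n)
  for (al in merged) {
    hit <- all$lo <= al & al <= all$hi
    keepInds <- character()
    sup <- integer()
    for (ind in unique(all$indIdx[hit])) {
      sel <- which(hit & all$indIdx == ind)
      if (length(sel) >= minReads) {
        keepInds <- c(keepInds, ind)
        sup <- c(sup, sel)
      }
    }
    if (length(keepInds)) {
      positions <- c(positions, al)
      support[[length(support) + 1L]] <- sup
      assigned[[length(assigned) + 1L]] <- keepInds
      covered[sup] <- TRUE
    }
  }
  errors <- which(!covered)
  new("CoverSolution", positions = positions, errors = as.integer(errors),
      support = support, individuals = assigned,
      objective = length(errors) + k1 * length(positions) +
        k2 * sum(lengths(assigned)),
      k = c(k1, k2))
}
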