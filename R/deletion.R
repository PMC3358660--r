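#' Collect the spanning set T for an annotated locus
#'
#' Builds the set of informative read pairs for genotyping a locus: all pairs
#' with both ends mapped inside the window extending \code{qHi} beyond each
#' side of the locus, plus any l/r Alu mates anchored in the window, realigned
#' to the locus element (their insert is recomputed against the element
#' coordinates from the consensus offset of the Alu read).  One-ended pairs
#' that are not Alu mates are ignored.
#'
#' @param locus A list or one-row data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param pairs A coordinate-sorted \link{pairsTable} for one individual.
#' @param model The individual's \linkS4class{InsertSizeModel}.
#' @param mates Optional \linkS4class{AluMateSet} (or mates data.frame) whose
#'   Alu reads matched this locus' element.
#' @param refLen Optional reference length for bounds checking.
#' @return A list with elements \code{t} (inserts, bp), \code{w} (weights),
#'   \code{n}, and \code{window}.
#' @export
collectSpanningSet <- function(locus, pairs, model, mates = NULL,
                               refLen = NULL) {
  if (!is.null(refLen) && (locus$start < 0 || locus$end > refLen))
    stop("locus [", locus$start, ", ", locus$end,
         ") lies outside the reference (length ", refLen, ")")
  q <- insertQuantiles(model)
  w0 <- locus$start - q[["qHi"]]
  w1 <- locus$end + q[["qHi"]]
  ## informative pairs overlap the element: the genotype products model every
  ## t in T as drawn from Y or Z = Y + lAlu, which only holds for pairs whose
  ## span intersects the annotated interval; window pairs wholly to one side
  ## are Y-distributed under every genotype and carry no signal
  keep <- pairs$mapped1 & pairs$mapped2 &
    pairs$chrom1 == locus$chrom & pairs$chrom2 == locus$chrom &
    pmin(pairs$start1, pairs$start2) >= w0 &
    pmax(pairs$end1, pairs$end2) <= w1 &
    pmax(pairs$end1, pairs$end2) > locus$start &
    pmin(pairs$start1, pairs$start2) < locus$end &
    !is.na(pairs$isize)
  t <- pairs$isize[keep]
  w <- 1 / pmax(pairs$b1[keep], pairs$b2[keep])
  if (!is.null(mates)) {
    df <- if (is(mates, "AluMateSet")) aluMates(mates) else mates
    df <- df[df$chrom == locus$chrom & df$start >= w0 & df$end <= w1, ,
             drop = FALSE]
    if (nrow(df)) {
      tm <- ifelse(df$label == "l",
                   (locus$start + df$at + df$aluLen) - df$start,
                   df$end - (locus$start + df$at))
      t <- c(t, tm)
      w <- c(w, df$weight)
    }
  }
  list(t = as.numeric(t), w = as.numeric(w), n = length(t),
       window = c(w0, w1))
}

#' Genotype a deletion from spanning insert lengths
#'
#' Computes the likelihood of the observed inserts under the three genotype
#' models, where g counts haplotypes carrying the deletion:
#' \deqn{P(D|0) = \prod_t Y(t), \quad
#'       P(D|1) = \prod_t (\tfrac13 Z(t) + \tfrac23 Y(t)), \quad
#'       P(D|2) = \prod_t Z(t)}
#' with Z = Y + lAlu.  The heterozygote mixture weight 1/3 reflects that a
#' window-spanning pair arises in one of three equally likely ways: from the
#' deletion-bearing haplotype, or from the element-bearing haplotype with one
#' end inside the element and the other to its left or to its right.  The
#' called genotype maximises the three log-likelihoods (ties toward smaller
#' g); the number of element copies carried is \code{2 - g}.
#'
#' @param spanning A spanning set from \code{\link{collectSpanningSet}}, or a
#'   numeric vector of insert lengths.
#' @param model An \linkS4class{InsertSizeModel}.
#' @param lAlu Element length (bp), > 0.
#' @param useWeights Multiply log-factors by read weights 1/b (default TRUE).
#' @return A one-row data.frame: \code{ll0}, \code{ll1}, \code{ll2} (natural
#'   log), \code{g} (NA when no informative pairs), \code{n}.
#' @export
genotypeDeletion <- function(spanning, model, lAlu, useWeights = TRUE) {
  if (lAlu <= 0) stop("lAlu must be > 0")
  if (is.numeric(spanning)) spanning <- list(t = spanning,
                                             w = rep(1, length(spanning)),
                                             n = length(spanning))
  t <- spanning$t
  w <- if (useWeights) spanning$w else rep(1, length(t))
  if (length(t) == 0L)
    return(data.frame(ll0 = 0, ll1 = 0, ll2 = 0, g = NA_integer_, n = 0L))
  dy <- insertDensity(model, t)
  dz <- shiftedDensity(model, t, lAlu)
  ll <- c(sum(w * log(dy)),
          sum(w * log(dz / 3 + 2 * dy / 3)),
          sum(w * log(dz)))
  g <- which(ll == max(ll))[1L] - 1L
  data.frame(ll0 = ll[1L], ll1 = ll[2L], ll2 = ll[3L], g = g,
             n = length(t))
}

## log(sum(exp(x))) without overflow; terms with weight 0 dropped.
.lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.popLoglik <- function(ll, logw) {
  tot <- 0
  for (i in seq_len(nrow(ll))) {
    v <- logw + ll[i, ]
    tot <- tot + .lse(v[is.finite(logw)])
  }
  tot
}

#' Likelihood-ratio test for a deletion across individuals
#'
#' Combines per-individual genotype likelihoods into a population test of the
#' presence of the non-reference allele.  Under Hardy-Weinberg equilibrium
#' (the default) the alternative has one free parameter, the allele frequency
#' p, with genotype weights ((1-p)^2, 2p(1-p), p^2); the statistic
#' \deqn{2\sum_i \log \hat L_i - 2\sum_i \log P(D_i|0)}
#' is referred to a chi-square distribution with 1 df.  Without HWE the
#' genotype frequencies (f0, f1, f2) are fitted on the simplex (EM) and the
#' statistic has 2 df.
#'
#' @param likelihoods A data.frame with columns \code{ll0}, \code{ll1},
#'   \code{ll2} (one row per individual; natural log), e.g. rbind of
#'   \code{\link{genotypeDeletion}} rows.
#' @param hwe Use the one-parameter HWE alternative (default TRUE).
#' @param tol Optimisation tolerance for the frequency estimate.
#' @return A list: \code{p} (allele-frequency MLE; NA when \code{hwe=FALSE}),
#'   \code{f} (genotype-frequency triple), \code{stat}, \code{df},
#'   \code{pvalue}, \code{loglik}, \code{loglik0}.
#' @export
populationLrt <- function(likelihoods, hwe = TRUE, tol = 1e-6) {
  ll <- as.matrix(likelihoods[, c("ll0", "ll1", "ll2")])
  if (nrow(ll) < 1L) stop("need at least one individual")
  loglik0 <- sum(ll[, 1L])
  if (hwe) {
    obj <- function(p) {
      w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      .popLoglik(ll, log(w))
    }
    opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = tol)
    cand <- c(0, opt$maximum, 1)
    val <- c(loglik0, opt$objective, sum(ll[, 3L]))
    best <- which.max(val)
    p <- cand[best]
    loglik <- val[best]
    f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    df <- 1L
  } else {
    f <- rep(1 / 3, 3)
    loglik <- .popLoglik(ll, log(f))
    for (it in seq_len(500L)) {
      ## E-step: posterior genotype memberships; M-step: mean responsibility
      post <- matrix(0, nrow(ll), 3L)
      for (i in seq_len(nrow(ll))) {
        v <- log(f) + ll[i, ]
        v <- exp(v - max(v[is.finite(v)]))
        v[!is.finite(v)] <- 0
        post[i, ] <- v / sum(v)
      }
      f <- pmax(colMeans(post), 0)
      f <- f / sum(f)
      new <- .popLoglik(ll, log(f))
      if (abs(new - loglik) < 1e-10) { loglik <- new; break }
      loglik <- new
    }
    p <- NA_real_
    df <- 2L
  }
  stat <- max(0, 2 * (loglik - loglik0))
  list(p = p, f = f, stat = stat, df = df,
       pvalue = pchisq(stat, df, lower.tail = FALSE),
       loglik = loglik, loglik0 = loglik0)
}

#' Genotype annotated Alu loci across individuals
#'
#' Runs the deletion genotyper at every annotated locus for every individual
#' and combines the evidence with the population likelihood-ratio test.  Loci
#' whose (multiplicity-adjusted) p-value passes \code{alpha} are flagged as
#' polymorphic deletions.  Per-individual genotypes are reported as copies of
#' the element, \code{2 - g}.
#'
#' @param annotations A data.frame (or GRanges) of annotated elements with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{family} (0-based
#'   half-open), sorted by position.
#' @param pairsOf Either a named list of \link{pairsTable}s (one per
#'   individual) or a function \code{function(ind)} returning one; the latter
#'   lets callers stream individuals without holding all alignments.
#' @param models Named list of per-individual
#'   \linkS4class{InsertSizeModel}s, or a single model used for all.
#' @param individuals Individual ids (defaults to \code{names(pairsOf)} or
#'   \code{names(models)}).
#' @param alpha Significance level on the adjusted LRT p-value (default
#'   0.05).
#' @param adjust Multiple-testing adjustment across loci: "bonferroni"
#'   (default), "BH" or "none".
#' @param hwe Use the 1-df HWE test (default TRUE).
#' @param useWeights Weight log-likelihood factors by 1/b (default TRUE).
#' @return An \linkS4class{AluCallSet} of type "deletion".
#' @export
scanDeletions <- function(annotations, pairsOf, models, individuals = NULL,
                          alpha = 0.05, adjust = c("bonferroni", "BH", "none"),
                          hwe = TRUE, useWeights = TRUE) {
  adjust <- match.arg(adjust)
  ann <- .asAnnotationDf(annotations)
  if (is.unsorted(ann$start)) stop("annotations must be sorted by position")
  if (is.null(individuals))
    individuals <- if (is.function(pairsOf)) names(models) else names(pairsOf)
  if (is.null(individuals) || !length(individuals))
    stop("cannot determine individual ids")
  getPairs <- if (is.function(pairsOf)) pairsOf else function(i) pairsOf[[i]]
  getModel <- if (is(models, "InsertSizeModel")) function(i) models else
    function(i) models[[i]]

  nL <- nrow(ann)
  nI <- length(individuals)
  likList <- vector("list", nL)
  for (l in seq_len(nL)) likList[[l]] <-
    data.frame(ind = individuals, ll0 = 0, ll1 = 0, ll2 = 0,
               g = NA_integer_, n = 0L)
  for (i in seq_len(nI)) {
    ind <- individuals[i]
    pr <- getPairs(ind)
    mod <- getModel(ind)
    for (l in seq_len(nL)) {
      loc <- ann[l, ]
      sp <- collectSpanningSet(loc, pr, mod)
      gl <- genotypeDeletion(sp, mod, loc$end - loc$start,
                             useWeights = useWeights)
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
  geno <- matrix(NA_integer_, nI, nL,
                 dimnames = list(individuals, NULL))
  for (l in seq_len(nL)) {
    lrt <- populationLrt(likList[[l]], hwe = hwe)
    calls$p[l] <- if (hwe) lrt$p else NA_real_
    calls$stat[l] <- lrt$stat
    calls$pvalue[l] <- lrt$pvalue
    geno[, l] <- 2L - likList[[l]]$g
  }
  calls$padj <- stats::p.adjust(calls$pvalue,
                                method = if (adjust == "none") "none"
                                else if (adjust == "BH") "BH" else "bonferroni")
  calls$flagged <- calls$padj <= alpha
  new("AluCallSet", calls = calls, genotypes = geno,
      likelihoods = likList, type = "deletion")
}

.asAnnotationDf <- function(annotations) {
  if (is(annotations, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(annotations)),
               start = GenomicRanges::start(annotations) - 1L,
               end = GenomicRanges::end(annotations),
               family = if (!is.null(annotations$family))
                 annotations$family else NA_character_)
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(annotations)))
    ann <- as.data.frame(annotations)
    if (is.null(ann$family)) ann$family <- NA_character_
    ann
  }
}
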