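#' The pairs table: one row per read pair
#'
#' @description
#' Alignment input to the scanning and genotyping stages is a plain
#' data.frame ("pairs table") with one row per read pair, using 0-based
#' half-open coordinates and outer insert lengths (rightmost end minus
#' leftmost start).  Columns:
#'
#' \describe{
#'   \item{pairId}{integer or character pair identifier}
#'   \item{ind}{individual id}
#'   \item{chrom1, start1, end1, strand1, mapped1, b1, seq1}{first end:
#'     chromosome, start, end (bp), strand ("+"/"-"), mapped flag,
#'     best-mapping count (integer >= 1; NA when unmapped) and read sequence
#'     (may be NA for mapped reads whose sequence is not needed)}
#'   \item{chrom2, ...}{likewise for the second end}
#'   \item{isize}{outer insert length (bp) when both ends map to one
#'     chromosome, else NA}
#' }
#'
#' Tables must be sorted by the leftmost mapped coordinate of each pair
#' (pairs with no mapped end sort last).  \code{\link{readPairRecords}}
#' produces this layout from SAM/BAM; the simulator emits it directly.
#' @name pairsTable
NULL

.pairsSortKey <- function(pairs) {
  s <- pmin(ifelse(pairs$mapped1, pairs$start1, Inf),
            ifelse(pairs$mapped2, pairs$start2, Inf))
  s
}

#' Is a read pair improper?
#'
#' A pair is improper when its two ends map inconsistently with the insert
#' size distribution: mate unmapped, ends on different chromosomes,
#' orientation not forward/reverse inward, or outer insert length outside the
#' model's \code{[qLo, qHi]} window.
#'
#' @param pairs A \link{pairsTable} (or a subset of its rows).
#' @param model An \linkS4class{InsertSizeModel}.
#' @return Logical vector, one element per pair.
#' @export
isImproperPair <- function(pairs, model) {
  q <- insertQuantiles(model)
  bothMapped <- pairs$mapped1 & pairs$mapped2
  sameChrom <- bothMapped & pairs$chrom1 == pairs$chrom2
  ## forward-reverse inward: leftmost read on +, rightmost on -
  firstLeft <- pairs$start1 <= pairs$start2
  fr <- ifelse(firstLeft,
               pairs$strand1 == "+" & pairs$strand2 == "-",
               pairs$strand2 == "+" & pairs$strand1 == "-")
  okSize <- !is.na(pairs$isize) & pairs$isize >= q[1L] & pairs$isize <= q[2L]
  !(bothMapped & sameChrom & !is.na(fr) & fr & okSize)
}

#' Scan alignments for Alu mates
#'
#' Performs the single linear pass over a sorted pairs table: flags improper
#' pairs, classifies the candidate Alu ends of improper pairs against the
#' consensus library, and emits one Alu mate per improper pair that has
#' exactly one Alu end and a uniquely mapped (b = 1) anchor.  The anchor is
#' labelled \code{"l"} when it lies to the left of the implied element
#' (anchor on the + strand, mate expected downstream) and \code{"r"}
#' otherwise.
#'
#' @param pairs A \link{pairsTable}, sorted by coordinate.
#' @param library An \linkS4class{AluLibrary}.
#' @param model An \linkS4class{InsertSizeModel} for the same individual.
#' @param thresholds Classification thresholds
#'   (\code{\link{aluReadThresholds}}).
#' @return An \linkS4class{AluMateSet}.
#' @export
scanAluMates <- function(pairs, library, model,
                         thresholds = aluReadThresholds()) {
  key <- .pairsSortKey(pairs)
  fin <- which(is.finite(key))
  if (length(fin) > 1L) {
    bad <- which(diff(key[fin]) < 0)
    if (length(bad))
      stop("pairs table is not coordinate-sorted: record ",
           fin[bad[1L] + 1L], " starts before record ", fin[bad[1L]])
  }
  n <- nrow(pairs)
  improper <- if (n) isImproperPair(pairs, model) else logical(0)

  ## candidate Alu ends: unmapped or multi-mapping ends with a sequence
  cand1 <- improper & (!pairs$mapped1 | (!is.na(pairs$b1) & pairs$b1 > 1L)) &
    !is.na(pairs$seq1)
  cand2 <- improper & (!pairs$mapped2 | (!is.na(pairs$b2) & pairs$b2 > 1L)) &
    !is.na(pairs$seq2)

  cls1 <- classifyAluRead(pairs$seq1[cand1], library, thresholds)
  cls2 <- classifyAluRead(pairs$seq2[cand2], library, thresholds)
  isAlu1 <- logical(n); isAlu1[cand1] <- cls1$isAlu
  isAlu2 <- logical(n); isAlu2[cand2] <- cls2$isAlu
  nAluReads <- sum(isAlu1) + sum(isAlu2)

  ## exactly one Alu end, anchored by a uniquely mapped mate
  m1 <- isAlu2 & !isAlu1 & pairs$mapped1 & !is.na(pairs$b1) & pairs$b1 == 1L
  m2 <- isAlu1 & !isAlu2 & pairs$mapped2 & !is.na(pairs$b2) & pairs$b2 == 1L

  take <- function(anchorIdx, cls, candMask, mateMask) {
    idx <- which(mateMask)
    if (!length(idx))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), label = character(),
                        alu = character(), family = character(),
                        at = integer(), aluLen = integer(), b = integer(),
                        weight = numeric(), ind = character(),
                        pairId = integer()))
    rowInCls <- match(idx, which(candMask))
    if (anchorIdx == 1L) {
      chrom <- pairs$chrom1[idx]; st <- pairs$start1[idx]
      en <- pairs$end1[idx]; strand <- pairs$strand1[idx]
      b <- pairs$b1[idx]; aluLen <- nchar(pairs$seq2[idx])
    } else {
      chrom <- pairs$chrom2[idx]; st <- pairs$start2[idx]
      en <- pairs$end2[idx]; strand <- pairs$strand2[idx]
      b <- pairs$b2[idx]; aluLen <- nchar(pairs$seq1[idx])
    }
    data.frame(chrom = chrom, start = st, end = en,
               label = ifelse(strand == "+", "l", "r"),
               alu = cls$alu[rowInCls], family = cls$family[rowInCls],
               at = cls$at[rowInCls], aluLen = aluLen,
               b = b, weight = 1 / b,
               ind = as.character(pairs$ind[idx]),
               pairId = pairs$pairId[idx])
  }
  mates <- rbind(take(1L, cls2, cand2, m1), take(2L, cls1, cand1, m2))
  mates <- mates[order(mates$chrom, mates$start), , drop = FALSE]
  rownames(mates) <- NULL
  counts <- c(readsSeen = 2L * n, pairsProcessed = n,
              improperPairs = sum(improper), aluReads = nAluReads,
              aluMates = nrow(mates))
  new("AluMateSet", mates = mates, counts = as.integer(counts) |>
        setNames(names(counts)))
}

#' Write / read Alu mates as TSV
#'
#' @param x An \linkS4class{AluMateSet} (or its mates data.frame).
#' @param path Output file.
#' @return \code{writeAluMates} returns \code{path} invisibly;
#'   \code{readAluMates} returns a data.frame.
#' @export
writeAluMates <- function(x, path) {
  df <- if (is(x, "AluMateSet")) aluMates(x) else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAluMates
#' @export
readAluMates <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write Alu-mate anchor positions as BED
#'
#' @param x An \linkS4class{AluMateSet}.
#' @param path Output BED file.
#' @return \code{path}, invisibly.
#' @export
writeAluMateBed <- function(x, path) {
  df <- aluMates(x)
  bed <- data.frame(df$chrom, df$start, df$end,
                    paste0(df$label, ":", df$alu), df$b,
                    ifelse(df$label == "l", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
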