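#' Read paired-end alignments into a pairs table
#'
#' Reads a SAM or BAM file (standard FLAG semantics, mate fields populated)
#' and returns one row per pair in the \link{pairsTable} layout.  The
#' best-mapping count b is taken from an integer tag (default \code{XB});
#' records without the tag fall back to \code{b = 2} when MAPQ is 0 (a
#' multi-mapper by convention) and \code{b = 1} otherwise.
#'
#' @param path SAM or BAM file.
#' @param bTag Name of the integer tag carrying the best-hit count.
#' @param ind Individual id recorded in the table (default: file base name).
#' @return A coordinate-sorted \link{pairsTable}.
#' @export
readPairRecords <- function(path, bTag = "XB", ind = NULL) {
  if (is.null(ind))
    ind <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  isSam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (isSam) .checkSamSorted(path)
  bam <- if (isSam)
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = bTag)
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  if (n == 0L)
    return(data.frame(pairId = integer(), ind = character(),
                      chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), strand1 = character(),
                      mapped1 = logical(), b1 = integer(),
                      seq1 = character(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      strand2 = character(), mapped2 = logical(),
                      b2 = integer(), seq2 = character(),
                      isize = numeric()))
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  if (!any(bitwAnd(flag, 1L) > 0L))
    stop("alignments carry no mate information (FLAG 0x1 unset)")
  b <- x$tag[[bTag]]
  if (is.null(b)) b <- rep(NA_integer_, n)
  b <- ifelse(!is.na(b), b, ifelse(x$mapq == 0L, 2L, 1L))
  width <- .cigarRefWidth(x$cigar, as.character(x$seq))
  reads <- data.frame(
    qname = x$qname,
    chrom = as.character(x$rname),
    start = ifelse(mapped, x$pos - 1L, NA_real_),
    end = ifelse(mapped, x$pos - 1L + width, NA_real_),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapped = mapped, b = as.integer(b),
    seq = as.character(x$seq),
    first = bitwAnd(flag, 64L) > 0L)
  reads$seq[reads$seq == ""] <- NA_character_
  r1 <- reads[reads$first, , drop = FALSE]
  r2 <- reads[!reads$first, , drop = FALSE]
  m <- match(r1$qname, r2$qname)
  if (anyNA(m)) stop("unpaired records present: ",
                     r1$qname[which(is.na(m))[1L]])
  r2 <- r2[m, , drop = FALSE]
  both <- r1$mapped & r2$mapped & r1$chrom == r2$chrom
  isize <- ifelse(both, pmax(r1$end, r2$end) - pmin(r1$start, r2$start),
                  NA_real_)
  pairs <- data.frame(
    pairId = r1$qname, ind = ind,
    chrom1 = r1$chrom, start1 = r1$start, end1 = r1$end,
    strand1 = r1$strand, mapped1 = r1$mapped, b1 = r1$b, seq1 = r1$seq,
    chrom2 = r2$chrom, start2 = r2$start, end2 = r2$end,
    strand2 = r2$strand, mapped2 = r2$mapped, b2 = r2$b, seq2 = r2$seq,
    isize = isize)
  pairs <- pairs[order(.pairsSortKey(pairs)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

## Coordinate-order check on the raw SAM record stream (conversion to BAM
## re-sorts, so the check must precede it).
.checkSamSorted <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (length(body) < 2L) return(invisible(TRUE))
  f <- strsplit(lines[body], "\t")
  flag <- vapply(f, function(x) as.integer(x[2L]), integer(1))
  rname <- vapply(f, `[`, "", 3L)
  pos <- vapply(f, function(x) as.integer(x[4L]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  idx <- which(mapped)
  if (length(idx) > 1L) {
    ooo <- which(rname[idx][-1L] == rname[idx][-length(idx)] &
                   diff(pos[idx]) < 0L)
    if (length(ooo))
      stop("input not coordinate-sorted: record ", idx[ooo[1L] + 1L],
           " (line ", body[idx[ooo[1L] + 1L]], ") starts before record ",
           idx[ooo[1L]])
  }
  invisible(TRUE)
}

.cigarRefWidth <- function(cigar, seq) {
  w <- rep(NA_real_, length(cigar))
  simple <- grepl("^\\d+M$", cigar)
  w[simple] <- as.numeric(sub("M$", "", cigar[simple]))
  need <- is.na(w) & !is.na(cigar) & cigar != "*"
  if (any(need)) {
    ## sum of reference-consuming op lengths (M/D/N/=/X)
    w[need] <- vapply(cigar[need], function(cg) {
      toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
      lens <- as.numeric(sub("[A-Z=]$", "", toks))
      op <- sub("^\\d+", "", toks)
      sum(lens[op %in% c("M", "D", "N", "=", "X")])
    }, numeric(1), USE.NAMES = FALSE)
  }
  w[is.na(w)] <- nchar(seq[is.na(w)])
  w
}

#' Write a pairs table as SAM
#'
#' Emits one record per read with standard FLAG semantics; unmapped reads of
#' half-mapped pairs are placed at their mate's position per the SAM
#' specification.  The best-hit count is written to the \code{XB} integer
#' tag.  Sequences absent from the table are written as "*".
#'
#' @param pairs A \link{pairsTable}.
#' @param path Output SAM path.
#' @param chromLens Named numeric vector of reference lengths.
#' @return \code{path}, invisibly.
#' @export
writeSimulatedSam <- function(pairs, path, chromLens) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(chromLens))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, as.integer(chromLens[ch])),
               con)
  fmt <- function(first) {
    if (first) {
      chrom <- pairs$chrom1; st <- pairs$start1; strand <- pairs$strand1
      mapped <- pairs$mapped1; b <- pairs$b1; seq <- pairs$seq1
      mchrom <- pairs$chrom2; mst <- pairs$start2; mmapped <- pairs$mapped2
      mstrand <- pairs$strand2
      base <- 64L
    } else {
      chrom <- pairs$chrom2; st <- pairs$start2; strand <- pairs$strand2
      mapped <- pairs$mapped2; b <- pairs$b2; seq <- pairs$seq2
      mchrom <- pairs$chrom1; mst <- pairs$start1; mmapped <- pairs$mapped1
      mstrand <- pairs$strand1
      base <- 128L
    }
    flag <- 1L + base +
      ifelse(mapped, 0L, 4L) + ifelse(mmapped, 0L, 8L) +
      ifelse(strand == "-", 16L, 0L) + ifelse(mstrand == "-", 32L, 0L)
    outChrom <- ifelse(mapped, chrom, ifelse(mmapped, mchrom, "*"))
    outPos <- ifelse(mapped, st + 1L, ifelse(mmapped, mst + 1L, 0L))
    width <- if (first) pairs$end1 - pairs$start1 else
      pairs$end2 - pairs$start2
    cigar <- ifelse(mapped, paste0(as.integer(width), "M"), "*")
    tlen <- ifelse(!is.na(pairs$isize),
                   ifelse(strand == "+", pairs$isize, -pairs$isize), 0L)
    sprintf("sim%d\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*\tXB:i:%d",
            pairs$pairId, flag, outChrom, as.integer(outPos),
            ifelse(mapped, 60L, 0L), cigar,
            ifelse(mmapped | mapped, "=", "*"),
            as.integer(ifelse(mmapped, mst + 1L,
                              ifelse(mapped, st + 1L, 0L))),
            as.integer(tlen),
            ifelse(!is.na(seq), seq, "*"),
            as.integer(ifelse(is.na(b), 2L, b)))
  }
  ## records are coordinate-sorted (unmapped reads sit at their mate's
  ## position, unplaced reads last), as a sorted SAM would be
  pos1 <- ifelse(pairs$mapped1, pairs$start1,
                 ifelse(pairs$mapped2, pairs$start2, Inf))
  pos2 <- ifelse(pairs$mapped2, pairs$start2,
                 ifelse(pairs$mapped1, pairs$start1, Inf))
  lines <- c(fmt(TRUE), fmt(FALSE))[order(c(pos1, pos2))]
  writeLines(lines, con)
  invisible(path)
}

#' Read an Alu annotation track
#'
#' Accepts BED (0-based half-open, name column = subfamily) or RepeatMasker
#' .out (1-based closed, converted).  Output is sorted by position.
#'
#' @param path Annotation file; dialect guessed from the extension
#'   (\code{.out} = RepeatMasker) unless \code{format} is given.
#' @param format "bed" or "repeatmasker".
#' @return data.frame: \code{chrom}, \code{start}, \code{end}, \code{name},
#'   \code{family} (major-family grouping of the name).
#' @export
readAluAnnotations <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.out$", path)) "repeatmasker" else "bed"
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t| +")
    nf <- lengths(parts)
    if (length(nf) && any(nf < 3L))
      stop("malformed BED line ", which(nf < 3L)[1L])
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L))),
      end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L))),
      name = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, ""))
    if (anyNA(df$start) || anyNA(df$end))
      stop("malformed BED line ",
           which(is.na(df$start) | is.na(df$end))[1L])
  } else {
    lines <- readLines(path)
    ## RepeatMasker .out: two header lines + blank, then whitespace table
    body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 11L)
    if (length(bad)) stop("malformed RepeatMasker line ", bad[1L])
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 5L),
      start = as.numeric(vapply(parts, `[`, "", 6L)) - 1,
      end = as.numeric(vapply(parts, `[`, "", 7L)),
      name = vapply(parts, `[`, "", 10L))
  }
  df$family <- aluFamilyOf(df$name)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Tally calls by major Alu family
#'
#' Groups subfamily annotations into their AluY/AluS/AluJ families and
#' reports counts and percentages.
#'
#' @param families Character vector of subfamily (or family) names.
#' @return data.frame: \code{family}, \code{count}, \code{percent}.
#' @export
familyTally <- function(families) {
  fam <- aluFamilyOf(families)
  tab <- sort(table(fam), decreasing = TRUE)
  data.frame(family = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab))
}

#' Write genotype calls as VCF (and an optional per-individual summary)
#'
#' Writes VCF 4.2 with symbolic mobile-element ALT alleles
#' (\code{<DEL:ME:ALU>} or \code{<INS:ME:ALU>}), INFO END/SVLEN/MEINFO and
#' per-sample GT plus log10-scaled genotype likelihoods (GL).  Only flagged
#' loci are emitted for deletion call sets; insertion calls are emitted as
#' given.
#'
#' @param callset An \linkS4class{AluCallSet}.
#' @param path Output VCF path.
#' @param tsvPath Optional per-individual summary TSV (non-reference call
#'   counts and family tallies).
#' @param onlyFlagged Write only LRT-flagged loci (default TRUE for
#'   deletions).
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(callset, path, tsvPath = NULL, onlyFlagged = TRUE) {
  stopifnot(is(callset, "AluCallSet"))
  calls <- callset@calls
  geno <- callset@genotypes
  inds <- rownames(geno)
  del <- callset@type == "deletion"
  sel <- if (del && onlyFlagged && !is.null(calls$flagged))
    which(calls$flagged %in% TRUE) else seq_len(nrow(calls))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=AluPolyScan",
    sprintf("##ALT=<ID=%s,Description=\"%s of ALU element\">",
            if (del) "DEL:ME:ALU" else "INS:ME:ALU",
            if (del) "Deletion" else "Insertion"),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed element length\">",
    "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"Alu family\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t")), con)
  for (l in sel) {
    gts <- vapply(seq_along(inds), function(i) {
      copies <- geno[i, l]
      ## alt allele = the non-reference state (deleted / inserted element)
      nAlt <- if (del) 2L - copies else copies
      gt <- if (is.na(nAlt)) "./." else
        c("0/0", "0/1", "1/1")[nAlt + 1L]
      gl <- callset@likelihoods[[l]]
      glv <- if (del)
        c(gl$ll0[i], gl$ll1[i], gl$ll2[i]) / log(10)
      else
        c(gl$ll2[i], gl$ll1[i], gl$ll0[i]) / log(10)
      paste0(gt, ":", paste(sprintf("%.2f", glv), collapse = ","))
    }, character(1))
    info <- sprintf("END=%d;SVLEN=%d;FAMILY=%s",
                    as.integer(calls$end[l]),
                    as.integer(if (del) -calls$lAlu[l] else calls$lAlu[l]),
                    calls$family[l])
    writeLines(paste(c(calls$chrom[l], as.integer(calls$start[l] + 1L),
                       sprintf("ALU%04d", l), "N",
                       if (del) "<DEL:ME:ALU>" else "<INS:ME:ALU>",
                       ".", "PASS", info, "GT:GL", gts),
                     collapse = "\t"), con)
  }
  if (!is.null(tsvPath)) {
    nonRef <- vapply(seq_along(inds), function(i) {
      g <- geno[i, sel]
      sum(!is.na(g) & (if (del) g < 2L else g > 0L))
    }, integer(1))
    summ <- data.frame(ind = inds, calls = nonRef)
    write.table(summ, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
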