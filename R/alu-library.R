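#' Build an Alu consensus library
#'
#' @param sequences A named character vector or
#'   \link[Biostrings]{DNAStringSet} of consensus sequences.
#' @param family Character vector of family labels.  Defaults to the leading
#'   "Alu" + one letter of each name (e.g. \code{AluYa5} -> \code{AluY}).
#' @return An \linkS4class{AluLibrary}.
#' @export
aluLibrary <- function(sequences, family = NULL) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (length(sequences) == 0L) stop("empty Alu library")
  if (is.null(family))
    family <- aluFamilyOf(names(sequences))
  new("AluLibrary", sequences = sequences, family = family)
}

#' Derive the major Alu family from a subfamily name
#'
#' Groups subfamily names by their AluY/AluS/AluJ prefix; names not matching
#' an Alu prefix are returned unchanged.
#'
#' @param names Character vector of subfamily names (e.g. "AluYb8").
#' @return Character vector of family labels.
#' @export
aluFamilyOf <- function(names) {
  fam <- sub("^(Alu[A-Z]).*$", "\\1", names)
  ifelse(grepl("^Alu[A-Z]", names), fam, names)
}

#' Read an Alu consensus library from FASTA
#'
#' @param path Path to a FASTA file of consensus sequences.
#' @return An \linkS4class{AluLibrary}.
#' @export
readAluLibrary <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  aluLibrary(seqs)
}

#' Generate a synthetic consensus library
#'
#' Draws random ~300 bp consensus sequences, named after active human Alu
#' subfamilies, for use by the simulator.  Synthetic consensi stand in for
#' repository entries: the algorithms depend on the similarity structure
#' between reads and consensus copies, not on the Alu alphabet itself.  A real
#' consensus FASTA can be supplied anywhere an \linkS4class{AluLibrary} is
#' accepted.
#'
#' @param n Number of entries (default 5).
#' @param length Consensus length in bp (default 300).
#' @param names Entry names (defaults to AluYa5, AluYb8, AluYb9, AluYk13,
#'   AluJo, recycled/truncated to \code{n}).
#' @return An \linkS4class{AluLibrary}.  Uses the current RNG state.
#' @export
syntheticAluLibrary <- function(n = 5L, length = 300L,
                                names = c("AluYa5", "AluYb8", "AluYb9",
                                          "AluYk13", "AluJo")) {
  names <- rep_len(names, n)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
  aluLibrary(setNames(seqs, names))
}

#' Classification thresholds for Alu reads
#'
#' A read is an Alu read when its best local alignment against the library
#' reaches at least \code{identity} over at least \code{minCoverage} of the
#' read length.
#'
#' @param identity Minimum percent identity of the local alignment, as a
#'   fraction (default 0.9).
#' @param minCoverage Minimum fraction of the read covered by the alignment
#'   (default 0.8).
#' @return A named list.
#' @export
aluReadThresholds <- function(identity = 0.9, minCoverage = 0.8) {
  stopifnot(identity > 0, identity <= 1, minCoverage > 0, minCoverage <= 1)
  list(identity = identity, minCoverage = minCoverage)
}

#' Classify reads against the Alu consensus library
#'
#' Aligns each read (and its reverse complement) locally against every
#' library consensus and labels it an Alu read when the best alignment passes
#' the identity/coverage thresholds.  Ties between equally scoring entries are
#' broken toward the lowest library index.
#'
#' @param seqs Character vector (or DNAStringSet) of read sequences.
#' @param library An \linkS4class{AluLibrary}.
#' @param thresholds See \code{\link{aluReadThresholds}}.
#' @return A data.frame with one row per read: \code{isAlu}, \code{alu},
#'   \code{family}, \code{at} (0-based offset of the alignment start within
#'   the consensus; NA when not an Alu read) and \code{score}.
#' @export
classifyAluRead <- function(seqs, library,
                            thresholds = aluReadThresholds()) {
  if (!is(library, "AluLibrary")) stop("library must be an AluLibrary")
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  out <- data.frame(isAlu = logical(n), alu = rep(NA_character_, n),
                    family = rep(NA_character_, n),
                    at = rep(NA_integer_, n), score = rep(-Inf, n))
  if (n == 0L) return(out)
  pats <- Biostrings::DNAStringSet(seqs)
  patsRc <- Biostrings::reverseComplement(pats)
  readLen <- nchar(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = FALSE)
  bestScore <- rep(-Inf, n)
  bestIdx <- rep(NA_integer_, n)
  bestAt <- rep(NA_integer_, n)
  bestOk <- rep(FALSE, n)
  for (i in seq_along(library@sequences)) {
    subj <- library@sequences[[i]]
    for (ori in 1:2) {
      p <- if (ori == 1L) pats else patsRc
      aln <- Biostrings::pairwiseAlignment(
        p, subj, type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(aln)
      nm <- Biostrings::nmatch(aln)
      alnLen <- Biostrings::nchar(aln)
      span <- Biostrings::width(Biostrings::pattern(aln))
      ident <- ifelse(alnLen > 0, nm / alnLen, 0)
      ok <- ident >= thresholds$identity &
        span >= thresholds$minCoverage * readLen
      at0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
      better <- (ok & !bestOk) | (ok == bestOk & sc > bestScore)
      bestIdx[better] <- i
      bestAt[better] <- at0[better]
      bestScore[better] <- sc[better]
      bestOk <- bestOk | ok
    }
  }
  hit <- bestOk & !is.na(bestIdx)
  out$isAlu <- hit
  out$alu[hit] <- names(library@sequences)[bestIdx[hit]]
  out$family[hit] <- library@family[bestIdx[hit]]
  out$at[hit] <- bestAt[hit]
  out$score <- bestScore
  out
}
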