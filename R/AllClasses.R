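#' @import methods
#' @importFrom stats dnorm qnorm pchisq median mad quantile optimize rnorm runif rbinom approx setNames
#' @importFrom utils head tail write.table read.table
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

## Density floor shared by both model forms: keeps log-likelihood products over
## many read pairs finite.
.DENSITY_FLOOR <- 1e-300

#' Insert-size distribution of a paired-end library
#'
#' Models the outer distance (rightmost end minus leftmost start, bp) between
#' the two reads of a properly mapped pair.  The fitted form is either a
#' Gaussian parameterised by robust location/scale estimates, or a smoothed
#' empirical density.  The \code{epsilon} and \code{1 - epsilon} quantiles
#' (\code{qLo}, \code{qHi}) delimit the proper insert range used throughout
#' discovery and genotyping.
#'
#' @slot form "gaussian" or "empirical".
#' @slot mean,sd Location and scale of the insert distribution (bp).
#' @slot epsilon Tail mass used for the quantile window, in (0, 0.5).
#' @slot qLo,qHi The epsilon and 1 - epsilon insert-size quantiles (bp).
#' @slot n Number of training pairs.
#' @slot empX,empY Grid and density values of the smoothed empirical form
#'   (zero-length for the Gaussian form).
#' @exportClass InsertSizeModel
setClass("InsertSizeModel",
  representation(
    form = "character",
    mean = "numeric",
    sd = "numeric",
    epsilon = "numeric",
    qLo = "numeric",
    qHi = "numeric",
    n = "integer",
    empX = "numeric",
    empY = "numeric"
  )
)

setValidity("InsertSizeModel", function(object) {
  msg <- character()
  if (!object@form %in% c("gaussian", "empirical"))
    msg <- c(msg, "form must be 'gaussian' or 'empirical'")
  if (!(object@epsilon > 0 && object@epsilon < 0.5))
    msg <- c(msg, "epsilon must lie in (0, 0.5)")
  if (object@sd <= 0)
    msg <- c(msg, "sd must be > 0 (degenerate insert distribution)")
  if (!(object@qLo < object@mean && object@mean < object@qHi))
    msg <- c(msg, "quantiles must bracket the mean: qLo < mean < qHi")
  if (object@form == "empirical" && length(object@empX) < 2L)
    msg <- c(msg, "empirical form requires a density grid")
  if (length(msg)) msg else TRUE
})

#' Alu consensus library
#'
#' A set of named consensus sequences (one per Alu subfamily entry, each
#' roughly 300 bp) with a family label per entry.  Reads are classified as Alu
#' reads by local alignment against this library.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} with unique, non-empty
#'   names.
#' @slot family Character vector of family labels, parallel to
#'   \code{sequences}.
#' @exportClass AluLibrary
setClass("AluLibrary",
  representation(sequences = "DNAStringSet", family = "character")
)

setValidity("AluLibrary", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n == 0L) msg <- c(msg, "library must contain at least one consensus")
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "consensus names must be present and unique")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "consensus sequences must be non-empty")
  if (length(object@family) != n)
    msg <- c(msg, "family labels must parallel the sequences")
  if (length(msg)) msg else TRUE
})

#' Result of a single pass over paired-end alignments
#'
#' Holds the Alu mates (uniquely mapped anchors of improper pairs whose other
#' end is an Alu read), labelled \code{"l"} (anchor to the left of the implied
#' element) or \code{"r"} (anchor to the right), together with scan counters.
#'
#' @slot mates A data.frame with one row per Alu mate: \code{chrom},
#'   \code{start}, \code{end} (anchor read, 0-based half-open), \code{label}
#'   ("l"/"r"), \code{alu}, \code{family}, \code{at} (offset of the Alu read
#'   within the matched consensus, bp from its 5' end), \code{aluLen} (Alu
#'   read length), \code{b} (anchor best-mapping count), \code{weight}
#'   (= 1/b), \code{ind} (individual id).  Sorted by chrom, start.
#' @slot counts Named integer vector: \code{readsSeen}, \code{pairsProcessed},
#'   \code{improperPairs}, \code{aluReads}, \code{aluMates}.
#' @exportClass AluMateSet
setClass("AluMateSet",
  representation(mates = "data.frame", counts = "integer")
)

setValidity("AluMateSet", function(object) {
  need <- c("chrom", "start", "end", "label", "alu", "family", "at",
            "aluLen", "b", "weight", "ind")
  msg <- character()
  if (!all(need %in% names(object@mates)))
    msg <- c(msg, paste("mates must have columns:", paste(need, collapse = ", ")))
  cn <- c("readsSeen", "pairsProcessed", "improperPairs", "aluReads", "aluMates")
  if (!all(cn %in% names(object@counts)))
    msg <- c(msg, paste("counts must be named:", paste(cn, collapse = ", ")))
  else {
    if (object@counts[["readsSeen"]] != 2L * object@counts[["pairsProcessed"]])
      msg <- c(msg, "readsSeen must equal 2 * pairsProcessed")
    if (object@counts[["aluMates"]] != nrow(object@mates))
      msg <- c(msg, "aluMates count must equal nrow(mates)")
    if (object@counts[["aluMates"]] > object@counts[["improperPairs"]])
      msg <- c(msg, "cannot have more Alu mates than improper pairs")
  }
  if (nrow(object@mates) &&
      !all(object@mates$label %in% c("l", "r")))
    msg <- c(msg, "labels must be 'l' or 'r'")
  if (length(msg)) msg else TRUE
})

#' Solution of the insertion covering problem
#'
#' A set of element positions \code{positions} (candidate insertion points,
#' 0-based bp) and a set of error-labelled reads \code{errors} (row indices
#' into the instance) minimising \code{|E| + k |A|} for one individual, or the
#' heuristic solution of \code{|E| + k1 |A| + k2 sum_j |A_j|} for several.
#'
#' @slot positions Numeric vector of chosen element positions.
#' @slot errors Integer vector of error-read indices.
#' @slot support List (parallel to positions) of covered read indices.
#' @slot individuals List (parallel to positions) of individual ids assigned
#'   to each position (multi-individual solutions; empty lists otherwise).
#' @slot objective The achieved objective value.
#' @slot k Numeric: \code{k} for single-individual, \code{c(k1, k2)} for
#'   multi-individual instances.
#' @exportClass CoverSolution
setClass("CoverSolution",
  representation(
    positions = "numeric",
    errors = "integer",
    support = "list",
    individuals = "list",
    objective = "numeric",
    k = "numeric"
  )
)

setValidity("CoverSolution", function(object) {
  msg <- character()
  if (length(object@support) != length(object@positions))
    msg <- c(msg, "support list must parallel positions")
  if (object@objective < 0) msg <- c(msg, "objective must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A candidate Alu insertion under refinement
#'
#' The model of the inserted element is the matched consensus of length
#' \code{lAlu} extended by a signed left offset \code{lambda} and right offset
#' \code{rho}, inserted at \code{position}; total length
#' \code{lAlu + lambda + rho}.
#'
#' @slot chrom Chromosome name.
#' @slot position Estimated insertion point (0-based bp).
#' @slot alu,family Matched consensus name and family.
#' @slot lAlu Consensus length (bp).
#' @slot lambda,rho Signed length offsets (bp) and their standard errors
#'   \code{lambdaSE}, \code{rhoSE} (NA when a side has no support).
#' @slot supports data.frame of supporting Alu mates (columns as in
#'   \linkS4class{AluMateSet} plus \code{mt}, \code{st}).
#' @slot converged Logical; FALSE when the position iteration hit
#'   \code{maxIter}.
#' @slot iterations Number of refinement iterations performed.
#' @exportClass CandidateInsertion
setClass("CandidateInsertion",
  representation(
    chrom = "character",
    position = "numeric",
    alu = "character",
    family = "character",
    lAlu = "numeric",
    lambda = "numeric",
    rho = "numeric",
    lambdaSE = "numeric",
    rhoSE = "numeric",
    supports = "data.frame",
    converged = "logical",
    iterations = "integer"
  )
)

setValidity("CandidateInsertion", function(object) {
  lam <- ifelse(is.na(object@lambda), 0, object@lambda)
  rho <- ifelse(is.na(object@rho), 0, object@rho)
  if (object@lAlu + lam + rho <= 0)
    return("estimated total element length must be positive")
  TRUE
})

#' A simulated reference population with planted Alu elements
#'
#' Produced by \code{\link{simulateCohort}}: a synthetic (or supplied)
#' reference chromosome, a consensus library, the planted polymorphic sites
#' (one mutated consensus copy per site, a population frequency each) and the
#' per-haploid carrier matrix that constitutes the ground truth.
#'
#' @slot reference A \link[Biostrings]{DNAString} (the Alu-free reference).
#' @slot chrom Reference sequence name.
#' @slot library The \linkS4class{AluLibrary} used for planting.
#' @slot sites data.frame: \code{pos} (0-based insertion point), \code{alu},
#'   \code{family}, \code{freq}, \code{len} (planted copy length), \code{seq}
#'   (the mutated copy).  Sorted by \code{pos}.
#' @slot carriers Logical matrix, haploid chromosomes x sites.
#' @slot config The \code{\link{simulationConfig}} list used.
#' @exportClass AluSimulation
setClass("AluSimulation",
  representation(
    reference = "DNAString",
    chrom = "character",
    library = "AluLibrary",
    sites = "data.frame",
    carriers = "matrix",
    config = "list"
  )
)

setValidity("AluSimulation", function(object) {
  msg <- character()
  if (ncol(object@carriers) != nrow(object@sites))
    msg <- c(msg, "carrier matrix must have one column per site")
  if (is.unsorted(object@sites$pos))
    msg <- c(msg, "sites must be sorted by position")
  if (length(msg)) msg else TRUE
})

#' Genotype calls for a set of loci across individuals
#'
#' @slot calls data.frame with one row per locus: \code{locus}, \code{chrom},
#'   \code{start}, \code{end}, \code{family}, \code{lAlu}, \code{p} (non-
#'   reference allele-frequency MLE), \code{stat}, \code{pvalue}, \code{padj},
#'   \code{flagged}.
#' @slot genotypes Integer matrix (individuals x loci) of Alu copy numbers
#'   (0, 1 or 2 copies of the element; NA = no call).
#' @slot likelihoods List (per locus) of data.frames with per-individual
#'   log-likelihoods \code{ll0}, \code{ll1}, \code{ll2}, called \code{g} and
#'   informative pair count \code{n}.
#' @slot type "deletion" or "insertion".
#' @exportClass AluCallSet
setClass("AluCallSet",
  representation(
    calls = "data.frame",
    genotypes = "matrix",
    likelihoods = "list",
    type = "character"
  )
)

setValidity("AluCallSet", function(object) {
  msg <- character()
  if (!object@type %in% c("deletion", "insertion"))
    msg <- c(msg, "type must be 'deletion' or 'insertion'")
  if (nrow(object@calls) != ncol(object@genotypes) && ncol(object@genotypes) > 0)
    msg <- c(msg, "genotype matrix must have one column per locus")
  if (length(msg)) msg else TRUE
})
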