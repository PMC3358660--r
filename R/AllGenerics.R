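#' @name accessors
#' @title Accessors for AluPolyScan classes
#' @description Small read-only accessors for the package's S4 containers.
#' @param x An object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("insertMean", function(x) standardGeneric("insertMean"))
#' @rdname accessors
#' @export
setGeneric("insertSd", function(x) standardGeneric("insertSd"))
#' @rdname accessors
#' @export
setGeneric("insertQuantiles", function(x) standardGeneric("insertQuantiles"))
#' @rdname accessors
#' @export
setGeneric("modelForm", function(x) standardGeneric("modelForm"))

#' Evaluate the insert-size density
#'
#' \code{insertDensity} evaluates the fitted insert-size density Y at outer
#' distances \code{t}; \code{shiftedDensity} evaluates the shifted density
#' Z = Y + lAlu, the distribution of inserts spanning a deleted element of
#' length \code{lAlu}, i.e. \code{insertDensity(model, t - lAlu)}.  Both are
#' floored at 1e-300 so that log-likelihood products stay finite.
#'
#' @param model An \linkS4class{InsertSizeModel}.
#' @param t Numeric vector of insert lengths (bp).
#' @param lAlu Element length (bp), must be > 0.
#' @return Numeric vector of (strictly positive) densities.
#' @examples
#' m <- gaussianInsertModel(400, 50)
#' insertDensity(m, 400)            # 1 / (50 sqrt(2 pi))
#' shiftedDensity(m, 700, 300)      # equals insertDensity(m, 400)
#' @export
setGeneric("insertDensity", function(model, t) standardGeneric("insertDensity"))

#' @rdname insertDensity
#' @export
setGeneric("shiftedDensity", function(model, t, lAlu)
  standardGeneric("shiftedDensity"))

#' @rdname accessors
#' @export
setGeneric("aluFamilies", function(x) standardGeneric("aluFamilies"))
#' @rdname accessors
#' @export
setGeneric("aluMates", function(x) standardGeneric("aluMates"))
#' @rdname accessors
#' @export
setGeneric("mateCounts", function(x) standardGeneric("mateCounts"))
#' @rdname accessors
#' @export
setGeneric("coverPositions", function(x) standardGeneric("coverPositions"))
#' @rdname accessors
#' @export
setGeneric("coverErrors", function(x) standardGeneric("coverErrors"))
#' @rdname accessors
#' @export
setGeneric("coverObjective", function(x) standardGeneric("coverObjective"))
#' @rdname accessors
#' @export
setGeneric("coverAssignments", function(x) standardGeneric("coverAssignments"))
#' @rdname accessors
#' @export
setGeneric("simReference", function(x) standardGeneric("simReference"))
#' @rdname accessors
#' @export
setGeneric("simSites", function(x) standardGeneric("simSites"))
#' @rdname accessors
#' @export
setGeneric("simCarriers", function(x) standardGeneric("simCarriers"))
#' @rdname accessors
#' @export
setGeneric("simLibrary", function(x) standardGeneric("simLibrary"))
#' @rdname accessors
#' @export
setGeneric("callsTable", function(x) standardGeneric("callsTable"))
#' @rdname accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

setMethod("insertMean", "InsertSizeModel", function(x) x@mean)
setMethod("insertSd", "InsertSizeModel", function(x) x@sd)
setMethod("insertQuantiles", "InsertSizeModel",
          function(x) c(qLo = x@qLo, qHi = x@qHi))
setMethod("modelForm", "InsertSizeModel", function(x) x@form)

setMethod("aluFamilies", "AluLibrary", function(x)
  setNames(x@family, names(x@sequences)))

setMethod("aluMates", "AluMateSet", function(x) x@mates)
setMethod("mateCounts", "AluMateSet", function(x) x@counts)

setMethod("coverPositions", "CoverSolution", function(x) x@positions)
setMethod("coverErrors", "CoverSolution", function(x) x@errors)
setMethod("coverObjective", "CoverSolution", function(x) x@objective)
setMethod("coverAssignments", "CoverSolution", function(x) x@individuals)

setMethod("simReference", "AluSimulation", function(x) x@reference)
setMethod("simSites", "AluSimulation", function(x) x@sites)
setMethod("simCarriers", "AluSimulation", function(x) x@carriers)
setMethod("simLibrary", "AluSimulation", function(x) x@library)

setMethod("callsTable", "AluCallSet", function(x) x@calls)
setMethod("genotypeMatrix", "AluCallSet", function(x) x@genotypes)

setMethod("show", "InsertSizeModel", function(object) {
  cat(sprintf(
    "InsertSizeModel (%s): mean %.1f bp, sd %.1f bp, eps %.3g, [%.0f, %.0f], n=%d\n",
    object@form, object@mean, object@sd, object@epsilon,
    object@qLo, object@qHi, object@n))
})

setMethod("show", "AluLibrary", function(object) {
  cat(sprintf("AluLibrary with %d consensus entries (%s)\n",
              length(object@sequences),
              paste(unique(object@family), collapse = ", ")))
})

setMethod("show", "AluMateSet", function(object) {
  cat("AluMateSet:", object@counts[["aluMates"]], "Alu mates from",
      object@counts[["pairsProcessed"]], "pairs (",
      object@counts[["improperPairs"]], "improper )\n")
})

setMethod("show", "CoverSolution", function(object) {
  cat(sprintf("CoverSolution: |A| = %d, |E| = %d, objective = %g\n",
              length(object@positions), length(object@errors),
              object@objective))
})

setMethod("show", "CandidateInsertion", function(object) {
  cat(sprintf(
    "CandidateInsertion %s:%d  %s (%s)  lAlu=%d lambda=%.1f rho=%.1f  %s (%d it)\n",
    object@chrom, round(object@position), object@alu, object@family,
    round(object@lAlu), object@lambda, object@rho,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
})

setMethod("show", "AluSimulation", function(object) {
  cat(sprintf(
    "AluSimulation: %d bp reference '%s', %d planted sites, %d haploid chromosomes\n",
    length(object@reference), object@chrom, nrow(object@sites),
    nrow(object@carriers)))
})

setMethod("show", "AluCallSet", function(object) {
  cat(sprintf("AluCallSet (%s): %d loci x %d individuals, %d flagged\n",
              object@type, nrow(object@calls), nrow(object@genotypes),
              sum(object@calls$flagged, na.rm = TRUE)))
})
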