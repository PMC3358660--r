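#' Estimate the insert-size distribution from proper pairs
#'
#' Fits the paired-end insert-size distribution Y from the outer distances of
#' properly mapped, uniquely mapping pairs.  Location and scale are estimated
#' robustly (median and 1.4826 x MAD) so that a minority of pairs spanning
#' true structural events does not bias the model; the window quantiles
#' \code{qLo}/\code{qHi} are the empirical \code{epsilon} and
#' \code{1 - epsilon} quantiles.
#'
#' @param inserts Numeric vector of outer insert lengths (bp), or a pairs
#'   table (see \code{\link{pairsTable}}) from which inserts of pairs with
#'   both ends uniquely mapped (b = 1) on one chromosome are taken.
#' @param epsilon Tail mass for the quantile window (default 0.005).
#' @param form "gaussian" (default) or "empirical".
#' @param minPairs Minimum number of training pairs (default 100).
#' @return An \linkS4class{InsertSizeModel}.
#' @examples
#' set.seed(1)
#' m <- estimateInsertModel(rnorm(10000, 400, 50))
#' insertQuantiles(m)   # approximately the 0.005/0.995 quantiles of N(400,50)
#' @export
estimateInsertModel <- function(inserts, epsilon = 0.005,
                                form = c("gaussian", "empirical"),
                                minPairs = 100L) {
  form <- match.arg(form)
  if (is.data.frame(inserts)) {
    p <- inserts
    keep <- p$mapped1 & p$mapped2 & p$chrom1 == p$chrom2 &
      p$b1 == 1L & p$b2 == 1L & !is.na(p$isize)
    inserts <- p$isize[keep]
  }
  inserts <- as.numeric(inserts[!is.na(inserts)])
  if (length(inserts) < minPairs)
    stop("insert-size estimation needs at least ", minPairs,
         " uniquely mapped proper pairs; got ", length(inserts))
  if (!(epsilon > 0 && epsilon < 0.5))
    stop("epsilon must lie in (0, 0.5)")
  m <- median(inserts)
  s <- mad(inserts)  # 1.4826 * MAD
  if (s <= 0)
    stop("degenerate insert distribution: scale estimate is zero")
  q <- unname(quantile(inserts, c(epsilon, 1 - epsilon), type = 7))
  empX <- numeric()
  empY <- numeric()
  if (form == "empirical") {
    d <- stats::density(inserts, n = 1024L)
    empX <- d$x
    empY <- pmax(d$y, .DENSITY_FLOOR)
  }
  new("InsertSizeModel", form = form, mean = m, sd = s, epsilon = epsilon,
      qLo = q[1L], qHi = q[2L], n = length(inserts),
      empX = empX, empY = empY)
}

#' Construct a Gaussian insert-size model directly
#'
#' Convenience constructor used when the library parameters are known (for
#' example by the read simulator): quantiles are taken from the normal
#' distribution at \code{epsilon} and \code{1 - epsilon}.
#'
#' @param mean,sd Insert mean and standard deviation (bp).
#' @param epsilon Tail mass (default 0.005).
#' @param n Nominal training size recorded in the object.
#' @return An \linkS4class{InsertSizeModel}.
#' @export
gaussianInsertModel <- function(mean, sd, epsilon = 0.005, n = 0L) {
  if (sd <= 0) stop("sd must be > 0")
  new("InsertSizeModel", form = "gaussian", mean = mean, sd = sd,
      epsilon = epsilon,
      qLo = qnorm(epsilon, mean, sd), qHi = qnorm(1 - epsilon, mean, sd),
      n = as.integer(n), empX = numeric(), empY = numeric())
}

setMethod("insertDensity", "InsertSizeModel", function(model, t) {
  if (model@form == "gaussian") {
    d <- dnorm(t, model@mean, model@sd)
  } else {
    d <- approx(model@empX, model@empY, xout = t, yleft = 0, yright = 0)$y
  }
  pmax(d, .DENSITY_FLOOR)
})

setMethod("shiftedDensity", "InsertSizeModel", function(model, t, lAlu) {
  if (any(lAlu <= 0)) stop("lAlu must be > 0")
  insertDensity(model, t - lAlu)
})

#' Serialize an insert-size model to and from JSON
#'
#' The model is written as a small key-value JSON object so that pipeline
#' stages (and the command-line driver) can share one estimate per individual.
#'
#' @param model An \linkS4class{InsertSizeModel}.
#' @param path File path.
#' @return \code{readInsertModel} returns the reconstructed model;
#'   \code{writeInsertModel} returns \code{path} invisibly.
#' @export
writeInsertModel <- function(model, path) {
  x <- list(form = model@form, mean = model@mean, sd = model@sd,
            epsilon = model@epsilon, qLo = model@qLo, qHi = model@qHi,
            n = model@n)
  if (model@form == "empirical") {
    x$empX <- model@empX
    x$empY <- model@empY
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeInsertModel
#' @export
readInsertModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("InsertSizeModel", form = x$form, mean = x$mean, sd = x$sd,
      epsilon = x$epsilon, qLo = x$qLo, qHi = x$qHi, n = as.integer(x$n),
      empX = as.numeric(x$empX %||% numeric()),
      empY = as.numeric(x$empY %||% numeric()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Quantiles of the mate-gap (inner spacing) distribution: the outer insert
## minus both read lengths.  The covering geometry of insertion discovery is
## defined on the gap between the anchor and its Alu mate, so the pipeline
## feeds these into coverInterval()/sweepCandidateRegions().
gapQuantiles <- function(model, readLen) {
  q <- insertQuantiles(model) - 2 * readLen
  c(qLo = unname(q[1L]), qHi = unname(q[2L]))
}
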