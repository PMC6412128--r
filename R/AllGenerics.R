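#' @include AllClasses.R
NULL

#' @export
setGeneric("originPositions", function(x) standardGeneric("originPositions"))
#' @export
setGeneric("originNames", function(x) standardGeneric("originNames"))
#' @export
setGeneric("interOriginDistances", function(x) standardGeneric("interOriginDistances"))
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @export
setGeneric("boxStarts", function(x) standardGeneric("boxStarts"))
#' @export
setGeneric("boxMids", function(x) standardGeneric("boxMids"))
#' @export
setGeneric("forwardCounts", function(x) standardGeneric("forwardCounts"))
#' @export
setGeneric("reverseCounts", function(x) standardGeneric("reverseCounts"))
#' @export
setGeneric("posteriorSamples", function(x, ...) standardGeneric("posteriorSamples"))
#' @export
setGeneric("derivedFractions", function(x, ...) standardGeneric("derivedFractions"))
#' @export
setGeneric("convergence", function(x) standardGeneric("convergence"))
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' Accessors
#'
#' Small accessor methods for the package's S4 classes.
#'
#' @param x an object of the documented class.
#' @param ... passed on (for \code{posteriorSamples}: \code{pooled}).
#' @name accessors
#' @aliases originPositions originNames interOriginDistances profileValues
#'   boxStarts boxMids forwardCounts reverseCounts posteriorSamples
#'   derivedFractions convergence nChains
NULL

#' @rdname accessors
#' @export
setMethod("originPositions", "OriginTriplet", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("originNames", "OriginTriplet", function(x) x@originNames)

#' @rdname accessors
#' @export
setMethod("interOriginDistances", "OriginTriplet", function(x) {
  d <- diff(x@positions)
  names(d) <- c("N1", "N2")
  d
})

#' @rdname accessors
#' @export
setMethod("profileValues", "AveragedProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("boxStarts", "AveragedProfile", function(x) x@boxStart)
#' @rdname accessors
#' @export
setMethod("boxMids", "AveragedProfile", function(x) x@boxStart + x@sBox / 2)
#' @rdname accessors
#' @export
setMethod("boxStarts", "BoxedCounts", function(x) x@boxStart)
#' @rdname accessors
#' @export
setMethod("boxMids", "BoxedCounts", function(x) x@boxStart + x@sBox / 2)
#' @rdname accessors
#' @export
setMethod("forwardCounts", "BoxedCounts", function(x) x@forward)
#' @rdname accessors
#' @export
setMethod("reverseCounts", "BoxedCounts", function(x) x@reverse)

#' @rdname accessors
#' @param pooled logical, pool chains into one matrix (default) or return the
#'   per-chain list.
#' @export
setMethod("posteriorSamples", "ChainSet", function(x, pooled = TRUE) {
  if (pooled) do.call(rbind, x@samples) else x@samples
})
#' @rdname accessors
#' @export
setMethod("derivedFractions", "ChainSet", function(x, pooled = TRUE) {
  if (pooled) do.call(rbind, x@derived) else x@derived
})
#' @rdname accessors
#' @export
setMethod("convergence", "ChainSet", function(x) x@convergence)
#' @rdname accessors
#' @export
setMethod("nChains", "ChainSet", function(x) length(x@samples))

setMethod("show", "OriginTriplet", function(object) {
  cat("OriginTriplet on", object@chrom, "\n")
  cat(sprintf("  %s at %s bp\n", object@originNames,
              format(object@positions, big.mark = ",")), sep = "")
  d <- interOriginDistances(object)
  cat(sprintf("  N1 = %d bp, N2 = %d bp\n", as.integer(d[1]), as.integer(d[2])))
})

setMethod("show", "FiringParams", function(object) {
  cat("FiringParams (times in rbp)\n")
  print(data.frame(mu = object@mu, sigma = object@sigma, q = object@q,
                   row.names = c("O1", "O2", "O3")))
})

setMethod("show", "AveragedProfile", function(object) {
  cat(sprintf("AveragedProfile: %d boxes of %g bp, M = %d cells\n",
              length(object@values), object@sBox, object@M))
  cat(sprintf("  F_ave range [%.3f, %.3f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BoxedCounts", function(object) {
  cat(sprintf("BoxedCounts: %d boxes of %g bp\n",
              length(object@forward), object@sBox))
  cat(sprintf("  mean(forward + reverse) = %.4f, b_chr = %s, n = %s\n",
              mean(object@forward + object@reverse),
              format(object@bChr), format(object@nNorm)))
})

setMethod("show", "ChainSet", function(object) {
  ns <- nrow(object@samples[[1]])
  cat(sprintf("ChainSet: %d chains x %d retained samples (M = %d cells)\n",
              length(object@samples), ns, object@config@M))
  if (nrow(object@convergence)) {
    rh <- object@convergence$Rhat
    cat(sprintf("  Gelman-Rubin R-hat: max %.3f (%s)\n",
                max(rh, na.rm = TRUE),
                if (all(is.na(rh) | rh < 1.1)) "converged at 1.1 threshold"
                else "NOT converged at 1.1 threshold"))
  }
})

setMethod("show", "ReplicationTimeProfile", function(object) {
  cat(sprintf("ReplicationTimeProfile: %d boxes, nu = %g kb/min, anchor = %g min\n",
              length(object@position), object@nu, object@anchor))
  cat(sprintf("  median time range [%.2f, %.2f] min\n",
              min(object@median), max(object@median)))
})
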