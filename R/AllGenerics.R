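#' @include AllClasses.R
NULL

#' @describeIn GINARModel-class geometric marginal parameter \code{p}.
#' @param object,x an object of the documented class.
#' @export
setGeneric("geomParam", function(object) standardGeneric("geomParam"))

#' @describeIn GINARModel-class thinning / lag-1 autocorrelation parameter
#'   \code{rho}.
#' @export
setGeneric("thinParam", function(object) standardGeneric("thinParam"))

#' @describeIn GINARModel-class stationary marginal mean \eqn{(1-p)/p},
#'   strictly decreasing in \code{p}.
#' @export
setGeneric("marginalMean", function(object) standardGeneric("marginalMean"))

#' @describeIn GINARModel-class stationary marginal variance
#'   \eqn{(1-p)/p^2}.
#' @export
setGeneric("marginalVar", function(object) standardGeneric("marginalVar"))

#' @describeIn GINARModel-class \code{TRUE} iff \eqn{\rho/(\rho+1) < p}, the
#'   admissibility condition under which the Kalmykov comparison of two
#'   chains (and the run-length orderings in \code{p}) are established.
#' @export
setGeneric("kalmykovDomain",
           function(object) standardGeneric("kalmykovDomain"))

#' Matrix of transition probabilities
#'
#' Accessor for the numeric entries of a [TransitionMatrix-class] (states
#' \eqn{0..n} in rows and columns, exact probabilities, not renormalised).
#'
#' @param object a \code{TransitionMatrix}.
#' @return a numeric matrix.
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))

#' Per-row truncated tail mass
#'
#' Accessor for the per-row probability mass lost to truncation,
#' \eqn{1 - \sum_{j \le n} p_{ij}}; converges to 0 as the truncation order
#' grows.
#'
#' @param object a [TransitionMatrix-class].
#' @return a numeric vector, one element per row.
#' @export
setGeneric("tailMass", function(object) standardGeneric("tailMass"))

#' Underlying GINAR(1) model of an object
#'
#' @param object a [TransitionMatrix-class], [CountSeries-class] or
#'   [RunLengthDistribution-class].
#' @return a [GINARModel-class] (or \code{NULL} for external series).
#' @export
setGeneric("ginarModel", function(object) standardGeneric("ginarModel"))

#' Run-length pmf, survival and hazard accessors
#'
#' \code{rlPmf} returns \eqn{P(RL = m)} for \eqn{m = 1..M}; \code{rlSurvival}
#' returns \eqn{P(RL > m)} for \eqn{m = 0..M}; \code{rlHazard} returns
#' \eqn{\lambda(m) = P(RL = m) / P(RL \ge m)} for \eqn{m = 1..M}, where
#' \eqn{P(RL \ge m)} is the survival at \eqn{m - 1}.
#'
#' @param object a [RunLengthDistribution-class].
#' @return a numeric vector.
#' @export
setGeneric("rlPmf", function(object) standardGeneric("rlPmf"))

#' @rdname rlPmf
#' @export
setGeneric("rlSurvival", function(object) standardGeneric("rlSurvival"))

#' @rdname rlPmf
#' @export
setGeneric("rlHazard", function(object) standardGeneric("rlHazard"))

#' @rdname rlPmf
#' @export
setGeneric("perronXi", function(object) standardGeneric("perronXi"))

#' Values of a count series
#'
#' @param object a [CountSeries-class].
#' @return an integer vector of counts.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
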