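setClassUnion("integerOrNULL", c("integer", "NULL"))

#' GINAR(1) model parameters
#'
#' An S4 container for the two parameters of the stationary GINAR(1) count
#' process: the geometric marginal parameter \code{p} and the binomial
#' thinning parameter \code{rho}. The process is
#' \deqn{X_t = \rho \circ X_{t-1} + B_t G_t,}
#' where \eqn{\rho \circ} denotes binomial thinning, \eqn{B_t} is
#' Bernoulli\eqn{(1-\rho)} and \eqn{G_t} is geometric\eqn{(p)} on
#' \eqn{\{0,1,2,\dots\}} with \eqn{P(G = j) = (1-p)^j p}. With a
#' geometric\eqn{(p)} start the chain is stationary with geometric\eqn{(p)}
#' marginal, mean \eqn{(1-p)/p} and lag-\eqn{k} autocorrelation \eqn{\rho^k}.
#'
#' @slot p geometric marginal parameter, a single value in (0, 1).
#' @slot rho thinning (autocorrelation) parameter in \eqn{[0, 1)};
#'   \code{rho = 0} is admitted as the iid geometric limit, \code{rho = 1}
#'   is rejected (non-ergodic chain).
#'
#' @seealso [GINARModel()] for the user constructor.
#' @exportClass GINARModel
setClass("GINARModel", representation(p = "numeric", rho = "numeric"))

setValidity("GINARModel", function(object) {
  msg <- character()
  if (length(object@p) != 1L || !is.finite(object@p) ||
      object@p <= 0 || object@p >= 1)
    msg <- c(msg, "'p' must be a single value in (0, 1)")
  if (length(object@rho) != 1L || !is.finite(object@rho) ||
      object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "'rho' must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Truncated transition probability matrix of a GINAR(1) chain
#'
#' Row-stochastic (up to truncation) matrix of exact one-step transition
#' probabilities \eqn{p_{ij}(p, \rho) = P(X_t = j \mid X_{t-1} = i)} on the
#' truncated state space \eqn{\{0, \dots, n\}}. Entries are the exact
#' infinite-chain values and are never renormalised; the per-row deficit
#' \eqn{1 - \sum_{j \le n} p_{ij}} is kept in \code{tailMass} so that
#' truncation error stays auditable.
#'
#' @slot model the [GINARModel-class] the matrix was built from.
#' @slot entries numeric \eqn{(n+1) \times (n+1)} matrix; rows and columns
#'   are states \eqn{0..n} (dimnames \code{state_0..state_n}).
#' @slot tailMass numeric vector of per-row truncated tail probabilities.
#'
#' @seealso [transitionMatrix()]
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
         representation(model = "GINARModel", entries = "matrix",
                        tailMass = "numeric"))

setValidity("TransitionMatrix", function(object) {
  e <- object@entries
  msg <- character()
  if (!is.numeric(e) || nrow(e) != ncol(e))
    msg <- c(msg, "'entries' must be a square numeric matrix")
  if (any(e < -1e-15) || any(e > 1 + 1e-12))
    msg <- c(msg, "entries must lie in [0, 1]")
  if (length(object@tailMass) != nrow(e))
    msg <- c(msg, "'tailMass' must have one element per row")
  if (any(object@tailMass < -1e-10))
    msg <- c(msg, "row sums must not exceed 1")
  if (length(msg)) msg else TRUE
})

#' An observed or simulated count series
#'
#' A plain non-negative integer time series, optionally carrying the
#' generating [GINARModel-class] and the simulation seed (both absent for
#' externally supplied data).
#'
#' @slot values integer vector of non-negative counts.
#' @slot model a [GINARModel-class], or \code{NULL} for external data.
#' @slot seed the integer seed used for simulation, or \code{NULL}.
#'
#' @exportClass CountSeries
setClass("CountSeries",
         representation(values = "integer", model = "ANY",
                        seed = "integerOrNULL"))

setValidity("CountSeries", function(object) {
  msg <- character()
  if (length(object@values) < 1L) msg <- c(msg, "series must be non-empty")
  if (anyNA(object@values) || any(object@values < 0L))
    msg <- c(msg, "counts must be non-negative integers")
  if (!is.null(object@model) && !is(object@model, "GINARModel"))
    msg <- c(msg, "'model' must be a GINARModel or NULL")
  if (length(msg)) msg else TRUE
})

#' Specification of an upper one-sided geometric chart
#'
#' The chart observes the counts \eqn{X_1, X_2, \dots} and signals at the
#' first time \eqn{t} with \eqn{X_t > U}. The run length depends on the
#' initial state: either a fixed value \eqn{u \in \{0, \dots, U\}} of
#' \eqn{X_0} (with \eqn{u = U} acting as a head start) or the token
#' \code{"overall"}, meaning the initial state is the random first
#' observation \eqn{X_1 \sim} geometric\eqn{(p)}, in which case a signal at
#' \eqn{t = 1} is possible.
#'
#' @slot U upper control limit, a non-negative integer.
#' @slot u fixed initial state in \eqn{0..U}, or \code{NA_integer_} for the
#'   \code{"overall"} (random geometric start) policy.
#'
#' @seealso [chartSpec()]
#' @exportClass ChartSpec
setClass("ChartSpec", representation(U = "integer", u = "integer"))

setValidity("ChartSpec", function(object) {
  msg <- character()
  if (length(object@U) != 1L || is.na(object@U) || object@U < 0L)
    msg <- c(msg, "'U' must be a single non-negative integer")
  if (length(object@u) != 1L)
    msg <- c(msg, "'u' must be a single integer or NA (overall)")
  else if (!is.na(object@u) && (object@u < 0L || object@u > object@U))
    msg <- c(msg, "fixed initial state 'u' must lie in 0..U")
  if (length(msg)) msg else TRUE
})

#' Exact run-length distribution of a geometric chart
#'
#' Phase-type representation of the run length: the substochastic block
#' \eqn{Q = [p_{ij}]_{i,j \le U}} of the transition matrix, the pmf
#' \eqn{P(RL = m)}, survival \eqn{P(RL > m)} and hazard
#' \eqn{\lambda(m) = P(RL = m)/P(RL \ge m)} arrays up to a horizon \eqn{M}
#' at which the survival has fallen below a cutoff, and the Perron root
#' \eqn{\xi} of \eqn{Q}, which governs the geometric-like tail: the hazard
#' converges to \eqn{1 - \xi} from either monotone direction.
#'
#' @slot chart the [ChartSpec-class] analysed.
#' @slot model the [GINARModel-class].
#' @slot Q numeric \eqn{(U+1)\times(U+1)} substochastic matrix (exact, no
#'   truncation: it is a finite block of the infinite transition matrix).
#' @slot pmf numeric, \eqn{P(RL = m)} for \eqn{m = 1..M}.
#' @slot survival numeric, \eqn{P(RL > m)} for \eqn{m = 0..M}
#'   (\code{survival[1]} is \eqn{P(RL > 0) = 1}).
#' @slot hazard numeric, \eqn{\lambda(m)} for \eqn{m = 1..M}.
#' @slot xi the Perron root of \code{Q}.
#'
#' @seealso [rlDistribution()], [rlSummary()]
#' @exportClass RunLengthDistribution
setClass("RunLengthDistribution",
         representation(chart = "ChartSpec", model = "GINARModel",
                        Q = "matrix", pmf = "numeric", survival = "numeric",
                        hazard = "numeric", xi = "numeric"))

setValidity("RunLengthDistribution", function(object) {
  msg <- character()
  if (length(object@survival) != length(object@pmf) + 1L)
    msg <- c(msg, "'survival' must be one longer than 'pmf' (m = 0..M)")
  if (abs(object@survival[1L] - 1) > 1e-12)
    msg <- c(msg, "survival at m = 0 must be 1")
  if (any(diff(object@survival) > 1e-15))
    msg <- c(msg, "survival must be nonincreasing")
  if (any(object@pmf < -1e-15)) msg <- c(msg, "pmf must be non-negative")
  if (length(object@xi) != 1L || object@xi <= 0 || object@xi >= 1)
    msg <- c(msg, "Perron root 'xi' must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Summary performance measures of a run-length distribution
#'
#' @slot arl average run length \eqn{E[RL]} (exact, linear-solve path).
#' @slot sdrl run-length standard deviation.
#' @slot quantiles named numeric vector of run-length percentiles (smallest
#'   \eqn{m} with \eqn{P(RL \le m) \ge q}).
#' @slot limitingHazard \eqn{1 - \xi}, the common limit of the hazard rate.
#'
#' @seealso [rlSummary()]
#' @exportClass RunLengthSummary
setClass("RunLengthSummary",
         representation(arl = "numeric", sdrl = "numeric",
                        quantiles = "numeric", limitingHazard = "numeric"))

#' Verdict of a stochastic-ordering / positivity check
#'
#' Every verifier ([isTP2()], [isPF2()], [lrLE()], [stLE()], [kalmykovLE()])
#' returns an \code{OrderReport}: a boolean verdict, the minimal signed
#' quantity whose non-negativity defines the property (smallest 2x2 minor,
#' smallest tail-sum gap, ...), the numerical tolerance used, and, when the
#' property fails, the indices of the first violating witness so the failure
#' can be recomputed independently.
#'
#' @slot check name of the property checked.
#' @slot holds logical; \code{TRUE} iff \code{margin >= -tolerance}.
#' @slot margin the minimal defining quantity over the whole scan.
#' @slot witness integer indices (R, 1-based) of the minimising
#'   configuration when \code{holds} is \code{FALSE}; \code{integer(0)}
#'   otherwise. For matrices over chain states, state = index - 1.
#' @slot tolerance the slack used in the comparison.
#'
#' @exportClass OrderReport
setClass("OrderReport",
         representation(check = "character", holds = "logical",
                        margin = "numeric", witness = "integer",
                        tolerance = "numeric"))

setValidity("OrderReport", function(object) {
  msg <- character()
  if (object@holds != (object@margin >= -object@tolerance))
    msg <- c(msg, "'holds' must equal margin >= -tolerance")
  if (!object@holds && length(object@witness) == 0L)
    msg <- c(msg, "a failing report must carry a witness")
  if (object@holds && length(object@witness) != 0L)
    msg <- c(msg, "a passing report must not carry a witness")
  if (length(msg)) msg else TRUE
})

#' Result of an upper-control-limit search
#'
#' @slot U the chosen (smallest feasible) upper control limit.
#' @slot achievedArl in-control ARL at the chosen \code{U}.
#' @slot targetArl the requested minimum in-control ARL.
#' @slot init initial-state policy used ("overall" or the fixed state as a
#'   character).
#'
#' @seealso [findUCL()]
#' @exportClass DesignResult
setClass("DesignResult",
         representation(U = "integer", achievedArl = "numeric",
                        targetArl = "numeric", init = "character"))
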