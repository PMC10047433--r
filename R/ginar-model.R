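#' @include AllGenerics.R
NULL

#' Construct a GINAR(1) model
#'
#' @param p geometric marginal parameter in (0, 1). The marginal pmf is
#'   \eqn{P(X = j) = (1-p)^j p} on \eqn{\{0, 1, 2, \dots\}} (support starts
#'   at 0; many libraries use support \eqn{\{1, 2, \dots\}} — this package
#'   does not), so the process mean is \eqn{(1-p)/p}.
#' @param rho thinning parameter in \eqn{[0, 1)}; equals the lag-1
#'   autocorrelation. \code{rho = 0} gives the iid geometric limit.
#'
#' @return a [GINARModel-class] object.
#' @examples
#' m <- GINARModel(p = 0.63, rho = 0.165)
#' marginalMean(m)   # (1 - 0.63) / 0.63
#' @export
GINARModel <- function(p, rho = 0) {
  new("GINARModel", p = as.numeric(p), rho = as.numeric(rho))
}

#' @rdname GINARModel-class
#' @export
setMethod("geomParam", "GINARModel", function(object) object@p)

#' @rdname GINARModel-class
#' @export
setMethod("thinParam", "GINARModel", function(object) object@rho)

#' @rdname GINARModel-class
#' @export
setMethod("marginalMean", "GINARModel",
          function(object) (1 - object@p) / object@p)

#' @rdname GINARModel-class
#' @export
setMethod("marginalVar", "GINARModel",
          function(object) (1 - object@p) / object@p^2)

#' @rdname GINARModel-class
#' @export
setMethod("kalmykovDomain", "GINARModel",
          function(object) object@rho / (object@rho + 1) < object@p)

setMethod("show", "GINARModel", function(object) {
  cat(sprintf("GINAR(1) model: p = %g, rho = %g\n", object@p, object@rho))
  cat(sprintf("  marginal geometric(p) on {0,1,...}: mean %.4f, var %.4f\n",
              marginalMean(object), marginalVar(object)))
  cat(sprintf("  lag-k autocorrelation rho^k; rho/(rho+1) = %.4f %s p\n",
              object@rho / (object@rho + 1),
              if (kalmykovDomain(object)) "<" else ">="))
  invisible(NULL)
})

#' Innovation probability function of a GINAR(1) process
#'
#' The innovations are products \eqn{\epsilon_t = B_t G_t} of a
#' Bernoulli\eqn{(1-\rho)} and an independent geometric\eqn{(p)} variable, so
#' \deqn{P(\epsilon = 0) = p(1-\rho) + \rho, \qquad
#'       P(\epsilon = j) = (1-\rho)(1-p)^j p, \; j \ge 1.}
#'
#' @param j non-negative integer (vectorised).
#' @param model a [GINARModel-class].
#' @return numeric vector of probabilities.
#' @examples
#' innovationPmf(0, GINARModel(0.63, 0.165))  # 0.69105
#' @export
innovationPmf <- function(j, model) {
  stopifnot(is(model, "GINARModel"))
  if (anyNA(j) || any(j < 0) || any(j != floor(j)))
    stop("'j' must be non-negative integer(s)")
  p <- model@p; rho <- model@rho
  ifelse(j == 0, p * (1 - rho) + rho, (1 - rho) * stats::dgeom(j, p))
}

#' Exact one-step transition probability of a GINAR(1) chain
#'
#' Computes \eqn{p_{ij}(p,\rho) = P(X_t = j \mid X_{t-1} = i)}: the
#' convolution of the binomial\eqn{(i, \rho)} thinning survivors with the
#' Bernoulli-geometric innovation, written in closed form as
#' \deqn{p_{ij} = \sum_{m=0}^{\min(i,j)} \binom{i}{m}\rho^m(1-\rho)^{i-m}
#'   (1-\rho)(1-p)^{j-m} p
#'   \;+\; \binom{i}{j}\rho^j(1-\rho)^{i-j}\,\rho \, [i \ge j].}
#' Binomial terms are evaluated through [stats::dbinom()] (log-space
#' internally), so large states (\eqn{n \ge 200}) are overflow-safe.
#'
#' @param i,j non-negative integer states; \code{j} may be a vector.
#' @param model a [GINARModel-class].
#' @return numeric vector of probabilities, one per element of \code{j}.
#' @examples
#' m <- GINARModel(0.63, 0.165)
#' transitionProb(0, 0:5, m)    # row 0 equals the innovation pmf
#' @export
transitionProb <- function(i, j, model) {
  stopifnot(is(model, "GINARModel"))
  if (length(i) != 1L || is.na(i) || i < 0 || i != floor(i))
    stop("'i' must be a single non-negative integer")
  if (anyNA(j) || any(j < 0) || any(j != floor(j)))
    stop("'j' must be non-negative integer(s)")
  .transitionRow(i, max(j), model@p, model@rho)[j + 1L]
}

# One row of the transition matrix, states j = 0..jmax, fully vectorised.
# First piece: thinning survivors m, innovation j - m >= 0 contributing
# (1-rho) * dgeom(j - m, p); second piece: all i thinned to j exactly and
# the innovation's extra atom rho at 0.
.transitionRow <- function(i, jmax, p, rho) {
  thin <- stats::dbinom(0:i, i, rho)
  lag <- outer(0:i, 0:jmax, function(m, j) ifelse(j >= m,
                                                  stats::dgeom(j - m, p), 0))
  drop(thin %*% ((1 - rho) * lag)) + rho * stats::dbinom(0:jmax, i, rho)
}

#' Theoretical autocorrelation of a GINAR(1) process
#'
#' @param k non-negative integer lag (vectorised).
#' @param model a [GINARModel-class].
#' @return \eqn{\rho^k} (1 at lag 0).
#' @export
theoreticalAcf <- function(k, model) {
  stopifnot(is(model, "GINARModel"))
  if (anyNA(k) || any(k < 0)) stop("lag 'k' must be non-negative")
  thinParam(model)^k
}

#' Binomial thinning operator
#'
#' Draws \eqn{\rho \circ x = \sum_{t=1}^{x} Y_t} with iid
#' Bernoulli\eqn{(\rho)} counters \eqn{Y_t}: a binomial\eqn{(x, \rho)}
#' variate. By convention \eqn{0 \circ x = 0} and \eqn{1 \circ x = x}.
#' Uses the current R random stream.
#'
#' @param x non-negative integer (vectorised).
#' @param rho retention probability in \eqn{[0, 1]}.
#' @return integer draws, elementwise in \eqn{\{0, \dots, x\}}.
#' @export
binomialThinning <- function(x, rho) {
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop("'x' must be non-negative integer(s)")
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]")
  stats::rbinom(length(x), size = x, prob = rho)
}

#' Simulate a GINAR(1) count series
#'
#' Iterates \eqn{X_t = \rho \circ X_{t-1} + B_t G_t} with the thinning drawn
#' by [binomialThinning()] and each innovation drawn as the product of a
#' Bernoulli\eqn{(1-\rho)} and a geometric\eqn{(p)} variate (two draws, exact
#' fidelity to the defining recursion, rather than inverse-cdf sampling of
#' the innovation law). All randomness flows through the single R stream
#' seeded by \code{seed}.
#'
#' @param model a [GINARModel-class].
#' @param length number of observations \eqn{T \ge 1} to return.
#' @param init \code{"stationary"} (first value drawn geometric\eqn{(p)}, so
#'   the whole series is stationary) or a fixed non-negative integer state
#'   for the first value.
#' @param seed optional integer seed; when supplied the series is
#'   reproducible.
#' @return a [CountSeries-class] of \code{length} values.
#' @examples
#' s <- simulateGINAR(GINARModel(0.63, 0.165), length = 200, seed = 1)
#' mean(counts(s))
#' @export
simulateGINAR <- function(model, length, init = "stationary", seed = NULL) {
  stopifnot(is(model, "GINARModel"))
  if (length(length) != 1L || is.na(length) || length < 1)
    stop("'length' must be at least 1")
  length <- as.integer(length)
  if (!is.null(seed)) set.seed(seed)
  p <- model@p; rho <- model@rho
  x <- integer(length)
  x[1L] <- if (identical(init, "stationary")) {
    stats::rgeom(1L, p)
  } else {
    if (!is.numeric(init) || length(init) != 1L || init < 0 ||
        init != floor(init))
      stop("'init' must be \"stationary\" or a non-negative integer")
    as.integer(init)
  }
  if (length > 1L) {
    eps <- stats::rbinom(length - 1L, 1L, 1 - rho) *
      stats::rgeom(length - 1L, p)
    for (t in 2:length)
      x[t] <- stats::rbinom(1L, x[t - 1L], rho) + eps[t - 1L]
  }
  new("CountSeries", values = x, model = model,
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Moment estimation of GINAR(1) parameters
#'
#' Minimal moment-based estimators supporting the monitoring workflow:
#' \eqn{\hat p = 1 / (1 + \bar x)} (from the geometric marginal mean) and
#' \eqn{\hat\rho} equal to the lag-1 sample autocorrelation clipped to
#' \eqn{[0, 1)}. Likelihood-based fitting is deliberately out of scope.
#'
#' @param series a [CountSeries-class] (or bare non-negative integer vector)
#'   with at least 10 observations and positive sample mean.
#' @return a [GINARModel-class] with the estimated parameters.
#' @examples
#' s <- simulateGINAR(GINARModel(0.63, 0.165), 5000, seed = 42)
#' estimateParams(s)
#' @export
estimateParams <- function(series) {
  x <- if (is(series, "CountSeries")) series@values else as.numeric(series)
  if (length(x) < 10L) stop("need at least 10 observations")
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  xb <- mean(x)
  if (xb <= 0) stop("sample mean must be positive (constant-zero series)")
  if (stats::sd(x) == 0)
    stop("constant series: lag-1 autocorrelation is undefined")
  r1 <- stats::cor(x[-length(x)], x[-1L])
  GINARModel(p = 1 / (1 + xb), rho = min(max(r1, 0), 1 - 1e-8))
}
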