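#' @include ordering.R
NULL

#' Construct a chart specification
#'
#' @param U upper control limit (non-negative integer); the chart signals
#'   at the first \eqn{t} with \eqn{X_t > U}.
#' @param init either a fixed initial state in \eqn{\{0, \dots, U\}} (state
#'   0 is the classical start, state \code{U} a head start) or the token
#'   \code{"overall"}: the initial state is the random first observation
#'   \eqn{X_1 \sim} geometric\eqn{(p)}, and a signal at \eqn{t = 1} is
#'   possible.
#' @return a [ChartSpec-class].
#' @examples
#' chartSpec(5, 0)          # classical start
#' chartSpec(5, "overall")  # random geometric start
#' @export
chartSpec <- function(U, init = 0L) {
  u <- if (identical(init, "overall")) NA_integer_ else {
    if (!is.numeric(init) || length(init) != 1L || init != floor(init))
      stop("'init' must be \"overall\" or an integer state in 0..U")
    as.integer(init)
  }
  new("ChartSpec", U = as.integer(U), u = u)
}

#' @param chart a [ChartSpec-class].
#' @describeIn chartSpec \code{TRUE} for the random-geometric-start policy.
#' @export
isOverall <- function(chart) {
  stopifnot(is(chart, "ChartSpec"))
  is.na(chart@u)
}

setMethod("show", "ChartSpec", function(object) {
  cat(sprintf("Upper one-sided geometric chart: UCL U = %d, init = %s\n",
              object@U,
              if (is.na(object@u)) "overall (X1 ~ geometric(p))"
              else sprintf("fixed state u = %d", object@u)))
  invisible(NULL)
})

#' Substochastic in-control block of the chart's Markov chain
#'
#' The \eqn{(U+1)\times(U+1)} matrix
#' \eqn{Q = [p_{ij}(p,\rho)]_{i,j \in \{0,\dots,U\}}} of transitions among
#' the non-signalling states. \code{Q} is exact — it is a finite block of
#' the infinite transition matrix, so no truncation error is involved — and
#' every row sum is strictly below 1 (escape beyond \eqn{U} has positive
#' probability from every state).
#'
#' @param model a [GINARModel-class].
#' @param U upper control limit.
#' @return a numeric matrix with state dimnames.
#' @export
substochasticBlock <- function(model, U) {
  stopifnot(is(model, "GINARModel"))
  if (length(U) != 1L || is.na(U) || U < 0 || U != floor(U))
    stop("'U' must be a single non-negative integer")
  entries(transitionMatrix(model, n = as.integer(U)))
}

# Defective initial distribution of the overall run length:
# pi_u = P(X1 = u) = (1-p)^u p for u = 0..U; the deficit P(X1 > U) is the
# probability of a signal at t = 1.
.overallInit <- function(model, U) {
  stats::dgeom(0:U, geomParam(model))
}

#' Exact run-length distribution of the geometric chart
#'
#' Markov-chain (Brook-Evans) computation of the run-length law. For a
#' fixed initial state \eqn{u}, \eqn{P(RL_u > m) = e_u^\top Q^m \mathbf 1}.
#' For the overall policy, \eqn{P(RL > 0) = 1} and, for \eqn{m \ge 1},
#' \eqn{P(RL > m) = \pi^\top Q^{m-1} \mathbf 1} with the defective vector
#' \eqn{\pi_u = (1-p)^u p}, \eqn{u \le U} — the missing mass
#' \eqn{P(X_1 > U)} is the probability of signalling at \eqn{t = 1}. The
#' horizon \eqn{M} is the first \eqn{m} with survival below \code{eps}
#' (capped at \code{maxHorizon}).
#'
#' @param model a [GINARModel-class].
#' @param chart a [ChartSpec-class].
#' @param eps positive tail cutoff for the horizon; default \code{1e-12}.
#' @param maxHorizon hard cap on the horizon to bound memory.
#' @return a [RunLengthDistribution-class].
#' @examples
#' d <- rlDistribution(GINARModel(0.63, 0.165), chartSpec(5, 0))
#' head(rlHazard(d))      # increasing: RL0 has increasing hazard rate
#' 1 - perronXi(d)        # limiting hazard
#' @export
rlDistribution <- function(model, chart, eps = 1e-12, maxHorizon = 1e6) {
  stopifnot(is(model, "GINARModel"), is(chart, "ChartSpec"))
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("'eps' must be a positive tail cutoff")
  U <- chart@U
  Q <- substochasticBlock(model, U)
  xi <- perronRoot(Q)
  # State vector positioned so that sum(w) = P(RL > 1): for the overall
  # policy w is the defective pi itself (its deficit is the t = 1 signal);
  # for a fixed start it is row u of Q.
  w <- if (isOverall(chart)) .overallInit(model, U) else Q[chart@u + 1L, ]
  est <- ceiling(log(eps) / log(xi)) + 10L
  surv <- numeric(min(est, maxHorizon) + 1L)
  surv[1L] <- 1
  m <- 0L
  repeat {
    s <- sum(w)
    m <- m + 1L
    if (m + 1L > length(surv)) surv <- c(surv, numeric(length(surv)))
    surv[m + 1L] <- s
    if (s < eps || m >= maxHorizon) break
    w <- drop(w %*% Q)
  }
  surv <- surv[seq_len(m + 1L)]
  pmf <- -diff(surv)
  new("RunLengthDistribution", chart = chart, model = model, Q = Q,
      pmf = pmf, survival = surv, hazard = pmf / surv[-length(surv)],
      xi = xi)
}

#' @rdname rlPmf
#' @export
setMethod("rlPmf", "RunLengthDistribution", function(object) object@pmf)

#' @rdname rlPmf
#' @export
setMethod("rlSurvival", "RunLengthDistribution",
          function(object) object@survival)

#' @rdname rlPmf
#' @export
setMethod("rlHazard", "RunLengthDistribution",
          function(object) object@hazard)

#' @rdname rlPmf
#' @export
setMethod("perronXi", "RunLengthDistribution", function(object) object@xi)

#' @rdname ginarModel
#' @export
setMethod("ginarModel", "RunLengthDistribution",
          function(object) object@model)

setMethod("show", "RunLengthDistribution", function(object) {
  show(object@chart)
  cat(sprintf("  run-length horizon M = %d, Perron root xi = %.8f\n",
              length(object@pmf), object@xi))
  cat(sprintf("  limiting hazard 1 - xi = %.6g\n", 1 - object@xi))
  invisible(NULL)
})

#' Average run length of the geometric chart
#'
#' Exact ARL through the linear-solve path: for a fixed initial state
#' \eqn{u}, solve \eqn{(I - Q) a = \mathbf 1} and return \eqn{a_u}; for the
#' overall policy return \eqn{1 + \pi^\top a} with the defective geometric
#' initial vector (no explicit matrix inverse is formed).
#'
#' @param model a [GINARModel-class].
#' @param chart a [ChartSpec-class].
#' @return the expected run length, a scalar \eqn{\ge 1}.
#' @examples
#' m <- GINARModel(0.63, 0.165)
#' arl(m, chartSpec(5, 0))          # ~ 393.7
#' arl(m, chartSpec(5, 5))          # head start, ~ 391.4
#' arl(m, chartSpec(5, "overall"))  # ~ 393.5
#' @export
arl <- function(model, chart) {
  stopifnot(is(model, "GINARModel"), is(chart, "ChartSpec"))
  U <- chart@U
  Q <- substochasticBlock(model, U)
  a <- unname(solve(diag(U + 1L) - Q, rep(1, U + 1L)))
  if (isOverall(chart)) 1 + sum(.overallInit(model, U) * a)
  else a[chart@u + 1L]
}

#' Overall ARL with a random geometric initial state
#'
#' Convenience wrapper for \code{arl(model, chartSpec(U, "overall"))}: the
#' expected overall run length when the chart starts from the random first
#' observation \eqn{X_1 \sim} geometric\eqn{(p)} of the monitored process
#' itself. Increasing in \eqn{p} on \eqn{(\rho/(\rho+1), 1)}.
#'
#' @param model a [GINARModel-class].
#' @param U upper control limit.
#' @return a scalar ARL.
#' @export
overallArl <- function(model, U) {
  arl(model, chartSpec(U, "overall"))
}

#' Perron root of a non-negative substochastic matrix
#'
#' The maximum real eigenvalue \eqn{\xi \in (0, 1)} of the in-control block
#' \eqn{Q}; the run-length tail is geometric-like with parameter
#' \eqn{1 - \xi}, and the hazard rates of all initial states converge to
#' \eqn{1 - \xi}. The default path is the full dense eigendecomposition
#' (adequate for the chart-sized blocks used here); \code{method = "power"}
#' is an independent power-iteration route kept as a cross-check.
#'
#' @param Q a non-negative square matrix with row sums \eqn{\le 1}.
#' @param method \code{"eigen"} (default) or \code{"power"}.
#' @param tol convergence tolerance for the power iteration.
#' @param maxit iteration cap for the power iteration.
#' @return the Perron eigenvalue, a scalar.
#' @export
perronRoot <- function(Q, method = c("eigen", "power"), tol = 1e-14,
                       maxit = 100000L) {
  method <- match.arg(method)
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || any(Q < 0))
    stop("'Q' must be a square non-negative matrix")
  if (method == "eigen") {
    # Q >= 0 guarantees the spectral radius is attained at a real
    # non-negative eigenvalue (Perron-Frobenius).
    max(Re(eigen(Q, only.values = TRUE)$values))
  } else {
    v <- rep(1, nrow(Q))
    lam <- 1
    for (it in seq_len(maxit)) {
      w <- drop(Q %*% v)
      lamNew <- sqrt(sum(w^2)) / sqrt(sum(v^2))
      w <- w / max(w)
      if (abs(lamNew - lam) < tol && it > 5L) return(lamNew)
      v <- w; lam <- lamNew
    }
    stop("power iteration failed to converge")
  }
}

#' Summary performance measures of a run length
#'
#' ARL from the linear-solve path of [arl()]; SDRL from the phase-type
#' second moment \eqn{E[RL^2] = e_u^\top (I + Q)(I - Q)^{-2}\mathbf 1}
#' (fixed start) or \eqn{1 + 2\pi^\top a + \pi^\top s} under the overall
#' convention (signal possible at \eqn{t = 1}), where \eqn{a} and \eqn{s}
#' are the first and second conditional moments; percentile \eqn{q} is the
#' smallest \eqn{m} with \eqn{P(RL \le m) \ge q}.
#'
#' @param dist a [RunLengthDistribution-class].
#' @param percentiles probabilities in (0, 1); default median only.
#' @return a [RunLengthSummary-class].
#' @examples
#' d <- rlDistribution(GINARModel(0.63, 0.165), chartSpec(5, 0))
#' rlSummary(d, c(0.5, 0.95))
#' @export
rlSummary <- function(dist, percentiles = 0.5) {
  stopifnot(is(dist, "RunLengthDistribution"))
  if (any(percentiles <= 0 | percentiles >= 1))
    stop("percentiles must lie strictly between 0 and 1")
  Q <- dist@Q
  n <- nrow(Q)
  I <- diag(n)
  a <- unname(solve(I - Q, rep(1, n)))            # E[RL_u]
  y <- solve(I - Q, a)                            # (I-Q)^{-2} 1
  s <- drop((I + Q) %*% y)                        # E[RL_u^2]
  if (isOverall(dist@chart)) {
    pi0 <- .overallInit(dist@model, dist@chart@U)
    m1 <- 1 + sum(pi0 * a)
    m2 <- 1 + 2 * sum(pi0 * a) + sum(pi0 * s)
  } else {
    u <- dist@chart@u + 1L
    m1 <- a[u]
    m2 <- s[u]
  }
  cdf <- 1 - dist@survival[-1L]                   # P(RL <= m), m = 1..M
  q <- vapply(percentiles,
              function(p) as.numeric(which(cdf >= p)[1L]), numeric(1))
  names(q) <- paste0("q", formatC(100 * percentiles, format = "g"))
  new("RunLengthSummary", arl = m1, sdrl = sqrt(max(m2 - m1^2, 0)),
      quantiles = q, limitingHazard = 1 - dist@xi)
}

setMethod("show", "RunLengthSummary", function(object) {
  cat(sprintf("Run-length summary: ARL = %.4f, SDRL = %.4f\n",
              object@arl, object@sdrl))
  cat("  percentiles:",
      paste(names(object@quantiles), object@quantiles, sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  limiting hazard 1 - xi = %.6g\n", object@limitingHazard))
  invisible(NULL)
})
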