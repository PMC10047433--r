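#' @include runlength.R
NULL

#' Find the smallest UCL achieving a target in-control ARL
#'
#' The in-control ARL is nondecreasing in the upper control limit, so the
#' smallest \eqn{U} with \eqn{ARL(U) \ge} \code{targetArl} is located by
#' doubling followed by bisection (exact, since the scan is over integers).
#' The \code{">= target"} convention is the usual design convention for
#' attribute charts: false alarms at most as frequent as requested.
#'
#' @param model a [GINARModel-class] at the in-control parameters.
#' @param targetArl required minimum in-control ARL (> 1).
#' @param init initial-state policy: fixed integer state or
#'   \code{"overall"}. A fixed state must remain \eqn{\le U}; the scan
#'   starts at \eqn{U =} \code{init} in that case.
#' @param maxU hard cap on the search; an unreachable target raises an
#'   explicit error.
#' @return a [DesignResult-class].
#' @examples
#' findUCL(GINARModel(0.63, 0.165), targetArl = 370, init = 0)  # U = 5
#' @export
findUCL <- function(model, targetArl, init = 0L, maxU = 1000L) {
  stopifnot(is(model, "GINARModel"))
  if (!is.numeric(targetArl) || length(targetArl) != 1L || targetArl <= 1)
    stop("'targetArl' must exceed 1")
  overall <- identical(init, "overall")
  u0 <- if (overall) 0L else as.integer(init)
  arlAt <- function(U) arl(model, chartSpec(U, if (overall) "overall"
                                            else min(u0, U)))
  lo <- u0
  if (arlAt(lo) >= targetArl) {
    hi <- lo
  } else {
    hi <- max(lo, 1L)
    while (arlAt(hi) < targetArl) {
      if (hi >= maxU)
        stop("target ARL ", targetArl, " unreachable with U <= ", maxU)
      hi <- min(2L * hi, maxU)
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (arlAt(mid) >= targetArl) hi <- mid else lo <- mid
    }
  }
  new("DesignResult", U = as.integer(hi), achievedArl = arlAt(hi),
      targetArl = targetArl,
      init = if (overall) "overall" else as.character(u0))
}

setMethod("show", "DesignResult", function(object) {
  cat(sprintf(
    "UCL search: U = %d (ARL %.4f >= target %.4f, init %s)\n",
    object@U, object@achievedArl, object@targetArl, object@init))
  invisible(NULL)
})

#' ARL profile over a grid of marginal parameters
#'
#' Tabulates the ARL of a fixed chart as the process parameter \eqn{p}
#' moves over a grid (the thinning parameter \eqn{\rho} stays at its
#' in-control value). The chart detects decreases in \eqn{p} — i.e.
#' increases in the process mean \eqn{(1-p)/p} — so the ARL falls as
#' \eqn{p} drops; for the \code{"overall"} policy it is monotone increasing
#' in \eqn{p} on \eqn{(\rho/(\rho+1), 1)}. Increases in \eqn{p} only
#' lengthen the run: this chart cannot detect upward shifts in \eqn{p}
#' expediently, which the profile makes visible rather than hiding.
#'
#' @param model a [GINARModel-class] fixing \eqn{\rho} (its \eqn{p} is not
#'   used beyond defaults).
#' @param U upper control limit of the chart.
#' @param pGrid numeric vector of marginal parameters in (0, 1).
#' @param init initial-state policy (fixed state or \code{"overall"}).
#' @return a \code{data.frame} with columns \code{p}, \code{mean}
#'   (\eqn{(1-p)/p}) and \code{arl}.
#' @export
arlProfile <- function(model, U, pGrid, init = "overall") {
  stopifnot(is(model, "GINARModel"))
  if (any(pGrid <= 0 | pGrid >= 1)) stop("grid values must lie in (0, 1)")
  rho <- thinParam(model)
  chart <- chartSpec(U, init)
  vals <- vapply(pGrid, function(p) arl(GINARModel(p, rho), chart),
                 numeric(1))
  data.frame(p = pGrid, mean = (1 - pGrid) / pGrid, arl = vals)
}

#' Numerically exercise every run-length ordering property at once
#'
#' One-shot verifier aggregating the structural consequences of the TP2 /
#' Kalmykov results for the chart at hand:
#' \itemize{
#'   \item PF2 (log-concavity) of the \eqn{RL_0} pmf, hence increasing
#'     hazard from the zero start;
#'   \item hazard monotonicity: nondecreasing for \eqn{RL_0}, nonincreasing
#'     for the head-start \eqn{RL_U};
#'   \item hazard dominance \eqn{\lambda_{RL_U}(m) \ge \lambda_{RL_0}(m)};
#'   \item likelihood-ratio ordering of the run-length pmfs across all
#'     initial-state pairs \eqn{u \le u'};
#'   \item usual-order dominance of run-length survival across the
#'     parameter pair \eqn{p \le p'} and across initial states;
#'   \item monotone overall ARL on a 10-point grid in
#'     \eqn{(\rho/(\rho+1), p]};
#'   \item convergence of both hazards to the limiting value
#'     \eqn{1 - \xi}.
#' }
#'
#' @param model in-control [GINARModel-class]; requires
#'   \eqn{\rho/(\rho+1) < p} ([kalmykovDomain()]).
#' @param U upper control limit.
#' @param pPrime comparison parameter with \eqn{p \le p' < 1}.
#' @param tol tolerance passed to the ordering checks.
#' @return a list of [OrderReport-class] objects and logical checks, plus
#'   \code{allPass}.
#' @examples
#' rep <- verifyCorollaries(GINARModel(0.63, 0.165), U = 5, pPrime = 0.7)
#' rep$allPass
#' @export
verifyCorollaries <- function(model, U, pPrime, tol = 1e-12) {
  stopifnot(is(model, "GINARModel"))
  p <- geomParam(model); rho <- thinParam(model)
  if (!kalmykovDomain(model))
    stop("precondition violated: need rho/(rho+1) < p, got rho/(rho+1) = ",
         format(rho / (rho + 1)), " >= p = ", format(p))
  if (pPrime < p || pPrime >= 1)
    stop("'pPrime' must satisfy p <= pPrime < 1")
  modelPrime <- GINARModel(pPrime, rho)
  dists <- lapply(0:U, function(u)
    rlDistribution(model, chartSpec(U, u)))
  # pairwise lr checks are O(grid^2); cap the grid at 2000 masses (the
  # tail beyond is geometric with ratio xi and adds no information).
  M <- min(2000L, vapply(dists, function(d) length(rlPmf(d)), integer(1)))
  pmfs <- lapply(dists, function(d) rlPmf(d)[seq_len(M)])
  out <- list()
  out$pf2_rl0 <- isPF2(pmfs[[1L]], tol)
  hz0 <- rlHazard(dists[[1L]]); hzU <- rlHazard(dists[[U + 1L]])
  Mh <- min(length(hz0), length(hzU))
  out$ihr_rl0 <- all(diff(hz0) >= -tol)
  out$dhr_rlU <- all(diff(hzU) <= tol)
  out$hazard_dominance <- all(hzU[seq_len(Mh)] >= hz0[seq_len(Mh)] - tol)
  lrOK <- TRUE
  if (U >= 1L) for (u in 0:(U - 1L)) for (up in (u + 1L):U) {
    r <- lrLE(pmfs[[up + 1L]], pmfs[[u + 1L]], tol)  # RL_{u'} <=lr RL_u
    if (!r@holds) { lrOK <- FALSE; out$lr_witness <- r }
  }
  out$lr_initial_state <- lrOK
  # survival dominance: RL_u(p) <=st RL_{u'}(p') for u' <= u, p <= p'
  dP0 <- rlDistribution(model, chartSpec(U, U))
  dP1 <- rlDistribution(modelPrime, chartSpec(U, 0L))
  Ms <- min(length(rlSurvival(dP0)), length(rlSurvival(dP1)))
  out$st_in_p_and_u <- all(rlSurvival(dP0)[seq_len(Ms)] <=
                             rlSurvival(dP1)[seq_len(Ms)] + tol)
  grid <- seq(rho / (rho + 1) + 1e-6, p, length.out = 10L)
  prof <- arlProfile(model, U, grid, init = "overall")
  out$overall_arl_monotone <- all(diff(prof$arl) > 0)
  lim <- 1 - perronXi(dists[[1L]])
  mTail <- min(2000L, length(hz0), length(hzU))
  out$hazard_limit <- abs(hz0[mTail] - lim) < 1e-6 &&
    abs(hzU[mTail] - lim) < 1e-6
  checks <- vapply(out, function(x)
    if (is(x, "OrderReport")) x@holds else isTRUE(x), logical(1))
  out$allPass <- all(checks[setdiff(names(checks), "lr_witness")])
  out
}

#' Monitor a count series against a designed chart
#'
#' Flags every index whose count exceeds the UCL and reports the first
#' signal time; when no count exceeds the limit the run length is reported
#' as censored at the series length.
#'
#' @param series a [CountSeries-class] or bare non-negative integer vector
#'   of monitored counts \eqn{X_1, X_2, \dots}.
#' @param U upper control limit.
#' @return a list: \code{signal} (logical), \code{firstSignal} (index or
#'   \code{NA}), \code{signals} (all offending indices), \code{runLength},
#'   and \code{censored}.
#' @export
monitorSeries <- function(series, U) {
  x <- if (is(series, "CountSeries")) counts(series) else as.integer(series)
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative integers")
  if (length(U) != 1L || U < 0) stop("'U' must be a non-negative integer")
  sig <- which(x > U)
  hit <- length(sig) > 0L
  list(signal = hit,
       firstSignal = if (hit) sig[1L] else NA_integer_,
       signals = sig,
       runLength = if (hit) sig[1L] else length(x),
       censored = !hit)
}
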