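#' @include transition-matrix.R
NULL

# Internal constructor enforcing the OrderReport invariant.
.orderReport <- function(check, margin, witness, tol) {
  holds <- margin >= -tol
  new("OrderReport", check = check, holds = holds, margin = margin,
      witness = if (holds) integer(0) else as.integer(witness),
      tolerance = tol)
}

setMethod("show", "OrderReport", function(object) {
  cat(sprintf("OrderReport [%s]: %s (margin %.3g, tol %.3g)\n",
              object@check, if (object@holds) "holds" else "VIOLATED",
              object@margin, object@tolerance))
  if (!object@holds)
    cat("  witness indices:", paste(object@witness, collapse = ", "), "\n")
  invisible(NULL)
})

#' Convert an order report to a plain list
#'
#' Convenience for JSON serialisation of [OrderReport-class] verdicts.
#'
#' @param report an [OrderReport-class].
#' @return a named list with fields check, holds, margin, witness,
#'   tolerance.
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "OrderReport"))
  list(check = report@check, holds = report@holds, margin = report@margin,
       witness = report@witness, tolerance = report@tolerance)
}

.asMatrix <- function(m) {
  if (is(m, "TransitionMatrix")) m <- entries(m)
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be a numeric matrix")
  if (any(m < 0)) stop("matrix entries must be non-negative")
  m
}

#' Total positivity of order 2 (TP2) of a non-negative matrix
#'
#' A matrix is TP2 when every 2x2 minor taken from rows \eqn{i < k} and
#' columns \eqn{j < l}, \eqn{m_{ij} m_{kl} - m_{il} m_{kj}}, is
#' non-negative; equivalently successive rows are ordered in likelihood
#' ratio. The exhaustive all-pairs scan is the reference check (truncated
#' transition-matrix rows can contain exact zeros, for which the
#' adjacent-minor shortcut argument fails); see [isTP2Adjacent()] for the
#' documented shortcut. The GINAR(1) transition matrix is TP2 for every
#' admissible parameter pair, so on [transitionMatrix()] entries only
#' floating-point rounding can produce (tiny) negative minors.
#'
#' @param m a numeric matrix with non-negative entries, or a
#'   [TransitionMatrix-class].
#' @param tol tolerance on the minors; default \code{1e-12} (entries are
#'   O(1) probabilities, so minors below this are rounding noise).
#' @return an [OrderReport-class]; \code{margin} is the smallest minor and
#'   the witness is \code{c(i, k, j, l)} (row pair then column pair,
#'   1-based).
#' @examples
#' isTP2(matrix(c(.1, .9, .9, .1), 2, byrow = TRUE))  # violated
#' @export
isTP2 <- function(m, tol = 1e-12) {
  m <- .asMatrix(m)
  nr <- nrow(m); nc <- ncol(m)
  best <- Inf; wit <- integer(0)
  if (nr >= 2L && nc >= 2L) {
    upper <- upper.tri(matrix(0, nc, nc))
    for (i in 1:(nr - 1L)) {
      for (k in (i + 1L):nr) {
        A <- outer(m[i, ], m[k, ])      # A[j, l] = m[i,j] m[k,l]
        D <- t(A) - A                   # minor(j, l) = A[j,l] - A[l,j]
        D <- t(D)
        mn <- min(D[upper])
        if (mn < best) {
          best <- mn
          jl <- which(D == mn & upper, arr.ind = TRUE)[1L, ]
          wit <- c(i, k, jl[[1L]], jl[[2L]])
        }
      }
    }
  } else best <- 0
  .orderReport("TP2", best, wit, tol)
}

#' @describeIn isTP2 adjacent-minor shortcut: checks only row pairs
#'   \eqn{(i, i+1)} and column pairs \eqn{(j, j+1)}. Sufficient for TP2 on
#'   strictly positive matrices; provided for speed, the exhaustive scan
#'   remains the reference.
#' @export
isTP2Adjacent <- function(m, tol = 1e-12) {
  m <- .asMatrix(m)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(.orderReport("TP2-adjacent", 0, integer(0), tol))
  D <- m[-nr, -nc] * m[-1L, -1L] - m[-nr, -1L] * m[-1L, -nc]
  best <- min(D)
  wit <- which(D == best, arr.ind = TRUE)[1L, ]
  .orderReport("TP2-adjacent", best,
               c(wit[[1L]], wit[[1L]] + 1L, wit[[2L]], wit[[2L]] + 1L), tol)
}

#' PF2 (log-concavity) of a probability sequence
#'
#' A pmf \eqn{f} on \eqn{\{0, 1, \dots\}} is a Polya frequency sequence of
#' order 2 iff \eqn{f(x+1)^2 \ge f(x) f(x+2)} for all \eqn{x}; for run
#' lengths this is equivalent to an increasing hazard rate. The geometric
#' pmf is the equality case (all defining expressions exactly 0).
#'
#' @param pmf numeric vector of non-negative masses, positions
#'   \eqn{x = 0, 1, \dots} (or 1, 2, ... — only contiguity matters).
#' @param tol tolerance, default \code{1e-12}.
#' @return an [OrderReport-class]; witness is the R index of the first
#'   minimising \eqn{x}.
#' @export
isPF2 <- function(pmf, tol = 1e-12) {
  pmf <- as.numeric(pmf)
  if (any(pmf < 0)) stop("pmf entries must be non-negative")
  n <- length(pmf)
  if (n < 3L) return(.orderReport("PF2", 0, integer(0), tol))
  d <- pmf[2:(n - 1L)]^2 - pmf[1:(n - 2L)] * pmf[3:n]
  best <- min(d)
  .orderReport("PF2", best, which.min(d), tol)
}

.checkGrid <- function(f, g) {
  f <- as.numeric(f); g <- as.numeric(g)
  if (length(f) != length(g))
    stop("'f' and 'g' must share a common support grid")
  if (any(f < 0) || any(g < 0)) stop("pmf entries must be non-negative")
  list(f = f, g = g)
}

#' Likelihood-ratio order of two discrete distributions
#'
#' Checks \eqn{f \le_{lr} g} on a common grid: \eqn{g/f} nondecreasing where
#' defined, verified in cross-product form
#' \eqn{f(x) g(y) \ge f(y) g(x)} for all \eqn{x < y}, which needs no
#' special-casing of zero-probability cells. The lr order implies the usual
#' stochastic order checked by [stLE()].
#'
#' @param f,g numeric pmf vectors on the same grid.
#' @param tol tolerance, default \code{1e-12}.
#' @return an [OrderReport-class]; witness is \code{c(x, y)} (1-based grid
#'   indices).
#' @export
lrLE <- function(f, g, tol = 1e-12) {
  fg <- .checkGrid(f, g)
  A <- outer(fg$f, fg$g)                # A[x, y] = f(x) g(y)
  D <- A - t(A)                         # f(x)g(y) - f(y)g(x)
  up <- upper.tri(D)
  if (!any(up)) return(.orderReport("lr-le", 0, integer(0), tol))
  best <- min(D[up])
  wit <- which(D == best & up, arr.ind = TRUE)[1L, ]
  .orderReport("lr-le", best, c(wit[[1L]], wit[[2L]]), tol)
}

#' Usual stochastic order of two discrete distributions
#'
#' Checks \eqn{f \le_{st} g} on a common grid by survival-function
#' dominance: \eqn{\sum_{y \ge x} f(y) \le \sum_{y \ge x} g(y)} for every
#' grid point \eqn{x}.
#'
#' @inheritParams lrLE
#' @return an [OrderReport-class]; \code{margin} is the smallest gap
#'   \eqn{\bar G(x) - \bar F(x)} and the witness its grid index.
#' @export
stLE <- function(f, g, tol = 1e-12) {
  fg <- .checkGrid(f, g)
  sf <- rev(cumsum(rev(fg$f)))
  sg <- rev(cumsum(rev(fg$g)))
  d <- sg - sf
  .orderReport("st-le", min(d), which.min(d), tol)
}

#' Kalmykov order between two transition matrices
#'
#' The chain with matrix \code{pSmall} is stochastically smaller (Kalmykov
#' order) than the chain with matrix \code{pLarge} when, for every pair of
#' states \eqn{i \le m}, row \eqn{i} of \code{pSmall} is dominated in the
#' usual order by row \eqn{m} of \code{pLarge}:
#' \deqn{\sum_{j \ge l} pSmall_{ij} \le \sum_{j \ge l} pLarge_{mj}
#'   \quad \text{for all } l.}
#' For GINAR(1) chains this holds with \code{pSmall} built at the larger
#' marginal parameter \eqn{p'} and \code{pLarge} at \eqn{p \le p'}, provided
#' \eqn{\rho/(\rho+1) < p} (see [kalmykovDomain()]); taking
#' \code{pSmall == pLarge} the check reduces to stochastic monotonicity of
#' the matrix in the usual sense.
#'
#' When [TransitionMatrix-class] objects are supplied, each row's audited
#' truncated tail mass is added back to its tail sums, so the comparison is
#' performed on the \emph{exact} infinite-state survival functions for
#' every cut \eqn{l \le n} (a raw truncated comparison can report spurious
#' violations of the order of the last rows' tail mass, because rows of
#' the heavier-tailed chain lose more mass to truncation). Plain matrices
#' are compared as given.
#'
#' @param pSmall,pLarge [TransitionMatrix-class] objects or numeric
#'   matrices of equal dimension (same truncation).
#' @param tol tolerance, default \code{1e-12}.
#' @return an [OrderReport-class]; witness is \code{c(i, m, l)} (1-based:
#'   offending row of \code{pSmall}, row of \code{pLarge}, tail start).
#' @export
kalmykovLE <- function(pSmall, pLarge, tol = 1e-12) {
  extraA <- if (is(pSmall, "TransitionMatrix")) tailMass(pSmall) else 0
  extraB <- if (is(pLarge, "TransitionMatrix")) tailMass(pLarge) else 0
  A <- .asMatrix(pSmall); B <- .asMatrix(pLarge)
  if (!all(dim(A) == dim(B)))
    stop("matrices must have equal dimensions (same truncation)")
  tailA <- t(apply(A, 1L, function(r) rev(cumsum(rev(r))))) + extraA
  tailB <- t(apply(B, 1L, function(r) rev(cumsum(rev(r))))) + extraB
  # runMax[m, l] = max_{i <= m} tailA[i, l]; then need tailB[m, l] >=
  # runMax[m, l] for all m, l.
  runMax <- apply(tailA, 2L, cummax)
  D <- tailB - runMax
  best <- min(D)
  wit <- integer(0)
  if (best < -tol) {
    ml <- which(D == best, arr.ind = TRUE)[1L, ]
    m <- ml[[1L]]; l <- ml[[2L]]
    i <- which.max(tailA[seq_len(m), l])
    wit <- c(i, m, l)
  }
  .orderReport("kalmykov-le", best, wit, tol)
}
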