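#' @include ginar-model.R
NULL

#' Default truncation order for the transition matrix
#'
#' Smallest \eqn{n} with \eqn{(1-p)^{n+1} < 10^{-12}} (marginal tail rule),
#' so the stationary distribution carried by the truncated state space is
#' complete to within \eqn{10^{-12}}.
#'
#' @param model a [GINARModel-class].
#' @param tail tail cutoff, default \code{1e-12}.
#' @return an integer truncation order.
#' @export
defaultTruncation <- function(model, tail = 1e-12) {
  stopifnot(is(model, "GINARModel"))
  n <- ceiling(log(tail) / log(1 - geomParam(model))) - 1
  while ((1 - geomParam(model))^(n + 1) >= tail) n <- n + 1
  as.integer(max(n, 1L))
}

#' Build the truncated transition probability matrix
#'
#' Assembles the exact transition probabilities \eqn{p_{ij}(p,\rho)} (see
#' [transitionProb()]) on the truncated state space \eqn{\{0,\dots,n\}}.
#' Entries are never renormalised; the truncated per-row tail mass is
#' retained for audit via [tailMass()].
#'
#' @param model a [GINARModel-class].
#' @param n truncation order (states \eqn{0..n}); defaults to the marginal
#'   tail rule of [defaultTruncation()].
#' @return a [TransitionMatrix-class].
#' @examples
#' tm <- transitionMatrix(GINARModel(0.63, 0.165), n = 5)
#' entries(tm)[1, ]   # row of state 0 = innovation pmf
#' @export
transitionMatrix <- function(model, n = defaultTruncation(model)) {
  stopifnot(is(model, "GINARModel"))
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer")
  n <- as.integer(n)
  p <- geomParam(model); rho <- thinParam(model)
  P <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) P[i + 1L, ] <- .transitionRow(i, n, p, rho)
  dimnames(P) <- list(paste0("state_", 0:n), paste0("state_", 0:n))
  tail <- unname(1 - rowSums(P))
  tail[tail < 0 & tail > -1e-10] <- 0   # clamp pure rounding residue
  new("TransitionMatrix", model = model, entries = P, tailMass = tail)
}

#' @rdname entries
#' @export
setMethod("entries", "TransitionMatrix", function(object) object@entries)

#' @rdname tailMass
#' @export
setMethod("tailMass", "TransitionMatrix", function(object) object@tailMass)

#' @rdname ginarModel
#' @export
setMethod("ginarModel", "TransitionMatrix", function(object) object@model)

setMethod("show", "TransitionMatrix", function(object) {
  n <- nrow(object@entries) - 1L
  cat(sprintf(
    "GINAR(1) transition matrix, states 0..%d (p = %g, rho = %g)\n",
    n, geomParam(object@model), thinParam(object@model)))
  cat(sprintf("  max row tail mass: %.3g\n", max(object@tailMass)))
  invisible(NULL)
})

#' Write / read a transition matrix as CSV
#'
#' The CSV carries row names and column headers \code{state_0..state_n} plus
#' a trailing \code{tail_mass} column; the reader reverses the writer.
#'
#' @param object a [TransitionMatrix-class].
#' @param path file path.
#' @param model the [GINARModel-class] to attach on reading.
#' @return \code{writeTransitionMatrix} returns \code{path} invisibly;
#'   \code{readTransitionMatrix} returns a [TransitionMatrix-class].
#' @export
writeTransitionMatrix <- function(object, path) {
  stopifnot(is(object, "TransitionMatrix"))
  df <- data.frame(state = rownames(object@entries), object@entries,
                   tail_mass = object@tailMass, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTransitionMatrix
#' @export
readTransitionMatrix <- function(path, model) {
  stopifnot(is(model, "GINARModel"))
  df <- utils::read.csv(path, check.names = FALSE)
  states <- grep("^state_", names(df), value = TRUE)
  P <- as.matrix(df[, states])
  rownames(P) <- df$state
  new("TransitionMatrix", model = model, entries = P,
      tailMass = df$tail_mass)
}
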