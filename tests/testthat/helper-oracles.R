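# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: plain choose()/powers instead of dbinom,
# the merged-atom innovation law instead of the split closed form, direct
# path simulation instead of the phase-type engine.

refModel <- function() GINARModel(0.63, 0.165)

# Innovation pmf written straight from the Bernoulli-geometric product law.
oracleInnovation <- function(j, p, rho) {
  ifelse(j == 0, p * (1 - rho) + rho, (1 - rho) * (1 - p)^j * p)
}

# Transition probability as an explicit binomial (x) innovation convolution.
oracleTransition <- function(i, j, p, rho) {
  thin <- choose(i, 0:i) * rho^(0:i) * (1 - rho)^(i:0)
  m <- 0:min(i, j)
  sum(thin[m + 1] * oracleInnovation(j - m, p, rho))
}

# Monte-Carlo run lengths of the upper one-sided chart, simulating the
# process recursion directly, vectorised across paths.
mcRunLengths <- function(model, U, init, nrep) {
  p <- geomParam(model); rho <- thinParam(model)
  rl <- rep(NA_integer_, nrep)
  if (identical(init, "overall")) {
    x <- rgeom(nrep, p)            # X1, monitored: signal at t = 1 possible
    t <- 1L
    hit <- x > U
    rl[hit] <- 1L
    active <- !hit
  } else {
    x <- rep(as.integer(init), nrep)   # X0, not monitored
    t <- 0L
    active <- rep(TRUE, nrep)
  }
  while (any(active)) {
    idx <- which(active)
    x[idx] <- rbinom(length(idx), x[idx], rho) +
      rbinom(length(idx), 1L, 1 - rho) * rgeom(length(idx), p)
    t <- t + 1L
    sig <- x[idx] > U
    rl[idx[sig]] <- t
    active[idx[sig]] <- FALSE
  }
  rl
}

# Closed forms for the iid (rho = 0) chart: RL ~ geometric on {1, 2, ...}
# with success probability theta = (1-p)^(U+1).
iidTheta <- function(p, U) (1 - p)^(U + 1)
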