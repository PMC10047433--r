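test_that("substochastic block is the exact upper-left TPM block", {
  m <- refModel()
  Q <- substochasticBlock(m, 5)
  expect_equal(dim(Q), c(6L, 6L))
  expect_true(all(rowSums(Q) > 0) && all(rowSums(Q) < 1))
  expect_equal(Q, entries(transitionMatrix(m, 10))[1:6, 1:6])

  # iid: identical rows, escape probability (1-p)^(U+1)
  Q0 <- substochasticBlock(GINARModel(0.63, 0), 5)
  expect_equal(unname(rowSums(Q0)), rep(1 - iidTheta(0.63, 5), 6))
})

test_that("run-length survival: basics, iid closed form, Monte Carlo", {
  m <- refModel()
  d <- rlDistribution(m, chartSpec(5, 0))
  s <- rlSurvival(d)
  expect_equal(s[1], 1)                       # P(RL > 0) = 1
  expect_true(all(diff(s) <= 0))
  expect_equal(rlPmf(d), -diff(s))
  expect_true(all(rlPmf(d) >= 0))
  expect_lt(s[length(s)], 1e-12)

  # rho = 0: RL is geometric, survival (1 - theta)^m exactly
  th <- iidTheta(0.63, 5)
  d0 <- rlDistribution(GINARModel(0.63, 0), chartSpec(5, 0))
  mm <- c(1, 5, 20, 100)
  expect_equal(rlSurvival(d0)[mm + 1], (1 - th)^mm, tolerance = 1e-12)

  # Monte-Carlo survival agrees within 3 binomial standard errors
  set.seed(51)
  rl <- mcRunLengths(m, 5, 0L, 2e4)
  for (mAt in c(10, 100, 400)) {
    phat <- mean(rl > mAt)
    pex <- rlSurvival(d)[mAt + 1]
    expect_lt(abs(phat - pex), 3 * sqrt(pex * (1 - pex) / 2e4) + 1e-12)
  }

  expect_error(rlDistribution(m, chartSpec(5, 0), eps = 0), "positive")
})

test_that("overall run-length law allows a signal at t = 1", {
  m <- refModel()
  d <- rlDistribution(m, chartSpec(5, "overall"))
  # P(RL = 1) = P(X1 > U) = (1-p)^(U+1)
  expect_equal(rlPmf(d)[1], iidTheta(0.63, 5), tolerance = 1e-12)
  expect_equal(rlSurvival(d)[1], 1)
  # ARL from the survival sum equals the linear-solve ARL
  expect_equal(sum(rlSurvival(d)), arl(m, chartSpec(5, "overall")),
               tolerance = 1e-6)
})

test_that("ARL: linear solve vs survival sum, iid closed form, Monte Carlo", {
  m <- refModel()
  for (init in list(0L, 5L, "overall")) {
    chart <- chartSpec(5, init)
    expect_equal(arl(m, chart), sum(rlSurvival(rlDistribution(m, chart))),
                 tolerance = 1e-6)
  }
  # iid closed form 1/theta for any fixed start
  m0 <- GINARModel(0.63, 0)
  th <- iidTheta(0.63, 5)
  expect_equal(arl(m0, chartSpec(5, 0)), 1 / th, tolerance = 1e-10)
  expect_equal(arl(m0, chartSpec(5, 3)), 1 / th, tolerance = 1e-10)
  # iid overall: signal at each t independently, same geometric law
  expect_equal(overallArl(m0, 5), 1 / th, tolerance = 1e-10)

  set.seed(61)
  rl <- mcRunLengths(m, 5, 0L, 2e4)
  expect_lt(abs(mean(rl) - arl(m, chartSpec(5, 0))),
            3 * sd(rl) / sqrt(2e4))
})

test_that("Perron root: iid rank-1 case, power-iteration cross-check,
           hazard convergence", {
  m <- refModel()
  Q <- substochasticBlock(m, 5)
  xi <- perronRoot(Q)
  expect_equal(perronRoot(Q, method = "power"), xi, tolerance = 1e-10)

  # rho = 0: rank-1 block, xi = 1 - (1-p)^(U+1)
  Q0 <- substochasticBlock(GINARModel(0.63, 0), 5)
  expect_equal(perronRoot(Q0), 1 - iidTheta(0.63, 5), tolerance = 1e-12)

  # hazards from both extreme starts converge to 1 - xi
  for (u in c(0L, 5L)) {
    h <- rlHazard(rlDistribution(m, chartSpec(5, u)))
    expect_lt(abs(h[2000] - (1 - xi)), 1e-6)
  }
  # geometric-like tail: pmf ratio converges to xi
  pm <- rlPmf(rlDistribution(m, chartSpec(5, 0)))
  expect_lt(abs(pm[2001] / pm[2000] - xi) / xi, 1e-6)
})

test_that("summary measures: iid closed forms and internal consistency", {
  # rho = 0: RL ~ geometric(theta) on {1,2,...}
  th <- iidTheta(0.63, 5)
  d0 <- rlDistribution(GINARModel(0.63, 0), chartSpec(5, 0))
  s0 <- rlSummary(d0, c(0.5, 0.9))
  expect_equal(s0@arl, 1 / th, tolerance = 1e-10)
  expect_equal(s0@sdrl, sqrt(1 - th) / th, tolerance = 1e-8)
  expect_equal(unname(s0@quantiles[["q50"]]),
               ceiling(log(0.5) / log(1 - th)))

  m <- refModel()
  d <- rlDistribution(m, chartSpec(5, 0))
  s <- rlSummary(d, 0.5)
  expect_equal(s@arl, arl(m, chartSpec(5, 0)), tolerance = 1e-6)
  expect_equal(s@limitingHazard, 1 - perronXi(d))
  # median: smallest m with exact survival below 0.5, by direct cumsum
  med <- which(cumsum(rlPmf(d)) >= 0.5)[1]
  expect_equal(unname(s@quantiles[["q50"]]), med)

  # overall summary consistency with direct pmf moments
  dov <- rlDistribution(m, chartSpec(5, "overall"))
  sov <- rlSummary(dov)
  mgrid <- seq_along(rlPmf(dov))
  expect_equal(sov@arl, sum(mgrid * rlPmf(dov)), tolerance = 1e-6)
  expect_equal(sov@sdrl,
               sqrt(sum(mgrid^2 * rlPmf(dov)) - sum(mgrid * rlPmf(dov))^2),
               tolerance = 1e-4)
  expect_error(rlSummary(d, 1.5), "percentiles")
})

test_that("hazard monotonicity, dominance and run-length orderings hold
           at the reference chart", {
  m <- refModel()
  d0 <- rlDistribution(m, chartSpec(5, 0))
  dU <- rlDistribution(m, chartSpec(5, 5))
  h0 <- rlHazard(d0); hU <- rlHazard(dU)
  expect_true(all(diff(h0) >= -1e-12))        # increasing hazard from u = 0
  expect_true(all(diff(hU) <= 1e-12))         # decreasing hazard from u = U
  n <- min(length(h0), length(hU))
  expect_true(all(hU[1:n] >= h0[1:n] - 1e-12))  # head start dominates

  expect_true(isPF2(rlPmf(d0))@holds)          # log-concave from u = 0
  # reversed (log-convex) inequality for the head-start run length
  pU <- rlPmf(dU); k <- length(pU)
  expect_true(all(pU[1:(k - 2)] * pU[3:k] - pU[2:(k - 1)]^2 >= -1e-12))

  # lr-ordering across all initial-state pairs (capped grid)
  G <- 1500
  pmfs <- lapply(0:5, function(u)
    rlPmf(rlDistribution(m, chartSpec(5, u)))[1:G])
  for (u in 0:4) for (up in (u + 1):5)
    expect_true(lrLE(pmfs[[up + 1]], pmfs[[u + 1]])@holds)
})

test_that("hazard monotonicity is reproduced across random parameters", {
  set.seed(71)
  for (k in 1:8) {
    # ranges keep the in-control ARL below ~4000 so horizons stay modest
    p <- runif(1, 0.25, 0.75); rho <- runif(1, 0, 0.85)
    U <- sample(2:5, 1)
    m <- GINARModel(p, rho)
    h0 <- rlHazard(rlDistribution(m, chartSpec(U, 0), eps = 1e-10))
    hU <- rlHazard(rlDistribution(m, chartSpec(U, U), eps = 1e-10))
    expect_true(all(diff(h0) >= -1e-12))
    expect_true(all(diff(hU) <= 1e-12))
  }
  # iid boundary: hazard exactly constant, IHR and DHR simultaneously
  h <- rlHazard(rlDistribution(GINARModel(0.5, 0), chartSpec(4, 0)))
  expect_lt(max(abs(h - h[1])), 1e-12)
})
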