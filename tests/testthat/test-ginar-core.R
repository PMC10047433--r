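test_that("model validity and derived moments behave", {
  m <- GINARModel(0.63, 0.165)
  expect_equal(geomParam(m), 0.63)
  expect_equal(thinParam(m), 0.165)
  expect_equal(marginalMean(m), 0.37 / 0.63)
  expect_equal(marginalVar(m), 0.37 / 0.63^2)
  expect_true(kalmykovDomain(m))
  expect_false(kalmykovDomain(GINARModel(0.10, 0.165)))

  # marginal mean strictly decreasing in p
  ps <- seq(0.05, 0.95, by = 0.05)
  means <- vapply(ps, function(p) marginalMean(GINARModel(p, 0.1)),
                  numeric(1))
  expect_true(all(diff(means) < 0))

  expect_error(GINARModel(0, 0.1), "p")
  expect_error(GINARModel(1, 0.1), "p")
  expect_error(GINARModel(0.5, 1), "rho")
  expect_error(GINARModel(0.5, -0.1), "rho")
  expect_s4_class(GINARModel(0.5, 0), "GINARModel")  # iid limit admitted
})

test_that("innovation pmf matches the product law and normalises", {
  m <- refModel()
  # frozen value: 0.63 * 0.835 + 0.165, direct arithmetic
  expect_equal(innovationPmf(0, m), 0.69105)
  # iid limit: plain geometric mass at 0
  expect_equal(innovationPmf(0, GINARModel(0.63, 0)), 0.63)
  expect_equal(innovationPmf(0:50, m), oracleInnovation(0:50, 0.63, 0.165))
  J <- 0:defaultTruncation(m)
  expect_equal(sum(innovationPmf(J, m)), 1, tolerance = 1e-12)
  expect_error(innovationPmf(-1, m), "non-negative")
})

test_that("transition probabilities equal the thinning convolution", {
  m <- refModel()
  # i = 0: thinning of nothing, row is the innovation law
  expect_equal(transitionProb(0, 0:20, m), innovationPmf(0:20, m))
  # frozen value: (1 - rho) * P(eps = 0) from the brute-force convolution
  expect_equal(transitionProb(1, 0, m), 0.835 * 0.69105, tolerance = 1e-12)
  # row normalisation
  J <- 0:300
  for (i in c(0L, 1L, 5L, 10L))
    expect_equal(sum(transitionProb(i, J, m)), 1, tolerance = 1e-10)
  expect_error(transitionProb(-1, 0, m), "non-negative")
})

test_that("closed form equals the oracle convolution on random parameters", {
  set.seed(101)
  for (k in 1:20) {
    p <- runif(1, 0.05, 0.95); rho <- runif(1, 0, 0.95)
    m <- GINARModel(p, rho)
    i <- sample(0:50, 1)
    jj <- sort(sample(0:50, 8))
    want <- vapply(jj, function(j) oracleTransition(i, j, p, rho),
                   numeric(1))
    expect_equal(transitionProb(i, jj, m), want, tolerance = 1e-12)
  }
})

test_that("truncated TPM: stationarity, tail mass, iid limit", {
  m <- refModel()
  tm <- transitionMatrix(m, n = 100)
  P <- entries(tm)
  expect_equal(dim(P), c(101L, 101L))
  expect_true(all(tailMass(tm) >= 0))
  expect_equal(P[1, ], transitionProb(0, 0:100, m), ignore_attr = TRUE)

  # geometric(p) is the left fixed vector, up to the truncated tail
  pi0 <- dgeom(0:100, 0.63)
  slack <- sum(pi0 * tailMass(tm)) + 1e-12
  expect_lt(max(abs(drop(pi0 %*% P) - pi0)), slack)

  # rho = 0: all rows identical and equal to the geometric pf
  tm0 <- transitionMatrix(GINARModel(0.63, 0), n = 30)
  P0 <- entries(tm0)
  expect_equal(P0, matrix(dgeom(0:30, 0.63), 31, 31, byrow = TRUE),
               ignore_attr = TRUE)

  # default truncation follows the marginal tail rule
  n <- defaultTruncation(m)
  expect_lt((1 - 0.63)^(n + 1), 1e-12)
  expect_gte((1 - 0.63)^n, 1e-12)
})

test_that("TPM CSV round-trips through writer and reader", {
  m <- refModel()
  tm <- transitionMatrix(m, 8)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTransitionMatrix(tm, path)
  back <- readTransitionMatrix(path, m)
  expect_equal(entries(back), entries(tm), tolerance = 1e-12)
  expect_equal(tailMass(back), tailMass(tm), tolerance = 1e-12)
})

test_that("binomial thinning has the right support and moments", {
  expect_identical(binomialThinning(0L, 0.7), 0L)
  expect_identical(binomialThinning(10L, 1), 10L)   # 1 o X = X
  expect_identical(binomialThinning(10L, 0), 0L)    # 0 o X = 0
  set.seed(5)
  draws <- binomialThinning(rep(20L, 1e5), 0.3)
  se <- sqrt(20 * 0.3 * 0.7 / 1e5)
  expect_lt(abs(mean(draws) - 6), 3 * se)
  expect_true(all(draws >= 0 & draws <= 20))
  expect_error(binomialThinning(5L, 1.2), "rho")
})

test_that("simulation reproduces marginal moments and autocorrelation", {
  m <- refModel()
  s <- simulateGINAR(m, 2e4, seed = 7)
  x <- counts(s)
  # AR(1)-inflated standard error of the mean
  seMean <- sqrt(marginalVar(m) * (1 + 0.165) / (1 - 0.165) / 2e4)
  expect_lt(abs(mean(x) - marginalMean(m)), 3 * seMean)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.165), 3 / sqrt(2e4))

  # rho = 0 is iid: lag-1 autocorrelation near zero
  s0 <- simulateGINAR(GINARModel(0.63, 0), 2e4, seed = 8)
  x0 <- counts(s0)
  expect_lt(abs(cor(x0[-1], x0[-length(x0)])), 3 / sqrt(2e4))

  # determinism and fixed start
  expect_identical(counts(simulateGINAR(m, 100, seed = 3)),
                   counts(simulateGINAR(m, 100, seed = 3)))
  expect_identical(counts(simulateGINAR(m, 10, init = 4, seed = 1))[1], 4L)
  expect_error(simulateGINAR(m, 0), "length")
})

test_that("moment estimators recover parameters and flag degenerate input", {
  # frozen: sample mean 0.5872 gives p-hat = 1 / 1.5872 = 0.63 (2 dp)
  x <- c(rep(0L, 5064), rep(1L, 4000), rep(2L, 936))  # mean exactly 0.5872
  expect_equal(mean(x), 0.5872)
  set.seed(99)
  est <- estimateParams(sample(x))  # shuffled; only p-hat is of interest
  expect_equal(round(geomParam(est), 2), 0.63)

  m <- refModel()
  est2 <- estimateParams(simulateGINAR(m, 1e5, seed = 11))
  expect_lt(abs(geomParam(est2) - 0.63), 0.01)
  expect_lt(abs(thinParam(est2) - 0.165), 3 / sqrt(1e5) * (1 + 1))

  expect_error(estimateParams(rep(0L, 100)), "mean")
  expect_error(estimateParams(rep(2L, 100)), "constant")
  expect_error(estimateParams(1:5), "10 observations")
})

test_that("count series I/O round-trips in both layouts", {
  s <- simulateGINAR(refModel(), 50, seed = 2)
  for (fmt in c("plain", "csv")) {
    path <- withr::local_tempfile(fileext = ".txt")
    writeCountSeries(s, path, format = fmt)
    back <- readCountSeries(path)
    expect_identical(counts(back), counts(s))
  }
  bad <- withr::local_tempfile()
  writeLines(c("1", "-2"), bad)
  expect_error(readCountSeries(bad), "non-negative")
})
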