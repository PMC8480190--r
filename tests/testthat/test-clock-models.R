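# Branch laws of the six clock models.

test_that("branch moments follow each model's mean/variance law", {
  expect_equal(branchMoments(clockModel("sc", 5), 2), list(mean = 10, variance = 10))
  expect_equal(branchMoments(clockModel("rc", 1, sigma2 = 2), 3),
               list(mean = 3, variance = 21))
  expect_equal(branchMoments(clockModel("arc", 1, omega = 2), 3),
               list(mean = 3, variance = 9))
  # omega = 0 reduces to the strict clock
  expect_equal(branchMoments(clockModel("carc", 1, omega = 0), 7),
               list(mean = 7, variance = 7))
  expect_error(branchMoments(clockModel("sc", 5), -1), "duration")
})

test_that("clock model construction validates its parameters", {
  expect_error(clockModel("rc", 1), "sigma2")
  expect_error(clockModel("arc", 1), "omega")
  expect_error(clockModel("sc", -1), "mu")
  expect_error(clockModel("arc", 1, omega = -2), "omega")
  expect_error(clockModel("sc", 1, sigma2 = 1), "sigma2")
  expect_identical(relaxation(clockModel("sc", 3)), 0)
  expect_identical(relaxation(clockModel("rc", 1, sigma2 = 4)), 4)
})

test_that("branch log-likelihoods match closed forms and oracles", {
  expect_equal(branchLogLik(clockModel("sc", 2), 1, 0), -2)
  # NegBin(1, 1/2) is geometric: P(0) = 1/2
  expect_equal(branchLogLik(clockModel("arc", 1, omega = 1), 1, 0), log(0.5))
  # k = 1, theta = 1 gives NegBin(1, 1/2) as well
  expect_equal(branchLogLik(clockModel("rc", 1, sigma2 = 1), 1, 0), log(0.5))
  # Gamma(shape 2, scale 1) density at 2: x e^-x
  expect_equal(branchLogLik(clockModel("csc", 1), 2, 2), log(2) - 2)
  # errors
  expect_error(branchLogLik(clockModel("sc", 1), 1, 1.5), "integral")
  expect_error(branchLogLik(clockModel("sc", 1), 1, -1), "x must be")
  expect_error(branchLogLik(clockModel("sc", 1), -1, 1), "duration")
})

test_that("discrete relaxed log-likelihood equals the gamma-Poisson mixture", {
  for (mu in c(0.5, 5)) for (omega in c(0.1, 1, 10)) for (l in c(0.1, 1, 10))
    for (x in c(0, 2, 7)) {
      oracle <- arcMixturePmf(mu, omega, l, x)
      got <- exp(branchLogLik(clockModel("arc", mu, omega = omega), l, x))
      expect_equal(got, oracle, tolerance = 1e-9)
    }
})

test_that("zero-duration branches carry a point mass at zero", {
  for (m in list(clockModel("sc", 2), clockModel("arc", 2, omega = 1),
                 clockModel("csc", 2), clockModel("carc", 2, omega = 3),
                 clockModel("rc", 2, sigma2 = 1),
                 clockModel("crc", 2, sigma2 = 1))) {
    expect_identical(branchLogLik(m, 0, 0), 0)
    expect_identical(branchLogLik(m, 0, 3), -Inf)
    expect_identical(sampleSubstitutions(m, 0), 0)
  }
})

test_that("relaxed continuous models reduce to the strict clock at zero relaxation", {
  grid <- expand.grid(l = c(0.1, 1, 10), x = c(0.01, 1, 5, 40))
  cs <- branchLogLik(clockModel("csc", 2), grid$l, grid$x)
  expect_equal(branchLogLik(clockModel("carc", 2, omega = 0), grid$l, grid$x), cs)
  expect_equal(branchLogLik(clockModel("crc", 2, sigma2 = 0), grid$l, grid$x), cs)
})

test_that("discrete pmfs sum to one and continuous densities integrate to one", {
  for (m in list(clockModel("sc", 3), clockModel("rc", 3, sigma2 = 2),
                 clockModel("arc", 3, omega = 2))) {
    p <- exp(branchLogLik(m, rep(2, 201), 0:200))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  for (m in list(clockModel("csc", 3), clockModel("crc", 3, sigma2 = 2),
                 clockModel("carc", 3, omega = 2))) {
    f <- function(x) exp(branchLogLik(m, rep(2, length(x)), x))
    expect_equal(integrate(f, 0, Inf, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
  }
})

test_that("per-branch rate sampler has the stated moments", {
  expect_identical(sampleRate(clockModel("sc", 3), 1, n = 5), rep(3, 5))
  set.seed(42)
  # arc: Gamma(mu*l/omega, omega/l), mean mu, variance mu*omega/l
  r <- sampleRate(clockModel("arc", 2, omega = 1), l = 4, n = 1e6)
  expect_equal(mean(r), 2, tolerance = 3 * sqrt(0.5 / 1e6) / 2)
  expect_equal(var(r), 0.5, tolerance = 0.01)
  # rc: Gamma(k, theta), independent of l
  r2 <- sampleRate(clockModel("rc", 1, sigma2 = 4), l = 99, n = 1e6)
  expect_equal(mean(r2), 1, tolerance = 3 * sqrt(4 / 1e6))
  expect_equal(var(r2), 4, tolerance = 0.15)
  expect_error(sampleRate(clockModel("arc", 1, omega = 1), l = 0), "undefined")
  expect_error(sampleRate(clockModel("carc", 1, omega = 1), l = 1),
               "not identically distributed")
})

test_that("sampled substitutions match the branch law", {
  set.seed(7)
  # geometric special case: P(x) = 2^-(x+1)
  x <- sampleSubstitutions(clockModel("arc", 1, omega = 1), rep(1, 1e6))
  for (k in 0:5) {
    p <- 2^-(k + 1)
    expect_equal(mean(x == k), p, tolerance = 4 * sqrt(p * (1 - p) / 1e6) / p)
  }
  # carc mean/variance
  y <- sampleSubstitutions(clockModel("carc", 5, omega = 2), rep(2, 1e6))
  expect_equal(mean(y), 10, tolerance = 3 * sqrt(30 / 1e6) / 10)
  expect_equal(var(y), 30, tolerance = 0.05)
  # every model: Monte-Carlo moments match branchMoments
  for (m in list(clockModel("sc", 2), clockModel("rc", 2, sigma2 = 1),
                 clockModel("arc", 2, omega = 1), clockModel("csc", 2),
                 clockModel("crc", 2, sigma2 = 1),
                 clockModel("carc", 2, omega = 1))) {
    z <- sampleSubstitutions(m, rep(1.5, 2e5))
    mm <- branchMoments(m, 1.5)
    expect_equal(mean(z), mm$mean,
                 tolerance = 3 * sqrt(mm$variance / 2e5) / mm$mean)
    expect_equal(var(z), mm$variance, tolerance = 0.1)
  }
})

test_that("additive models are exactly additive, classical relaxed models are not", {
  for (mu in c(0.5, 1, 5)) for (omega in c(0.1, 1, 10))
    for (l in list(c(0.01, 1), c(1, 10), c(0.5, 0.5))) {
      for (mod in c("arc", "carc")) {
        g <- additivityGap(clockModel(mod, mu, omega = omega), l[1], l[2])
        expect_lt(g$distance, 1e-10)
        expect_equal(g$varianceGap, 0)
      }
      gS <- additivityGap(clockModel("sc", mu), l[1], l[2])
      expect_lt(gS$distance, 1e-10)
      gC <- additivityGap(clockModel("csc", mu), l[1], l[2])
      expect_lt(gC$distance, 1e-10)
      for (mod in c("rc", "crc")) {
        g <- additivityGap(clockModel(mod, mu, sigma2 = omega), l[1], l[2])
        expect_equal(g$varianceGap, 2 * omega * l[1] * l[2])
      }
    }
  # the distribution gap for rc is real, not a numerical artifact
  expect_gt(additivityGap(clockModel("rc", 1, sigma2 = 1), 1, 1)$distance, 0.01)
  expect_gt(additivityGap(clockModel("crc", 1, sigma2 = 1), 1, 1)$distance, 0.01)
})
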