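# Bayesian dating MCMC: posterior evaluation, sampling, summaries,
# diagnostics, reversible jump.

test_that("log posterior matches its pieces and rejects invalid states", {
  fx <- quickStudy(2, 1, nTips = 12)
  data <- fx$substtree
  state <- list(dates = nodeDates(fx$timetree), mu = 5, relax = 2, alpha = 5)
  lp <- logPosterior(state, data, "arc")
  ll <- logPosterior(state, data, "arc", likelihoodOnly = TRUE)
  expect_true(is.finite(lp))
  # likelihood equals the sum of branch log-likelihoods
  phy <- data@tree
  l <- state$dates[phy$edge[, 2]] - state$dates[phy$edge[, 1]]
  expect_equal(ll, sum(branchLogLik(clockModel("arc", 5, omega = 2), l,
                                    branchSubstitutions(data))))
  # parent dated after child: -Inf, not an error
  bad <- state
  bad$dates[13] <- 2100
  expect_identical(logPosterior(bad, data, "arc"), -Inf)
  # single branch, strict clock, fixed dates: one Poisson term
  sb <- singleBranchData(x = 7, l = 10)
  st1 <- list(dates = c(2010, 2000, 2000), mu = 1.3, relax = 0, alpha = 1)
  expect_equal(logPosterior(st1, sb, "sc", treePrior = "uniform",
                            likelihoodOnly = TRUE),
               dpois(7, 13, log = TRUE))
})

test_that("compiled likelihood and prior agree with the plain-R evaluation", {
  fx <- quickStudy(1, 4, nTips = 15)
  tr <- runMcmc(fx$substtree, "arc", nIter = 2000, seed = 2)
  s <- traceSamples(tr, burnin = 0.8)
  ntip <- 15
  tipd <- tipDates(fx$substtree)[fx$substtree@tree$tip.label]
  for (i in seq_len(min(nrow(s), 10))) {
    state <- list(dates = c(unname(tipd), s[i, paste0("date_", 16:29)]),
                  mu = s[i, "mu"], relax = s[i, "relax"], alpha = s[i, "alpha"])
    full <- logPosterior(state, fx$substtree, "arc")
    expect_equal(unname(s[i, "treeLogLik"] + s[i, "logPrior"]), unname(full),
                 tolerance = 1e-8)
  }
  # the two coalescent prior implementations agree
  ds <- nodeDates(fx$timetree)
  expect_equal(arcdating:::.coalLogPriorCpp(ds[16:29], ds[1:15], 4.2),
               arcdating:::.coalLogPrior(ds[16:29], ds[1:15], 4.2),
               tolerance = 1e-10)
})

test_that("the chain is exactly reproducible and input checks fire", {
  fx <- quickStudy(1, 6, nTips = 10)
  t1 <- runMcmc(fx$substtree, "arc", nIter = 2000, seed = 9)
  t2 <- runMcmc(fx$substtree, "arc", nIter = 2000, seed = 9)
  expect_identical(t1@samples, t2@samples)
  expect_error(runMcmc(fx$substtree, "arc", nIter = 500), "burn-in floor")
  frac <- fx$substtree
  frac@tree$edge.length <- frac@tree$edge.length + 0.25
  expect_error(runMcmc(frac, "arc", nIter = 2000), "integral")
  same <- substTree(fx$substtree@tree,
                    setNames(rep(2020, 10), fx$substtree@tree$tip.label))
  expect_warning(runMcmc(same, "arc", nIter = 2000, seed = 1),
                 "unidentifiable")
})

test_that("prior-only runs return the prior on mu", {
  sb <- singleBranchData()
  tr <- runMcmc(sb, "sc", nIter = 3e4, seed = 2, treePrior = "uniform",
                priorOnly = TRUE, updateDates = FALSE,
                initDates = c(2010, 2000, 2000),
                priors = list(mu = c(shape = 2, scale = 0.5)))
  q <- quantile(traceSamples(tr)[, "mu"], c(0.25, 0.5, 0.75))
  expect_equal(unname(q), qgamma(c(0.25, 0.5, 0.75), 2, scale = 0.5),
               tolerance = 0.08)
})

test_that("single-branch strict-clock posterior matches the conjugate gamma", {
  sb <- singleBranchData(x = 25, l = 10)
  tr <- runMcmc(sb, "sc", nIter = 2e4, seed = 1, treePrior = "uniform",
                updateDates = FALSE, initDates = c(2010, 2000, 2000),
                priors = list(mu = c(shape = 2, scale = 0.5)))
  s <- traceSamples(tr)[, "mu"]
  shape <- 2 + 25; scale <- 0.5 / (1 + 0.5 * 10)
  expect_equal(unname(quantile(s, c(0.025, 0.5, 0.975))),
               qgamma(c(0.025, 0.5, 0.975), shape, scale = scale),
               tolerance = 0.12)
})

test_that("a zero-length split leaves the additive posterior unchanged, not rc", {
  # same data once as a 3-tip tree with a polytomy resolved by a zero-length
  # branch, once unresolved as a star
  star <- substTree(ape::read.tree(text = "(A:4,B:6,C:5);"),
                    c(A = 2010, B = 2011, C = 2012))
  res <- readDatedTree(writeNewick(star),
                       dates = data.frame(c("A", "B", "C"), c(2010, 2011, 2012)))
  expect_true(ape::is.binary(res@tree))
  dates <- c(2010, 2011, 2012, 2005, 2005)  # resolved node at the root date
  dStar <- c(2010, 2011, 2012, 2005)
  for (mod in c("arc", "carc")) {
    llS <- logPosterior(list(dates = dStar, mu = 2, relax = 1), star, mod,
                        treePrior = "uniform", likelihoodOnly = TRUE)
    llR <- logPosterior(list(dates = dates, mu = 2, relax = 1), res, mod,
                        treePrior = "uniform", likelihoodOnly = TRUE)
    expect_equal(llS, llR, tolerance = 1e-10)
  }
})

test_that("trace summaries behave on analytic inputs", {
  const <- matrix(c(rep(0, 200), rep(3.5, 200)), ncol = 2,
                  dimnames = list(NULL, c("treeLogLik", "mu")))
  tr <- new("PosteriorTrace", samples = const, thin = 1L, seed = 1L,
            model = "sc", settings = list(burnin = 0))
  s <- summarizeTrace(tr)
  expect_equal(s["mu", "mean"], 3.5)
  expect_equal(s["mu", "ciLength"], 0)
  set.seed(31)
  z <- matrix(c(rep(0, 2e4), rnorm(2e4)), ncol = 2,
              dimnames = list(NULL, c("treeLogLik", "mu")))
  trz <- new("PosteriorTrace", samples = z, thin = 1L, seed = 1L,
             model = "sc", settings = list(burnin = 0))
  sz <- summarizeTrace(trz)
  expect_equal(sz["mu", "lower"], -1.96, tolerance = 0.05)
  expect_equal(sz["mu", "upper"], 1.96, tolerance = 0.05)
  # thinning that preserves >= 1e3 samples leaves summaries stable
  thin <- z[seq(1, 2e4, by = 10), , drop = FALSE]
  trt <- new("PosteriorTrace", samples = thin, thin = 10L, seed = 1L,
             model = "sc", settings = list(burnin = 0))
  expect_equal(summarizeTrace(trt)["mu", "mean"], sz["mu", "mean"],
               tolerance = 0.1)
  expect_error(summarizeTrace(new("PosteriorTrace",
    samples = const, thin = 1L, seed = 1L, model = "sc",
    settings = list(burnin = 1))), "empty")
})

test_that("diagnostics recover analytic effective sizes and detect identity", {
  mkTrace <- function(v) new("PosteriorTrace",
    samples = cbind(treeLogLik = 0, mu = v), thin = 1L, seed = 1L,
    model = "sc", settings = list(burnin = 0))
  set.seed(41)
  iid <- rnorm(5000)
  d1 <- traceDiagnostics(mkTrace(iid))
  expect_equal(unname(d1$ess[["mu"]]), 5000, tolerance = 0.2)
  expect_null(d1$psrf)
  # AR(1) with rho = 0.9: ESS ~ n (1-rho)/(1+rho)
  n <- 2e4; rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  d2 <- traceDiagnostics(mkTrace(ar))
  expect_equal(unname(d2$ess[["mu"]]), n * (1 - rho) / (1 + rho),
               tolerance = 0.25)
  expect_true("mu" %in% traceDiagnostics(mkTrace(ar[1:900]))$flagged)
  # identical chains: split-Rhat = 1 up to O(1/sqrt(n))
  d3 <- traceDiagnostics(list(mkTrace(iid), mkTrace(iid)))
  expect_equal(unname(d3$psrf[["mu"]]), 1, tolerance = 0.01)
  expect_warning(traceDiagnostics(list(mkTrace(iid), mkTrace(iid[1:4000]))),
                 "unequal")
})

test_that("reversible jump prefers the generating continuous model", {
  favStrict <- favRelax <- logical(0)
  for (s in 1:6) {
    fxS <- quickStudy(0, 100 + s, nTips = 30, model = "csc")
    rj <- runRjMcmc(fxS$substtree, nIter = 4000, seed = s)
    favStrict <- c(favStrict, rj$bayesFactor > 1)
    ind <- traceSamples(rj$trace)[, "indicator"]
    expect_equal(mean(ind == 0) + mean(ind == 1), 1)
    fxR <- quickStudy(5, 200 + s, nTips = 30, model = "carc")
    rj2 <- runRjMcmc(fxR$substtree, nIter = 4000, seed = s)
    favRelax <- c(favRelax, rj2$bayesFactor < 1)
  }
  expect_gte(sum(favStrict), 4)   # majority favors the strict clock
  expect_gte(sum(favRelax), 4)    # majority favors relaxation
  expect_error(runRjMcmc(quickStudy(1, 1, nTips = 10)$substtree,
                         models = c("sc", "arc")), "continuous")
})
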