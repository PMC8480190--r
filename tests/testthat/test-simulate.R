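# Coalescent simulator, branch simulation, alignments, study fixture.

test_that("coalescent trees are valid dated binary trees", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(3:30, 1)
    sd <- runif(n, 2000, 2020)
    tt <- sampleCoalescentTree(samplingDates = sd, alpha = 5)
    expect_s4_class(tt, "TimeTree")
    expect_equal(tt@tree$Nnode, n - 1L)
    expect_true(ape::is.binary(tt@tree))
    expect_true(all(branchDurations(tt) >= 0))
    expect_equal(sort(unname(tipDates(tt))), sort(sd))
  }
})

test_that("coalescent TMRCA matches closed forms", {
  # reduced-replicate check; the full 1e5-replicate version runs in the
  # acceptance suite
  set.seed(11)
  d2 <- replicate(20000, 2020 - tmrca(
    sampleCoalescentTree(samplingDates = c(2020, 2020), alpha = 5)))
  expect_equal(mean(d2), 5, tolerance = 3 * sd(d2) / sqrt(2e4) / 5)
  d10 <- replicate(10000, -tmrca(
    sampleCoalescentTree(samplingDates = rep(0, 10), alpha = 5)))
  expect_equal(mean(d10), 2 * 5 * (1 - 1 / 10),
               tolerance = 3 * sd(d10) / sqrt(1e4) / 9)
})

test_that("simulated substitutions have the model's moments on a fixed tree", {
  tt <- tinyTimeTree()
  clock <- clockModel("arc", 5, omega = 2)
  set.seed(8)
  xs <- replicate(4000, unname(branchSubstitutions(
    simulateObservedTree(tt, clock))))
  l <- unname(branchDurations(tt))
  for (b in seq_along(l)) {
    mm <- branchMoments(clock, l[b])
    expect_equal(mean(xs[b, ]), mm$mean,
                 tolerance = 3 * sqrt(mm$variance / 4000) / mm$mean)
    expect_equal(var(xs[b, ]), mm$variance, tolerance = 0.15)
  }
  # strict clock: total substitutions average mu * total duration
  set.seed(9)
  tot <- replicate(4000, sum(branchSubstitutions(
    simulateObservedTree(tt, clockModel("sc", 5)))))
  expect_equal(mean(tot), 5 * sum(l), tolerance = 0.02)
})

test_that("branch simulation is reproducible given a seed", {
  tt <- tinyTimeTree()
  set.seed(4); a <- simulateObservedTree(tt, clockModel("arc", 5, omega = 1))
  set.seed(4); b <- simulateObservedTree(tt, clockModel("arc", 5, omega = 1))
  expect_identical(branchSubstitutions(a), branchSubstitutions(b))
})

test_that("splitting a branch does not change additive laws but breaks rc", {
  clock <- clockModel("arc", 5, omega = 2)
  set.seed(13)
  n <- 1e5
  split <- sampleSubstitutions(clock, rep(0.8, n)) +
    sampleSubstitutions(clock, rep(1.2, n))
  whole <- sampleSubstitutions(clock, rep(2, n))
  # two-sample chi-square on pooled bins
  breaks <- c(-0.5, seq(0.5, 30.5), Inf)
  tab <- rbind(table(cut(split, breaks)), table(cut(whole, breaks)))
  keep <- colSums(tab) >= 10
  expect_gt(suppressWarnings(chisq.test(tab[, keep]))$p.value, 1e-3)
  # rc: merged branch has variance excess 2*sigma2*l1*l2 = 16
  rc <- clockModel("rc", 5, sigma2 = 4)
  splitRc <- sampleSubstitutions(rc, rep(1, n)) + sampleSubstitutions(rc, rep(1, n))
  wholeRc <- sampleSubstitutions(rc, rep(2, n))
  gap <- var(wholeRc) - var(splitRc)
  se <- sqrt((var((wholeRc - mean(wholeRc))^2) +
              var((splitRc - mean(splitRc))^2)) / n)
  expect_equal(gap, 2 * 4 * 1 * 1, tolerance = 3 * se / 8)
  # and through the tree machinery, with a degree-2 node
  phyU <- ape::read.tree(text = "(A:2,B:1);")
  ttU <- timeTree(phyU, c(2002, 2001, 2000))
  phyS <- ape::read.tree(text = "((A:1.2):0.8,B:1);")
  ttS <- timeTree(phyS, c(2002, 2001, 2000, 2000.8))
  set.seed(14)
  xu <- replicate(3000, rootToTip(simulateObservedTree(ttU, clock))[["A"]])
  xsp <- replicate(3000, rootToTip(simulateObservedTree(ttS, clock))[["A"]])
  expect_equal(mean(xu), mean(xsp), tolerance = 3 * sqrt(2 * 30 / 3000) / 10)
  expect_equal(var(xu), var(xsp), tolerance = 0.2)
})

test_that("alignment simulation follows the Jukes-Cantor process", {
  tt <- tinyTimeTree()
  set.seed(21)
  # zero rate: everyone identical
  aln0 <- simulateAlignment(tt, clockModel("sc", 1e-12), 500)
  expect_true(all(aln0[1, ] == aln0[2, ]) && all(aln0[2, ] == aln0[3, ]))
  # two tips 10 years apart under a strict clock, 5 subs/genome/year:
  # expected per-site divergence on the path d = 100/L
  phy <- ape::read.tree(text = "(A:1,B:1);")
  t2 <- timeTree(phy, c(2010, 2010, 2000))
  L <- 10000
  set.seed(22)
  diffs <- replicate(30, {
    a <- simulateAlignment(t2, clockModel("sc", 5), L)
    mean(a[1, ] != a[2, ])
  })
  pExp <- 0.75 * (1 - exp(-4 * (100 / L) / 3))
  expect_equal(mean(diffs), pExp,
               tolerance = 3 * sd(diffs) / sqrt(30) / pExp)
  set.seed(23); a1 <- simulateAlignment(t2, clockModel("arc", 5, omega = 1), 100)
  set.seed(23); a2 <- simulateAlignment(t2, clockModel("arc", 5, omega = 1), 100)
  expect_identical(a1, a2)
})

test_that("the study fixture matches its declared design", {
  fx <- simulateStudy(omega = 0, seed = 3, nTips = 100)
  td <- tipDates(fx$substtree)
  expect_length(td, 100)
  expect_equal(min(td), 2010)
  expect_equal(max(td), 2020)
  expect_equal(unname(diff(sort(td))), rep(10 / 99, 99), tolerance = 1e-9)
  expect_true(all(branchSubstitutions(fx$substtree) ==
                  round(branchSubstitutions(fx$substtree))))
  expect_identical(fx$config@alpha, 5)
  expect_identical(clockRate(fx$config@clock), 5)
  fx2 <- simulateStudy(omega = 0, seed = 3, nTips = 100)
  expect_identical(branchSubstitutions(fx$substtree),
                   branchSubstitutions(fx2$substtree))
  expect_identical(nodeDates(fx$timetree), nodeDates(fx2$timetree))
})
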