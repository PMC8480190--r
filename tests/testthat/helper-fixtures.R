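# Shared fixtures, built in code.

# Independent oracle for the discrete additive relaxed clock pmf: numerical
# integration of the gamma rate law mixed into a Poisson.
# Integrating in probability space (m = Q(p)) keeps the integrand bounded
# even when the gamma shape is far below one.
arcMixturePmf <- function(mu, omega, l, x) {
  shape <- mu * l / omega
  scale <- omega / l
  # primary: quadrature in probability space, m = Q(p); bounded smooth
  # integrand even for shapes far below 1
  v <- tryCatch(
    integrate(function(p)
        dpois(x, qgamma(p, shape = shape, scale = scale) * l),
      lower = 0, upper = 1, rel.tol = 1e-12, abs.tol = 0,
      subdivisions = 2000L)$value,
    error = function(e) NA_real_)
  if (!is.na(v)) return(v)
  # fallback for far-tail spikes: log-stabilised composite Simpson over
  # log(m) on the window where the integrand is within e^-80 of its peak
  lf <- function(m) dgamma(m, shape = shape, scale = scale, log = TRUE) +
    dpois(x, m * l, log = TRUE)
  lo <- min(qgamma(1e-14, shape = shape, scale = scale),
            if (x > 0) 0.01 * x / l else Inf)
  hi <- max(qgamma(1e-14, shape = shape, scale = scale, lower.tail = FALSE),
            (x + 30 + 10 * sqrt(x)) / l)
  tg <- seq(log(max(lo, 1e-14)), log(hi), length.out = 4001)
  lv <- lf(exp(tg)) + tg            # d m = e^t d t
  K <- max(lv)
  win <- range(tg[lv > K - 80])
  n <- 65536L
  t2 <- seq(win[1], win[2], length.out = n + 1L)
  y <- exp(lf(exp(t2)) + t2 - K)
  h <- t2[2] - t2[1]
  exp(K) * h / 3 * (y[1] + y[n + 1L] + 4 * sum(y[seq(2, n, 2)]) +
                    2 * sum(y[seq(3, n - 1, 2)]))
}

# A tiny hand-built dated three-tip tree:
# root (n+1) at 2000, internal (n+2) at 2005, tips A 2010, B 2020 under the
# internal node, C 2015 off the root.
tinyTimeTree <- function() {
  phy <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  dates <- numeric(5)
  dates[match(c("A", "B", "C"), phy$tip.label)] <- c(2010, 2020, 2015)
  dates[4] <- 2000; dates[5] <- 2005
  timeTree(phy, dates)
}

# Single-informative-branch tree: tip A 10 years from the (fixed) root, tip
# B on a zero-length branch carrying zero substitutions, so the likelihood
# reduces to one Poisson term and the mu posterior is conjugate.
singleBranchData <- function(x = 25, l = 10) {
  phy <- ape::read.tree(text = sprintf("(A:%d,B:0);", x))
  substTree(phy, c(A = 2000 + l, B = 2000))
}

quickStudy <- function(omega, seed, nTips = 40, ...) {
  simulateStudy(omega = omega, seed = seed, nTips = nTips, ...)
}
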