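# Closed-form branch laws for the six clock models.
#
# All gamma distributions are shape-scale. The negative binomial NegBin(r, p)
# has pmf C(x+r-1, x) p^x (1-p)^r with mean r p/(1-p); R's dnbinom() uses the
# complementary probability, so prob = 1 - p everywhere below. Under this
# convention the additive relaxed clock law NegBin(mu*l/omega, omega/(1+omega))
# has mean mu*l and variance mu*l*(1+omega).

# Single funnel for shape-scale gamma parameters of each continuous model /
# rate law, to avoid rate-vs-scale mix-ups.
.gammaShapeScale <- function(model, mu, sigma2, omega, l) {
  switch(model,
    csc = list(shape = mu * l, scale = 1),
    crc = list(shape = mu^2 * l / (mu + sigma2 * l),
               scale = 1 + sigma2 * l / mu),
    carc = list(shape = mu * l / (1 + omega), scale = 1 + omega),
    stop("no gamma branch law for model '", model, "'"))
}

# Rate-law gamma parameters (shape-scale) for the relaxed models.
.rateShapeScale <- function(clock, l) {
  switch(clock@model,
    rc = , crc = list(shape = clock@mu^2 / clock@sigma2,
                      scale = clock@sigma2 / clock@mu),
    arc = list(shape = clock@mu * l / clock@omega,
               scale = clock@omega / l),
    stop("no per-branch rate law for model '", clock@model, "'"))
}

.checkDuration <- function(l) {
  if (any(!is.finite(l)) || any(l < 0))
    stop("branch duration l must be finite and >= 0")
}

# Floor applied to continuous observations at zero before likelihood
# evaluation (gamma densities with shape < 1 diverge at 0).
.CONT_EPS <- 1e-9

# Below this relaxation the negative binomial is evaluated as its Poisson
# limit: the same switch point is used by the compiled sampler, and the
# stable log pmf below would need r = mu*l/omega beyond lgamma's range.
.RELAX_EPS <- 1e-10

# NegBin(r, p) log pmf, parametrised by log(p) and log(1-p) so that p can sit
# within double rounding of 0 or 1 (omega near 0 or very large) without
# catastrophic cancellation; stats::dnbinom takes prob = 1 - p directly and
# loses the branch likelihood entirely once 1 - p rounds to 1.
# the binomial coefficient is evaluated as -log(x+r) - lbeta(x+1, r), which
# stays accurate when r is huge (lgamma(x+r) - lgamma(r) cancels badly)
.nbinomLogPmf <- function(x, r, logP, log1mP) {
  -log(x + r) - lbeta(x + 1, r) + x * logP + r * log1mP
}

#' Mean and variance of the substitution count on a branch
#'
#' Returns \eqn{E(x_i)} and \eqn{V(x_i)} for a branch of duration \code{l}
#' years: strict clocks give \eqn{(\mu l, \mu l)}, the classical relaxed
#' clock \eqn{(\mu l, \mu l + \sigma^2 l^2)}, and the additive relaxed clock
#' \eqn{(\mu l, \mu l (1+\omega))}.
#'
#' @param clock a [ClockModel-class].
#' @param l branch duration in years (vectorised, all >= 0).
#' @return A list with numeric components \code{mean} and \code{variance}.
#' @examples
#' branchMoments(clockModel("arc", mu = 1, omega = 2), l = 3)
#' @export
branchMoments <- function(clock, l) {
  stopifnot(is(clock, "ClockModel"))
  .checkDuration(l)
  m <- clock@mu * l
  v <- switch(clock@model,
    sc = , csc = m,
    rc = , crc = m + clock@sigma2 * l^2,
    arc = , carc = m * (1 + clock@omega))
  list(mean = m, variance = v)
}

#' Log-likelihood of an observed branch under a clock model
#'
#' Evaluates the log pmf (discrete models: Poisson for sc, negative binomial
#' for rc and arc) or log pdf (continuous models: gamma) of observing \code{x}
#' substitutions on a branch of duration \code{l} years. Vectorised over
#' \code{l} and \code{x} in parallel. A zero-duration branch is a point mass
#' at zero under every model. For continuous models, observations below
#' \code{1e-9} are floored at \code{1e-9} (gamma densities with shape < 1
#' diverge at the origin); a warning is issued once per call.
#'
#' @inheritParams branchMoments
#' @param x observed substitutions: non-negative integers for discrete
#'   models, non-negative reals for continuous models.
#' @return Numeric vector of log-probabilities (log-densities).
#' @examples
#' branchLogLik(clockModel("sc", mu = 2), l = 1, x = 0)   # -2
#' branchLogLik(clockModel("arc", mu = 1, omega = 1), l = 1, x = 0)  # log(1/2)
#' @export
branchLogLik <- function(clock, l, x) {
  stopifnot(is(clock, "ClockModel"))
  .checkDuration(l)
  if (any(!is.finite(x)) || any(x < 0))
    stop("substitution count x must be finite and >= 0")
  n <- max(length(l), length(x))
  l <- rep_len(l, n); x <- rep_len(x, n)
  mod <- clock@model
  if (isDiscrete(clock)) {
    if (any(abs(x - round(x)) > 1e-8))
      stop("x must be integral for discrete model '", mod, "'")
    x <- round(x)
  } else if (any(x < .CONT_EPS)) {
    if (any(l > 0 & x < .CONT_EPS))
      warning("continuous branch lengths below ", .CONT_EPS,
              " floored before likelihood evaluation")
    x <- pmax(x, .CONT_EPS)
  }
  out <- numeric(n)
  zero <- l == 0
  if (any(zero)) # point mass at 0 (continuous: up to the floor)
    out[zero] <- ifelse(x[zero] <= .CONT_EPS, 0, -Inf)
  if (all(zero)) return(out)
  l1 <- l[!zero]; x1 <- x[!zero]
  mu <- clock@mu
  ll <- switch(mod,
    sc = dpois(x1, mu * l1, log = TRUE),
    rc = {
      if (clock@sigma2 < .RELAX_EPS) dpois(x1, mu * l1, log = TRUE)
      else {
        theta <- clock@sigma2 / mu
        # NegBin(k, theta*l/(1+theta*l))
        .nbinomLogPmf(x1, mu^2 / clock@sigma2,
                      log(theta * l1) - log1p(theta * l1),
                      -log1p(theta * l1))
      }
    },
    arc = {
      if (clock@omega < .RELAX_EPS) dpois(x1, mu * l1, log = TRUE)
      else .nbinomLogPmf(x1, mu * l1 / clock@omega,
                         log(clock@omega) - log1p(clock@omega),
                         -log1p(clock@omega))
    },
    {
      p <- .gammaShapeScale(mod, mu, clock@sigma2, clock@omega, l1)
      dgamma(x1, shape = p$shape, scale = p$scale, log = TRUE)
    })
  out[!zero] <- ll
  out
}

#' Sample a per-branch substitution rate
#'
#' Draws the latent per-branch rate \eqn{m_i}: strict clocks return \code{mu}
#' deterministically; the classical relaxed clock draws
#' Gamma(\eqn{\mu^2/\sigma^2}, \eqn{\sigma^2/\mu}) independently of the branch
#' duration; the discrete additive relaxed clock draws
#' Gamma(\eqn{\mu l/\omega}, \eqn{\omega/l}), whose variance
#' \eqn{\mu\omega/l} shrinks with branch duration. The continuous additive
#' clock specifies the branch law directly and has no per-branch rate sampler.
#'
#' @inheritParams branchMoments
#' @param l branch duration in years; must be > 0 for the arc model.
#' @param n number of draws.
#' @return Numeric vector of \code{n} rates (substitutions/genome/year).
#' @export
sampleRate <- function(clock, l, n = 1) {
  stopifnot(is(clock, "ClockModel"))
  mod <- clock@model
  if (mod %in% c("sc", "csc")) return(rep(clock@mu, n))
  if (mod == "carc")
    stop("the carc model specifies branch lengths directly; its implied ",
         "per-branch rates are not identically distributed and no rate ",
         "sampler is defined")
  if (mod == "arc" && (!is.finite(l) || l <= 0))
    stop("arc per-branch rate is undefined for l = 0 (variance mu*omega/l)")
  p <- .rateShapeScale(clock, l)
  rgamma(n, shape = p$shape, scale = p$scale)
}

#' Sample substitution counts on branches
#'
#' Draws \eqn{x_i} from the branch law of the model: Poisson, negative
#' binomial, or gamma. Vectorised over \code{l}. Zero-duration branches
#' return exactly 0.
#'
#' @inheritParams branchMoments
#' @return Numeric vector of substitutions, one per element of \code{l}
#'   (integral for discrete models).
#' @export
sampleSubstitutions <- function(clock, l) {
  stopifnot(is(clock, "ClockModel"))
  .checkDuration(l)
  n <- length(l)
  out <- numeric(n)
  pos <- l > 0
  if (!any(pos)) return(out)
  lp <- l[pos]
  mu <- clock@mu
  out[pos] <- switch(clock@model,
    sc = rpois(sum(pos), mu * lp),
    rc = {
      if (clock@sigma2 < .RELAX_EPS) rpois(sum(pos), mu * lp)
      else {
        theta <- clock@sigma2 / mu
        rnbinom(sum(pos), size = mu^2 / clock@sigma2,
                prob = 1 / (1 + theta * lp))
      }
    },
    arc = {
      if (clock@omega < .RELAX_EPS) rpois(sum(pos), mu * lp)
      else rnbinom(sum(pos), size = mu * lp / clock@omega,
                   prob = 1 / (1 + clock@omega))
    },
    {
      p <- .gammaShapeScale(clock@model, mu, clock@sigma2, clock@omega, lp)
      rgamma(sum(pos), shape = p$shape, scale = p$scale)
    })
  out
}

# Truncation point covering all but < 1e-14 of a discrete branch law's mass.
.discreteSupport <- function(clock, l) {
  mu <- clock@mu
  q <- switch(clock@model,
    sc = qpois(1e-14, mu * l, lower.tail = FALSE),
    rc = {
      theta <- clock@sigma2 / mu
      qnbinom(1e-14, size = mu^2 / clock@sigma2,
              prob = 1 / (1 + theta * l), lower.tail = FALSE)
    },
    arc = qnbinom(1e-14, size = mu * l / clock@omega,
                  prob = 1 / (1 + clock@omega), lower.tail = FALSE))
  as.integer(q) + 2L
}

.discretePmf <- function(clock, l, xmax) {
  exp(branchLogLik(clock, rep(l, xmax + 1L), 0:xmax))
}

# CDF of x1 + x2 for two independent continuous branch laws. Quadrature is
# done in probability space, P(S <= t) = int_0^{F1(t)} F2(t - Q1(p)) dp,
# which keeps the integrand bounded and smooth even when a gamma shape is
# far below 1 and the density diverges at the origin.
.contSumCdf <- function(clock, l1, l2, t) {
  p1 <- .gammaShapeScale(clock@model, clock@mu, clock@sigma2, clock@omega, l1)
  p2 <- .gammaShapeScale(clock@model, clock@mu, clock@sigma2, clock@omega, l2)
  if (p2$shape > p1$shape) { tmp <- p1; p1 <- p2; p2 <- tmp }
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    upper <- pgamma(tt, shape = p1$shape, scale = p1$scale)
    if (upper == 0) return(0)
    f <- function(p)
      pgamma(tt - pmin(qgamma(p, shape = p1$shape, scale = p1$scale), tt),
             shape = p2$shape, scale = p2$scale)
    quad <- function(lo, hi) tryCatch(
      integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-14,
                subdivisions = 1000L)$value,
      error = function(e) NA_real_)
    # piecewise, concentrating near the upper endpoint where the inner
    # argument approaches zero and the integrand can be nearly a step
    cuts <- upper * c(0, 0.5, 0.9, 0.99, 0.999, 0.9999, 1)
    sum(vapply(seq_len(length(cuts) - 1L), function(i) {
      vi <- quad(cuts[i], cuts[i + 1L])
      if (is.na(vi)) { # last resort: Simpson on a fine fixed grid
        g <- seq(cuts[i], cuts[i + 1L], length.out = 2001L)
        h <- g[2] - g[1]
        y <- f(g)
        vi <- h / 3 * (y[1] + y[2001] + 4 * sum(y[seq(2, 2000, 2)]) +
                       2 * sum(y[seq(3, 1999, 2)]))
      }
      vi
    }, numeric(1)))
  }, numeric(1))
}

#' Additivity gap between split and merged branches
#'
#' Quantifies how far the law of \eqn{x_1 + x_2} on two abutting branches of
#' durations \code{l1} and \code{l2} is from the law of \eqn{x} on a single
#' branch of duration \code{l1 + l2}. For the strict and additive models the
#' two laws coincide (infinite divisibility); for the classical relaxed clock
#' they differ, with a variance excess of exactly
#' \eqn{2\sigma^2 l_1 l_2} on the merged branch.
#'
#' The distributional distance is total variation, computed by exact
#' truncated convolution for discrete models and as the sup of the CDF
#' difference over a quantile grid (quadrature convolution) for continuous
#' models. The variance gap is computed from [branchMoments()].
#'
#' @inheritParams branchMoments
#' @param l1,l2 durations of the two abutting branches (> 0).
#' @return List with \code{distance} (total-variation distance) and
#'   \code{varianceGap} (\eqn{V(x) - V(x_1) - V(x_2)}).
#' @examples
#' additivityGap(clockModel("arc", mu = 1, omega = 1), 1, 2)$distance  # ~0
#' additivityGap(clockModel("rc", mu = 1, sigma2 = 1), 1, 1)$varianceGap  # 2
#' @export
additivityGap <- function(clock, l1, l2) {
  stopifnot(is(clock, "ClockModel"), l1 > 0, l2 > 0)
  vGap <- branchMoments(clock, l1 + l2)$variance -
    branchMoments(clock, l1)$variance - branchMoments(clock, l2)$variance
  if (isDiscrete(clock)) {
    xmax <- .discreteSupport(clock, l1 + l2)
    pmfSum <- .discretePmf(clock, l1 + l2, xmax)
    c1 <- .discretePmf(clock, l1, xmax)
    c2 <- .discretePmf(clock, l2, xmax)
    conv <- convolve(c1, rev(c2), type = "open")[seq_len(xmax + 1L)]
    tail <- max(0, 1 - sum(pmfSum)) + max(0, 1 - sum(conv))
    dist <- 0.5 * (sum(abs(conv - pmfSum)) + tail)
  } else {
    pS <- .gammaShapeScale(clock@model, clock@mu, clock@sigma2, clock@omega,
                           l1 + l2)
    qs <- qgamma(seq(0.005, 0.995, length.out = 60),
                 shape = pS$shape, scale = pS$scale)
    qs <- unique(qs[qs > 0])
    cdfSum <- pgamma(qs, shape = pS$shape, scale = pS$scale)
    cdfConv <- .contSumCdf(clock, l1, l2, qs)
    dist <- max(abs(cdfConv - cdfSum))
  }
  list(distance = dist, varianceGap = vGap)
}
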