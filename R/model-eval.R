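# Model comparison (DIC) and temporal-signal utilities.

#' Deviance information criterion of a dating run
#'
#' \eqn{D(\theta) = -2 \log L(\theta)}; \eqn{\bar D} is the posterior mean
#' deviance over the trace and \eqn{p_D = \mathrm{Var}(D)/2} the
#' effective number of parameters (the half-variance estimator), giving
#' DIC \eqn{= \bar D + p_D}. Smaller is better.
#'
#' The half-variance form is used rather than the plug-in
#' \eqn{\bar D - D(\bar\theta)}: with ~100 node-date parameters the plug-in
#' state of a heavily relaxed clock sits on a likelihood ridge that is almost
#' flat in the dates, which biases its \eqn{p_D} towards zero and can invert
#' comparisons between clock models of equal dimension.
#'
#' @param trace a [PosteriorTrace-class] from [runMcmc()].
#' @param data the [SubstTree-class] the run used.
#' @param model clock model family (default: the trace's model).
#' @param burnin burn-in fraction (default: the run's stored setting).
#' @return List with \code{DIC}, \code{pD}, and \code{Dbar}.
#' @export
dic <- function(trace, data, model = NULL, burnin = NULL) {
  stopifnot(is(trace, "PosteriorTrace"), is(data, "SubstTree"))
  if (is.null(model)) model <- trace@model
  if (!model %in% names(.MODEL_CODE))
    stop("trace/model mismatch: '", model, "' is not a single clock model")
  s <- traceSamples(trace, burnin)
  phy <- data@tree
  ntip <- length(phy$tip.label)
  dcols <- paste0("date_", (ntip + 1L):(ntip + phy$Nnode))
  if (!all(dcols %in% colnames(s)))
    stop("trace/model mismatch: trace does not cover this tree's nodes")
  devs <- -2 * s[, "treeLogLik"]
  Dbar <- mean(devs)
  pD <- if (length(devs) > 1L) var(devs) / 2 else 0
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Fit and compare clock models by DIC
#'
#' Runs the dating MCMC once per requested model on the same data and
#' tabulates DIC; the preferred model minimises DIC.
#'
#' @param data a [SubstTree-class].
#' @param models character vector of clock model families.
#' @param ... passed to [runMcmc()] (\code{nIter}, \code{seed}, priors, ...).
#' @return A data.frame (one row per model) with columns \code{model},
#'   \code{DIC}, \code{pD}, \code{preferred}; the traces are attached as
#'   \code{attr(, "traces")}.
#' @export
compareModels <- function(data, models = c("arc", "rc"), ...) {
  traces <- lapply(models, function(m) runMcmc(data, model = m, ...))
  names(traces) <- models
  tab <- do.call(rbind, lapply(models, function(m) {
    d <- dic(traces[[m]], data, model = m)
    data.frame(model = m, DIC = d$DIC, pD = d$pD)
  }))
  tab$preferred <- tab$DIC == min(tab$DIC)
  attr(tab, "traces") <- traces
  tab
}

#' Date-randomization test of temporal signal
#'
#' Re-runs the dating analysis \code{nRand} times with the tip sampling
#' dates permuted uniformly at random (without replacement) among the tips,
#' and compares the 95\% credible interval of the mean rate \code{mu} on the
#' real dates against the randomized intervals. Temporal signal is declared
#' significant when the original interval overlaps none of the randomized
#' intervals.
#'
#' @param data a [SubstTree-class].
#' @param model clock model family for the runs.
#' @param nRand number of randomizations (>= 10).
#' @param seed integer seed governing both the permutations and the MCMC.
#' @param nIter,... passed to [runMcmc()].
#' @return List with \code{significant} (logical), \code{original}
#'   (\code{c(lower, upper)} for \code{mu}), and \code{table} (one row per
#'   randomization: seed, interval, overlap flag).
#' @export
dateRandomizationTest <- function(data, model = "arc", nRand = 100,
                                  seed = 1L, nIter = 1e4, ...) {
  stopifnot(is(data, "SubstTree"))
  if (nRand < 10) stop("nRand must be >= 10")
  td <- data@tipDates
  if (length(unique(td)) < 3)
    stop("need at least 3 distinct tip dates to randomize")
  tr0 <- runMcmc(data, model = model, nIter = nIter, seed = seed, ...)
  s0 <- summarizeTrace(tr0)["mu", ]
  orig <- c(lower = s0$lower, upper = s0$upper)
  set.seed(seed)
  perms <- lapply(seq_len(nRand), function(i) sample(unname(td)))
  rows <- lapply(seq_len(nRand), function(i) {
    d2 <- data
    d2@tipDates <- setNames(perms[[i]], names(td))
    tri <- runMcmc(d2, model = model, nIter = nIter, seed = seed + i, ...)
    si <- summarizeTrace(tri)["mu", ]
    overlap <- si$lower <= orig[["upper"]] && si$upper >= orig[["lower"]]
    data.frame(rep = i, seed = seed + i, lower = si$lower, upper = si$upper,
               overlap = overlap)
  })
  tab <- do.call(rbind, rows)
  list(significant = !any(tab$overlap), original = orig, table = tab)
}

#' Root-to-tip regression
#'
#' Ordinary least squares of root-to-tip substitution distance on tip
#' sampling date. Under a strict clock the slope estimates the substitution
#' rate (per genome or per site per year, matching the tree's units).
#'
#' @param data a [SubstTree-class] with >= 3 tips and >= 2 distinct dates.
#' @return List with \code{slope}, \code{intercept}, \code{r.squared}, and
#'   the underlying \code{lm} fit.
#' @export
rttRegression <- function(data) {
  stopifnot(is(data, "SubstTree"))
  d <- rootToTip(data)
  dates <- data@tipDates[names(d)]
  if (length(d) < 3) stop("need at least 3 tips")
  if (length(unique(dates)) < 2) stop("tip dates are degenerate (all equal)")
  fit <- lm(d ~ dates)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = summary(fit)$r.squared, fit = fit)
}
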