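# Bayesian MCMC dating of a fixed rooted topology with tip dates.

.MODEL_CODE <- c(sc = 0L, rc = 1L, arc = 2L, csc = 3L, crc = 4L, carc = 5L)

# Default relaxation priors differ by family: omega is a dimensionless
# variance-inflation factor and takes the conservative Gamma(0.1, 1) (mean
# and variance 0.1); sigma2 is a squared rate whose data-relevant scale
# (around mu * omega / lbar, i.e. tens for epidemic-scale trees) lies far
# outside that prior's mass, so it defaults to an improper flat prior on
# (0, Inf) — encoded as NA shape/scale — and the likelihood alone drives
# the relaxation.
.defaultPriors <- function(model = "arc") {
  list(mu = c(shape = 0.001, scale = 1000),   # vague, mean 1
       relax = if (model %in% c("rc", "crc")) c(shape = NA_real_, scale = NA_real_)
               else c(shape = 0.1, scale = 1),
       alphaMean = 10)                        # Exp hyperprior on alpha
}

.mergePriors <- function(priors, model = "arc") {
  d <- .defaultPriors(model)
  if (is.null(priors)) return(d)
  for (nm in names(priors)) d[[nm]] <- priors[[nm]]
  d
}

# Heuristic initial state: rate from root-to-tip regression (clipped), node
# dates from a post-order pass placing each parent just before its children.
.initState <- function(data, model) {
  phy <- data@tree
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  slope <- tryCatch(rttRegression(data)$slope, error = function(e) NA_real_)
  mu0 <- if (is.finite(slope) && slope > 1e-3) slope else
    max(sum(phy$edge.length) / max(diff(range(data@tipDates)), 1) / ntip, 0.5)
  dates <- rep(Inf, nnode)
  dates[seq_len(ntip)] <- data@tipDates[phy$tip.label]
  po <- ape::reorder.phylo(phy, "postorder")
  xe <- po$edge.length
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    dates[p] <- min(dates[p], dates[ch] - max(xe[e] / mu0, 0.01))
  }
  list(dates = dates, mu = mu0)
}

#' Run the dating MCMC
#'
#' Metropolis-Hastings sampling of internal-node dates, the mean rate
#' \code{mu}, the relaxation parameter (\code{omega} or \code{sigma2}), and
#' the coalescent parameter \code{alpha}, on a fixed rooted topology with
#' known tip dates. Moves: a uniform-window proposal for each internal node
#' date, multiplicative scale moves for \code{mu}, the relaxation parameter
#' and \code{alpha}; proposal widths adapt during the first 20\% of
#' iterations (targeting ~25\% acceptance) and are then frozen.
#'
#' Default priors: \code{mu} ~ Gamma(0.001, 1000) (shape-scale; vague);
#' \code{omega} ~ Gamma(0.1, 1) (conservative: mean and variance 0.1);
#' \code{sigma2} ~ flat (improper, on \eqn{(0, \infty)}: sigma2 is a squared
#' rate whose data-relevant scale is far above the omega prior's mass, and
#' is left to the likelihood; supply \code{priors = list(relax = c(shape,
#' scale))} for a proper gamma prior instead); and under the
#' coalescent tree prior \code{alpha} ~ Exponential(mean 10). The tree prior
#' is either the constant-size heterochronous coalescent (default) or
#' uniform on date configurations satisfying the parent-before-child
#' constraint.
#'
#' @param data a [SubstTree-class] (branch lengths integral, in per-genome
#'   units, for discrete models; see [toGenomeUnits()]).
#' @param model clock model family: \code{"sc"}, \code{"rc"}, \code{"arc"},
#'   \code{"csc"}, \code{"crc"} or \code{"carc"}.
#' @param nIter number of iterations (>= 1000).
#' @param thin thinning interval (default: about 2000 recorded samples).
#' @param seed integer RNG seed; the run is exactly reproducible given
#'   (seed, nIter, thin).
#' @param priors list overriding the defaults: \code{mu = c(shape, scale)},
#'   \code{relax = c(shape, scale)}, \code{alphaMean}.
#' @param treePrior \code{"coalescent"} or \code{"uniform"}.
#' @param burnin fraction discarded by downstream summaries (default 0.5).
#' @param updateDates set \code{FALSE} to keep node dates fixed at their
#'   initial values (e.g. likelihood checks on a known tree).
#' @param priorOnly set \code{TRUE} to ignore the data and sample from the
#'   prior (the likelihood is treated as constant).
#' @param initDates optional full node-date vector to start from.
#' @return A [PosteriorTrace-class].
#' @seealso [summarizeTrace()], [traceDiagnostics()], [dic()], [runRjMcmc()]
#' @export
runMcmc <- function(data, model = "arc", nIter = 1e5,
                    thin = max(1L, nIter %/% 2000L), seed = 1L,
                    priors = NULL, treePrior = c("coalescent", "uniform"),
                    burnin = 0.5, updateDates = TRUE, priorOnly = FALSE,
                    initDates = NULL) {
  stopifnot(is(data, "SubstTree"))
  model <- match.arg(tolower(model), names(.MODEL_CODE))
  treePrior <- match.arg(treePrior)
  if (nIter < 1000) stop("nIter below the burn-in floor (1000)")
  pr <- .mergePriors(priors, model)
  phy <- data@tree
  x <- phy$edge.length
  discrete <- model %in% c("sc", "rc", "arc")
  if (discrete) {
    if (data@units != "per-genome")
      stop("discrete models need per-genome substitution counts; ",
           "convert with toGenomeUnits(rounding = 'nearest')")
    if (any(abs(x - round(x)) > 1e-8))
      stop("discrete models need integral branch lengths; ",
           "round with toGenomeUnits(rounding = 'nearest')")
    x <- round(x)
  }
  td <- data@tipDates[phy$tip.label]
  if (updateDates && length(unique(td)) == 1L)
    warning("all tips share one sampling date: node dates are unidentifiable")
  init <- .initState(data, model)
  if (!is.null(initDates)) init$dates <- initDates
  relaxed <- model %in% c("rc", "crc", "arc", "carc")
  set.seed(seed)
  samp <- .mcmcCore(phy$edge, length(phy$tip.label), x,
                    .MODEL_CODE[[model]], relaxed,
                    pr$mu[["shape"]], pr$mu[["scale"]],
                    pr$relax[["shape"]], pr$relax[["scale"]],
                    pr$alphaMean, treePrior == "coalescent",
                    as.integer(nIter), as.integer(thin),
                    init$dates, init$mu, 0.5, 5.0,
                    updateDates, priorOnly, 0.2)
  ntip <- length(phy$tip.label)
  colnames(samp) <- c("treeLogLik", "logPrior", "mu", "relax", "alpha",
                      paste0("date_", (ntip + 1L):(ntip + phy$Nnode)))
  samp <- cbind(samp, tmrca = samp[, paste0("date_", ntip + 1L)])
  keep <- colnames(samp)
  if (!relaxed) keep <- setdiff(keep, "relax")
  if (treePrior == "uniform") keep <- setdiff(keep, "alpha")
  new("PosteriorTrace", samples = samp[, keep, drop = FALSE],
      thin = as.integer(thin), seed = as.integer(seed), model = model,
      settings = list(priors = pr, treePrior = treePrior,
                      nIter = as.integer(nIter), burnin = burnin,
                      updateDates = updateDates, priorOnly = priorOnly))
}

#' Reversible-jump MCMC between strict and relaxed continuous clocks
#'
#' Moves between the continuous strict clock (\code{csc}, \eqn{\omega = 0})
#' and the continuous additive relaxed clock (\code{carc}, \eqn{\omega > 0}),
#' which nest at \eqn{\omega = 0}. The trans-model move draws \eqn{\omega}
#' from its Gamma prior (an independence sampler, so prior and proposal
#' densities cancel); model prior odds are 1:1, so the Bayes factor equals
#' the posterior odds of the indicator.
#'
#' @inheritParams runMcmc
#' @param models the two nested models to compare; only the continuous pair
#'   \code{c("csc", "carc")} is supported (the discrete strict clock is not
#'   nested in the discrete relaxed models).
#' @return List with \code{trace} (a [PosteriorTrace-class] whose samples
#'   include an \code{indicator} column, 0 = strict, 1 = relaxed),
#'   \code{bayesFactor} (posterior odds strict : relaxed), and
#'   \code{postStrict} (posterior probability of the strict model).
#' @export
runRjMcmc <- function(data, nIter = 1e5, thin = max(1L, nIter %/% 2000L),
                      seed = 1L, priors = NULL,
                      treePrior = c("coalescent", "uniform"),
                      burnin = 0.5, models = c("csc", "carc")) {
  stopifnot(is(data, "SubstTree"))
  if (any(models %in% c("sc", "rc", "arc")))
    stop("reversible-jump comparison is only supported for the continuous ",
         "nested pair csc/carc")
  treePrior <- match.arg(treePrior)
  if (nIter < 1000) stop("nIter below the burn-in floor (1000)")
  pr <- .mergePriors(priors)
  phy <- data@tree
  init <- .initState(data, "carc")
  set.seed(seed)
  samp <- .rjmcmcCore(phy$edge, length(phy$tip.label), phy$edge.length,
                      pr$mu[["shape"]], pr$mu[["scale"]],
                      pr$relax[["shape"]], pr$relax[["scale"]],
                      pr$alphaMean, treePrior == "coalescent",
                      as.integer(nIter), as.integer(thin),
                      init$dates, init$mu, 0.5, 5.0, 0.2)
  ntip <- length(phy$tip.label)
  colnames(samp) <- c("treeLogLik", "logPrior", "mu", "relax", "alpha",
                      "indicator",
                      paste0("date_", (ntip + 1L):(ntip + phy$Nnode)))
  samp <- cbind(samp, tmrca = samp[, paste0("date_", ntip + 1L)])
  if (treePrior == "uniform")
    samp <- samp[, setdiff(colnames(samp), "alpha"), drop = FALSE]
  trace <- new("PosteriorTrace", samples = samp, thin = as.integer(thin),
               seed = as.integer(seed), model = "csc/carc",
               settings = list(priors = pr, treePrior = treePrior,
                               nIter = as.integer(nIter), burnin = burnin))
  ind <- traceSamples(trace)[, "indicator"]
  nStrict <- sum(ind == 0)
  nRelax <- sum(ind == 1)
  list(trace = trace,
       bayesFactor = nStrict / nRelax,
       postStrict = nStrict / length(ind))
}

# R-side coalescent tree prior (independent of the C++ path; used by
# logPosterior and cross-checked in the tests).
.coalLogPrior <- function(internalDates, tipDates, alpha) {
  ev <- rbind(cbind(sort(internalDates), 1),  # coalescence: +1 lineage
              cbind(sort(tipDates), -1))      # sampling: -1 lineage
  # forward in time; coalescences first on ties
  ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
  k <- 1 + cumsum(ev[, 2])   # after the root coalescence, k = 2
  dt <- diff(ev[, 1])
  kk <- k[-length(k)]
  integral <- sum(0.5 * kk * (kk - 1) * dt)
  -length(internalDates) * log(alpha) - integral / alpha
}

#' Log posterior density of a dating state
#'
#' Evaluates \eqn{\sum_i \log p(x_i | l_i)} over branches, plus the log tree
#' prior on node dates and the log parameter priors. States violating the
#' parent-before-child constraint return \code{-Inf} (not an error). This is
#' a plain-R evaluation used for checking and for DIC plug-in deviances; the
#' MCMC itself uses an equivalent compiled path.
#'
#' @param state list with \code{dates} (full node-date vector, tips first,
#'   in ape node order), \code{mu}, \code{relax} (omega or sigma2; ignored
#'   for strict models), and \code{alpha} (coalescent prior parameter).
#' @param data a [SubstTree-class].
#' @param model clock model family name.
#' @param priors as in [runMcmc()].
#' @param treePrior \code{"coalescent"} or \code{"uniform"}.
#' @param likelihoodOnly return only the branch log-likelihood sum.
#' @return A single number (possibly \code{-Inf}).
#' @export
logPosterior <- function(state, data, model, priors = NULL,
                         treePrior = c("coalescent", "uniform"),
                         likelihoodOnly = FALSE) {
  stopifnot(is(data, "SubstTree"))
  model <- match.arg(tolower(model), names(.MODEL_CODE))
  treePrior <- match.arg(treePrior)
  pr <- .mergePriors(priors, model)
  phy <- data@tree
  ntip <- length(phy$tip.label)
  l <- state$dates[phy$edge[, 2]] - state$dates[phy$edge[, 1]]
  if (any(l < 0)) return(-Inf)
  clock <- switch(model,
    sc = clockModel("sc", state$mu),
    csc = clockModel("csc", state$mu),
    rc = clockModel("rc", state$mu, sigma2 = state$relax),
    crc = clockModel("crc", state$mu, sigma2 = state$relax),
    arc = clockModel("arc", state$mu, omega = state$relax),
    carc = clockModel("carc", state$mu, omega = state$relax))
  ll <- sum(suppressWarnings(branchLogLik(clock, l, phy$edge.length)))
  if (likelihoodOnly) return(ll)
  lp <- dgamma(state$mu, shape = pr$mu[["shape"]], scale = pr$mu[["scale"]],
               log = TRUE)
  if (model %in% c("rc", "crc", "arc", "carc") && !is.na(pr$relax[["shape"]]))
    lp <- lp + dgamma(state$relax, shape = pr$relax[["shape"]],
                      scale = pr$relax[["scale"]], log = TRUE)
  if (treePrior == "coalescent")
    lp <- lp + dexp(state$alpha, rate = 1 / pr$alphaMean, log = TRUE) +
      .coalLogPrior(state$dates[(ntip + 1L):length(state$dates)],
                    state$dates[seq_len(ntip)], state$alpha)
  ll + lp
}

#' Posterior summaries of a dating run
#'
#' Posterior mean and central 95\% credible interval for the TMRCA (root
#' date), \code{mu}, the relaxation parameter, \code{alpha}, and every
#' internal-node date, after discarding burn-in.
#'
#' @param trace a [PosteriorTrace-class].
#' @param burnin burn-in fraction (default: the run's stored setting).
#' @param level credible level (default 0.95).
#' @return A data.frame with columns \code{mean}, \code{lower}, \code{upper},
#'   \code{ciLength}, one row per parameter.
#' @export
summarizeTrace <- function(trace, burnin = NULL, level = 0.95) {
  stopifnot(is(trace, "PosteriorTrace"))
  s <- traceSamples(trace, burnin)
  if (nrow(s) == 0L) stop("empty trace after burn-in")
  if (nrow(s) < 100L)
    warning("fewer than 100 post-burn-in samples; summaries are unreliable")
  pars <- setdiff(colnames(s), c("treeLogLik", "logPrior"))
  a <- (1 - level) / 2
  out <- t(vapply(pars, function(p) {
    v <- s[, p]
    q <- unname(quantile(v, c(a, 1 - a), names = FALSE, type = 7))
    c(mean = mean(v), lower = q[1], upper = q[2], ciLength = q[2] - q[1])
  }, numeric(4)))
  as.data.frame(out)
}

# Split-Rhat: each chain halved, then the usual between/within comparison.
.splitRhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n2 <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[seq_len(n2)], ch[n2 + seq_len(n2)]))
  }
  n <- min(lengths(halves))
  m <- length(halves)
  mat <- vapply(halves, function(h) h[seq_len(n)], numeric(n))
  W <- mean(apply(mat, 2, var))
  B <- n * var(colMeans(mat))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for dating runs
#'
#' Effective sample size per parameter (autocorrelation-based, via
#' \pkg{coda}) and, given two or more chains, the split-\eqn{\hat R}
#' potential scale reduction factor. Parameters with ESS < 200 or
#' \eqn{\hat R > 1.1} are flagged.
#'
#' @param traces a [PosteriorTrace-class] or list of them (same parameters);
#'   chains of unequal length are truncated to the shortest, with a warning.
#' @param burnin burn-in fraction (default: each run's stored setting).
#' @return List with \code{ess} (named vector, summed across chains),
#'   \code{psrf} (named vector or \code{NULL} for a single chain), and
#'   \code{flagged} (character vector of parameter names).
#' @export
traceDiagnostics <- function(traces, burnin = NULL) {
  if (is(traces, "PosteriorTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  mats <- lapply(traces, function(tr) {
    s <- traceSamples(tr, burnin)
    s[, setdiff(colnames(s), c("treeLogLik", "logPrior")), drop = FALSE]
  })
  ns <- vapply(mats, nrow, integer(1))
  if (length(unique(ns)) > 1L) {
    warning("chains of unequal length; truncating to the shortest")
    mats <- lapply(mats, function(m) m[seq_len(min(ns)), , drop = FALSE])
  }
  pars <- colnames(mats[[1]])
  ess <- setNames(Reduce(`+`, lapply(mats, function(m)
    unname(coda::effectiveSize(coda::mcmc(m))[pars]))), pars)
  psrf <- NULL
  if (length(mats) >= 2L) {
    psrf <- vapply(pars, function(p)
      .splitRhat(lapply(mats, function(m) m[, p])), numeric(1))
  }
  flagged <- union(names(ess)[ess < 200],
                   if (!is.null(psrf)) names(psrf)[psrf > 1.1] else character())
  list(ess = ess, psrf = psrf, flagged = flagged)
}

#' Posterior-mean dated tree from a trace
#'
#' @param trace a [PosteriorTrace-class] from [runMcmc()].
#' @param data the [SubstTree-class] the run used.
#' @return A [TimeTree-class] with internal nodes at their posterior-mean
#'   dates.
#' @export
posteriorMeanTree <- function(trace, data) {
  stopifnot(is(trace, "PosteriorTrace"), is(data, "SubstTree"))
  s <- traceSamples(trace)
  phy <- data@tree
  ntip <- length(phy$tip.label)
  dates <- numeric(ntip + phy$Nnode)
  dates[seq_len(ntip)] <- data@tipDates[phy$tip.label]
  for (k in (ntip + 1L):(ntip + phy$Nnode))
    dates[k] <- mean(s[, paste0("date_", k)])
  # posterior means of jointly constrained dates can violate the ordering
  # marginally; clamp parents below their children
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge)))
    dates[po$edge[e, 1]] <- min(dates[po$edge[e, 1]], dates[po$edge[e, 2]])
  timeTree(phy, dates)
}
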