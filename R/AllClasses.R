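#' @useDynLib arcdating, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats dgamma pgamma qgamma rgamma dpois rpois qpois dnbinom
#'   rnbinom qnbinom pnbinom ppois dexp rexp runif integrate quantile var
#'   lm coef setNames convolve
#' @importFrom utils write.csv read.csv packageVersion
NULL

.CLOCK_MODELS <- c("sc", "rc", "arc", "csc", "crc", "carc")

#' Clock model parameters
#'
#' An S4 container for a molecular clock model and its parameters. Six models
#' are supported, in three families and two flavours each (discrete
#' substitution counts vs. continuous branch lengths):
#' \describe{
#'   \item{\code{sc}, \code{csc}}{strict clock: every branch accumulates
#'     substitutions at the same mean rate \code{mu}; counts are
#'     Poisson(\eqn{\mu l}) (discrete) or Gamma(shape \eqn{\mu l}, scale 1)
#'     (continuous).}
#'   \item{\code{rc}, \code{crc}}{classical uncorrelated relaxed clock: each
#'     branch draws its own rate from a Gamma distribution with mean \code{mu}
#'     and variance \code{sigma2}, identically across branches, giving
#'     branch variance \eqn{\mu l + \sigma^2 l^2}. Not additive.}
#'   \item{\code{arc}, \code{carc}}{additive relaxed clock: the per-branch
#'     rate variance scales as \eqn{\mu\omega/l}, giving branch variance
#'     \eqn{\mu l (1+\omega)} and a negative-binomial (resp. gamma) Levy
#'     process for the counts, which is additive under branch splitting and
#'     merging.}
#' }
#'
#' @slot model character; one of \code{"sc"}, \code{"rc"}, \code{"arc"},
#'   \code{"csc"}, \code{"crc"}, \code{"carc"}.
#' @slot mu mean substitution rate, substitutions per genome per year (> 0).
#' @slot sigma2 per-branch rate variance, defined only for \code{rc}/\code{crc}
#'   (>= 0); \code{NA_real_} otherwise.
#' @slot omega relaxation parameter, defined only for \code{arc}/\code{carc}
#'   (>= 0); \code{NA_real_} otherwise. \code{omega = 0} recovers the strict
#'   clock.
#'
#' @seealso [clockModel()] to construct, [branchMoments()], [branchLogLik()],
#'   [sampleSubstitutions()], [additivityGap()].
#' @export
setClass("ClockModel",
  representation(model = "character", mu = "numeric",
                 sigma2 = "numeric", omega = "numeric"),
  prototype(model = "sc", mu = 1, sigma2 = NA_real_, omega = NA_real_))

setValidity("ClockModel", function(object) {
  m <- object@model
  if (length(m) != 1L || !(m %in% .CLOCK_MODELS))
    return(sprintf("model must be one of: %s", paste(.CLOCK_MODELS, collapse = ", ")))
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    return("mu must be a single finite value > 0")
  relaxedRC <- m %in% c("rc", "crc")
  relaxedARC <- m %in% c("arc", "carc")
  if (relaxedRC) {
    if (!is.finite(object@sigma2) || object@sigma2 < 0)
      return("sigma2 must be finite and >= 0 for rc/crc models")
  } else if (!is.na(object@sigma2)) {
    return("sigma2 is only defined for rc/crc models")
  }
  if (relaxedARC) {
    if (!is.finite(object@omega) || object@omega < 0)
      return("omega must be finite and >= 0 for arc/carc models")
  } else if (!is.na(object@omega)) {
    return("omega is only defined for arc/carc models")
  }
  TRUE
})

#' Construct a clock model
#'
#' @param model one of \code{"sc"}, \code{"rc"}, \code{"arc"}, \code{"csc"},
#'   \code{"crc"}, \code{"carc"} (case-insensitive).
#' @param mu mean substitution rate (substitutions per genome per year, > 0).
#' @param sigma2 per-branch rate variance; required for \code{rc}/\code{crc}.
#' @param omega relaxation parameter; required for \code{arc}/\code{carc}.
#' @return A [ClockModel-class] object.
#' @examples
#' clockModel("arc", mu = 5, omega = 2)
#' clockModel("sc", mu = 5)
#' @export
clockModel <- function(model, mu, sigma2 = NA_real_, omega = NA_real_) {
  model <- tolower(as.character(model))
  if (model %in% c("rc", "crc") && is.na(sigma2))
    stop("sigma2 must be supplied for model '", model, "'")
  if (model %in% c("arc", "carc") && is.na(omega))
    stop("omega must be supplied for model '", model, "'")
  new("ClockModel", model = model, mu = as.numeric(mu),
      sigma2 = as.numeric(sigma2), omega = as.numeric(omega))
}

#' @describeIn ClockModel-class model identifier ("sc", "rc", ...).
#' @param object,x a \code{ClockModel}.
#' @export
modelName <- function(x) x@model

#' @describeIn ClockModel-class mean substitution rate.
#' @export
clockRate <- function(x) x@mu

#' @describeIn ClockModel-class relaxation parameter: \code{sigma2} for
#'   rc/crc, \code{omega} for arc/carc, 0 for strict clocks.
#' @export
relaxation <- function(x) {
  switch(x@model,
         rc = x@sigma2, crc = x@sigma2,
         arc = x@omega, carc = x@omega,
         0)
}

#' @describeIn ClockModel-class TRUE for the discrete (integer-count) models.
#' @export
isDiscrete <- function(x) x@model %in% c("sc", "rc", "arc")

#' @describeIn ClockModel-class TRUE for relaxed (non-strict) models.
#' @export
isRelaxed <- function(x) x@model %in% c("rc", "crc", "arc", "carc")

setMethod("show", "ClockModel", function(object) {
  extra <- switch(object@model,
    rc = , crc = sprintf(", sigma2 = %g", object@sigma2),
    arc = , carc = sprintf(", omega = %g", object@omega),
    "")
  cat(sprintf("ClockModel '%s' (mu = %g%s)\n", object@model, object@mu, extra))
})

#' Dated (time-scaled) phylogeny
#'
#' A rooted tree together with a calendar date (decimal year) for every node,
#' tips and internal nodes alike. Branch "lengths" are implied durations
#' \eqn{l_i =} date(child) \eqn{-} date(parent), all non-negative.
#'
#' @slot tree an \code{ape} \code{phylo} object (rooted).
#' @slot dates numeric vector of node dates in decimal years, indexed by
#'   \code{ape} node number (tips \code{1..n}, root \code{n+1}, ...).
#' @seealso [timeTree()], [branchDurations()], [tmrca()], [nodeDates()].
#' @export
setClass("TimeTree", representation(tree = "ANY", dates = "numeric"))

setValidity("TimeTree", function(object) {
  phy <- object@tree
  if (!inherits(phy, "phylo")) return("tree must be a 'phylo' object")
  nn <- length(phy$tip.label) + phy$Nnode
  if (length(object@dates) != nn)
    return(sprintf("dates must have one entry per node (%d), got %d",
                   nn, length(object@dates)))
  if (any(!is.finite(object@dates))) return("all node dates must be finite")
  d <- object@dates[phy$edge[, 2]] - object@dates[phy$edge[, 1]]
  if (any(d < -1e-9)) {
    bad <- phy$edge[which(d < -1e-9)[1], 2]
    return(sprintf("node %d is dated before its parent", bad))
  }
  TRUE
})

#' Construct a TimeTree
#' @param tree a rooted \code{phylo}.
#' @param dates node dates (decimal years), one per node in \code{ape} node
#'   order (tips first, then internal nodes starting at the root).
#' @return A [TimeTree-class] object.
#' @export
timeTree <- function(tree, dates) new("TimeTree", tree = tree, dates = as.numeric(dates))

#' @describeIn TimeTree-class all node dates (tips then internal nodes).
#' @param x a \code{TimeTree}.
#' @export
nodeDates <- function(x) x@dates

#' @describeIn TimeTree-class sampling dates of the tips, named by tip label.
#' @export
setGeneric("tipDates", function(x) standardGeneric("tipDates"))

#' @rdname TimeTree-class
setMethod("tipDates", "TimeTree", function(x) {
  setNames(x@dates[seq_along(x@tree$tip.label)], x@tree$tip.label)
})

#' @describeIn TimeTree-class date of the most recent common ancestor
#'   (the root).
#' @export
tmrca <- function(x) {
  stopifnot(is(x, "TimeTree"))
  x@dates[length(x@tree$tip.label) + 1L]
}

setMethod("show", "TimeTree", function(object) {
  n <- length(object@tree$tip.label)
  cat(sprintf("TimeTree: %d tips, root (TMRCA) at %.4f, tips sampled %.4f-%.4f\n",
              n, tmrca(object), min(object@dates[1:n]), max(object@dates[1:n])))
})

#' Substitution-scaled phylogeny
#'
#' A rooted tree whose branch lengths are observed numbers of substitutions
#' (integral, per genome) or expected substitutions (fractional, per site or
#' per genome), together with the sampling date of each tip. This is the
#' data object consumed by the dating MCMC.
#'
#' @slot tree an \code{ape} \code{phylo}; \code{edge.length} holds the
#'   substitution branch lengths.
#' @slot units \code{"per-genome"} or \code{"per-site"}.
#' @slot genomeLength genome length in bp (\code{NA} if unknown).
#' @slot tipDates numeric, named by tip label; decimal years.
#' @seealso [substTree()], [readDatedTree()], [toGenomeUnits()], [rootToTip()].
#' @export
setClass("SubstTree",
  representation(tree = "ANY", units = "character",
                 genomeLength = "numeric", tipDates = "numeric"))

setValidity("SubstTree", function(object) {
  phy <- object@tree
  if (!inherits(phy, "phylo")) return("tree must be a 'phylo' object")
  if (is.null(phy$edge.length)) return("tree must have branch lengths")
  if (any(phy$edge.length < 0)) return("branch lengths must be >= 0")
  if (!(object@units %in% c("per-genome", "per-site")))
    return("units must be 'per-genome' or 'per-site'")
  labs <- phy$tip.label
  if (anyDuplicated(labs)) return("duplicate tip labels")
  if (length(object@tipDates) != length(labs))
    return("tipDates must have one entry per tip")
  if (!all(labs %in% names(object@tipDates)))
    return("tipDates names must match tip labels")
  if (any(!is.finite(object@tipDates)))
    return("tipDates must be finite decimal years")
  TRUE
})

#' Construct a SubstTree
#' @param tree rooted \code{phylo} with substitution-scaled branch lengths.
#' @param tipDates named numeric vector of tip sampling dates (decimal years);
#'   names must match the tip labels.
#' @param units \code{"per-genome"} (default) or \code{"per-site"}.
#' @param genomeLength genome length in bp, used by unit conversion.
#' @return A [SubstTree-class] object.
#' @export
substTree <- function(tree, tipDates, units = "per-genome", genomeLength = NA_real_) {
  new("SubstTree", tree = tree, units = units,
      genomeLength = as.numeric(genomeLength),
      tipDates = tipDates[tree$tip.label])
}

#' @rdname SubstTree-class
#' @param x a \code{SubstTree}.
setMethod("tipDates", "SubstTree", function(x) x@tipDates)

#' @describeIn SubstTree-class per-branch substitution lengths, in edge order.
#' @export
branchSubstitutions <- function(x) x@tree$edge.length

setMethod("show", "SubstTree", function(object) {
  cat(sprintf("SubstTree: %d tips, lengths in %s units%s, dates %.4f-%.4f\n",
              length(object@tree$tip.label), object@units,
              if (is.na(object@genomeLength)) ""
              else sprintf(" (genome %g bp)", object@genomeLength),
              min(object@tipDates), max(object@tipDates)))
})

#' Simulation configuration
#'
#' Parameters of a full simulated dating study: a heterochronous coalescent
#' tree, a clock model generating per-branch substitutions, and (optionally)
#' Jukes-Cantor sequences.
#'
#' @slot nTips number of sampled genomes.
#' @slot samplingDates decimal-year sampling date of every tip.
#' @slot alpha expected pairwise coalescence time in years
#'   (\eqn{\alpha = N_e g}).
#' @slot clock a [ClockModel-class].
#' @slot genomeLength genome length in bp (for sequence simulation and unit
#'   conversion).
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [sampleCoalescentTree()], [simulateStudy()].
#' @export
setClass("SimConfig",
  representation(nTips = "integer", samplingDates = "numeric",
                 alpha = "numeric", clock = "ClockModel",
                 genomeLength = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@alpha <= 0) return("alpha must be > 0")
  if (length(object@samplingDates) != object@nTips)
    return("samplingDates must have length nTips")
  if (object@nTips < 2L) return("need at least 2 tips")
  if (!is.na(object@genomeLength) && object@genomeLength <= 0)
    return("genomeLength must be > 0")
  TRUE
})

#' Construct a SimConfig
#' @param nTips number of tips.
#' @param samplingDates numeric vector of tip dates (length \code{nTips}).
#' @param alpha expected pairwise coalescence time (years), > 0.
#' @param clock a [ClockModel-class].
#' @param genomeLength genome length in bp.
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nTips, samplingDates, alpha, clock,
                      genomeLength = NA_real_, seed = 1L) {
  new("SimConfig", nTips = as.integer(nTips),
      samplingDates = as.numeric(samplingDates), alpha = as.numeric(alpha),
      clock = clock, genomeLength = as.numeric(genomeLength),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d tips sampled %.2f-%.2f, alpha = %g, clock '%s'\n",
              object@nTips, min(object@samplingDates), max(object@samplingDates),
              object@alpha, object@clock@model))
})

#' Posterior trace of the dating MCMC
#'
#' Per-iteration records of the MCMC over node dates and clock parameters.
#' Columns of \code{samples}: \code{treeLogLik}, \code{logPrior}, \code{mu},
#' \code{relax} (omega or sigma2; absent for strict clocks), \code{alpha}
#' (coalescent tree-prior parameter), \code{indicator} (rjMCMC only;
#' 0 = strict, 1 = relaxed), \code{tmrca}, and one \code{date_<k>} column per
#' internal node (ape node number \code{k}).
#'
#' @slot samples numeric matrix, one row per recorded iteration.
#' @slot thin thinning interval.
#' @slot seed RNG seed used for the run.
#' @slot model model identifier ("sc", ..., or "csc/carc" for rjMCMC runs).
#' @slot settings list: priors, tree prior, nIter, burn-in fraction.
#' @seealso [runMcmc()], [summarizeTrace()], [traceDiagnostics()], [dic()].
#' @export
setClass("PosteriorTrace",
  representation(samples = "matrix", thin = "integer", seed = "integer",
                 model = "character", settings = "list"))

setValidity("PosteriorTrace", function(object) {
  if (nrow(object@samples) < 1L) return("empty trace")
  if (!("treeLogLik" %in% colnames(object@samples)))
    return("samples must contain a treeLogLik column")
  if (any(!is.finite(object@samples[, "treeLogLik"])))
    return("treeLogLik must be finite at every recorded state")
  TRUE
})

#' @describeIn PosteriorTrace-class the samples matrix, optionally after
#'   discarding burn-in.
#' @param x a \code{PosteriorTrace}.
#' @param burnin fraction of initial samples to discard (default: the value
#'   stored at run time, itself defaulting to 0.5).
#' @export
traceSamples <- function(x, burnin = NULL) {
  if (is.null(burnin)) burnin <- x@settings$burnin %||% 0.5
  s <- x@samples
  drop <- floor(nrow(s) * burnin)
  if (drop > 0) s <- s[-seq_len(drop), , drop = FALSE]
  s
}

setMethod("show", "PosteriorTrace", function(object) {
  cat(sprintf("PosteriorTrace: %d samples (thin %d) of %d parameters, model '%s', seed %d\n",
              nrow(object@samples), object@thin, ncol(object@samples),
              object@model, object@seed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
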