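# Simulation: heterochronous coalescent trees, clock-model substitutions,
# Jukes-Cantor alignments, and the standard simulation study design.

#' Simulate a dated tree under the heterochronous coalescent
#'
#' Going backwards in time, with \eqn{k} active lineages the next coalescence
#' is exponential with rate \eqn{k(k-1)/(2\alpha)}; lineages become active at
#' their sampling dates. \eqn{\alpha = N_e g} is the expected coalescence
#' time of any two contemporaneous lineages.
#'
#' @param config a [SimConfig-class]; alternatively supply
#'   \code{samplingDates} and \code{alpha} directly.
#' @param samplingDates,alpha used when \code{config} is missing.
#' @return A [TimeTree-class] with binary topology, \code{n - 1} internal
#'   nodes, and tips carrying the sampling dates.
#' @examples
#' set.seed(1)
#' tt <- sampleCoalescentTree(samplingDates = rep(2020, 5), alpha = 5)
#' tmrca(tt)
#' @export
sampleCoalescentTree <- function(config = NULL, samplingDates = NULL,
                                 alpha = NULL) {
  if (!is.null(config)) {
    stopifnot(is(config, "SimConfig"))
    samplingDates <- config@samplingDates
    alpha <- config@alpha
  }
  n <- length(samplingDates)
  stopifnot(n >= 2, alpha > 0)
  labs <- names(samplingDates)
  if (is.null(labs)) labs <- sprintf("t%d_%s", seq_len(n),
                                     format(samplingDates, trim = TRUE))
  sim <- .coalSimCore(as.numeric(samplingDates), alpha)
  # renumber internal nodes to ape convention: root = n + 1
  apeId <- c(seq_len(n), seq.int(2L * n - 1L, n + 1L))
  anc <- sim$anc
  hasParent <- which(anc > 0L)
  edge <- cbind(apeId[anc[hasParent]], apeId[hasParent])
  dates <- numeric(2L * n - 1L)
  dates[apeId] <- sim$nodeDate
  phy <- structure(list(edge = edge, tip.label = labs, Nnode = n - 1L),
                   class = "phylo", order = NULL)
  phy$edge.length <- dates[edge[, 2]] - dates[edge[, 1]]
  new("TimeTree", tree = phy, dates = dates)
}

#' Simulate observed substitutions on a dated tree
#'
#' Draws per-branch substitution counts (or continuous lengths) under a clock
#' model. For the discrete additive relaxed clock the two-stage mechanism is
#' used: a per-branch rate \eqn{m_i \sim} Gamma(\eqn{\mu l_i/\omega},
#' \eqn{\omega/l_i}) and then \eqn{x_i \sim} Poisson(\eqn{m_i l_i}), which
#' marginally is the negative-binomial branch law. Other models draw from
#' their branch law directly.
#'
#' @param timetree a [TimeTree-class].
#' @param clock a [ClockModel-class].
#' @param genomeLength genome length in bp to record on the result.
#' @return A [SubstTree-class] in per-genome units (integral lengths for
#'   discrete models).
#' @export
simulateObservedTree <- function(timetree, clock, genomeLength = NA_real_) {
  stopifnot(is(timetree, "TimeTree"), is(clock, "ClockModel"))
  l <- branchDurations(timetree)
  if (clock@model == "arc" && clock@omega > 0) {
    x <- numeric(length(l))
    pos <- l > 0
    m <- vapply(which(pos), function(i) sampleRate(clock, l[i]), numeric(1))
    x[pos] <- rpois(sum(pos), m * l[pos])
  } else {
    x <- sampleSubstitutions(clock, l)
  }
  phy <- timetree@tree
  phy$edge.length <- unname(x)
  substTree(phy, tipDates(timetree), units = "per-genome",
            genomeLength = genomeLength)
}

.BASES <- c("a", "c", "g", "t")

#' Simulate a Jukes-Cantor alignment along a dated tree
#'
#' The root sequence is uniform over \{A, C, G, T\}; each branch applies the
#' Jukes-Cantor substitution process with an expected number of substitutions
#' per site equal to the branch's realized clock draw divided by the genome
#' length (for the discrete additive clock, \eqn{m_i l_i / L} with
#' \eqn{m_i} from the per-branch rate law). Per site, the probability of
#' observing a changed base over divergence \eqn{d} is
#' \eqn{(3/4)(1 - e^{-4d/3})}.
#'
#' @inheritParams simulateObservedTree
#' @param genomeLength sequence length in bp (> 0).
#' @return A character matrix (tips x sites) of class \code{DNAbin}-friendly
#'   lower-case bases, rownames = tip labels. Write with [writeFasta()].
#' @export
simulateAlignment <- function(timetree, clock, genomeLength) {
  stopifnot(is(timetree, "TimeTree"), is(clock, "ClockModel"))
  if (is.na(genomeLength) || genomeLength <= 0)
    stop("genomeLength must be > 0")
  L <- as.integer(genomeLength)
  phy <- timetree@tree
  ntip <- length(phy$tip.label)
  l <- branchDurations(timetree)
  # realized expected substitutions per branch
  ex <- vapply(seq_along(l), function(i) {
    if (l[i] == 0) return(0)
    switch(clock@model,
      sc = , csc = clock@mu * l[i],
      rc = , crc = , arc = sampleRate(clock, l[i]) * l[i],
      carc = sampleSubstitutions(clock, l[i]))
  }, numeric(1))
  d <- ex / L                              # substitutions per site
  pChange <- 0.75 * (1 - exp(-4 * d / 3))  # JC
  seqs <- vector("list", ntip + phy$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(.BASES, L, replace = TRUE)
  eo <- ape::reorder.phylo(phy, "cladewise")
  ord <- match(paste(eo$edge[, 1], eo$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  for (e in ord) {
    par <- phy$edge[e, 1]; chd <- phy$edge[e, 2]
    s <- seqs[[par]]
    hit <- runif(L) < pChange[e]
    if (any(hit)) {
      # conditional on change, the three other bases are equally likely
      cur <- s[hit]
      new <- .BASES[(match(cur, .BASES) - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L + 1L]
      s[hit] <- new
    }
    seqs[[chd]] <- s
  }
  aln <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(aln) <- phy$tip.label
  aln
}

#' Write an alignment matrix as FASTA
#' @param aln character matrix (sequences in rows, rownames = labels).
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeFasta <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  invisible(file)
}

#' Simulate a complete dating study data set
#'
#' The standard study design: \code{nTips} genomes of \code{genomeLength} bp
#' sampled at regular intervals (equally spaced, endpoints included) over
#' \code{dateRange}, a heterochronous coalescent genealogy with
#' \eqn{\alpha = 5} years, and per-branch substitutions from the discrete
#' additive relaxed clock with mean rate \eqn{\mu = 5} substitutions per
#' genome per year and relaxation \code{omega}. The observed tree is the true
#' topology with branch lengths drawn from the clock law ("error-free
#' reconstruction"); set \code{sequences = TRUE} to also get a Jukes-Cantor
#' alignment for use with an external tree estimator.
#'
#' @param omega relaxation parameter (>= 0; 0 gives a strict clock).
#' @param seed integer RNG seed.
#' @param nTips number of sampled genomes.
#' @param dateRange first and last sampling date (decimal years).
#' @param alpha expected pairwise coalescence time, years.
#' @param mu mean substitution rate per genome per year.
#' @param genomeLength genome length in bp.
#' @param model clock model for the substitution simulation.
#' @param sequences also simulate an alignment?
#' @return List with components \code{timetree} ([TimeTree-class], the
#'   truth), \code{substtree} ([SubstTree-class], the data),
#'   \code{alignment} (or \code{NULL}), and \code{config}
#'   ([SimConfig-class]).
#' @examples
#' fx <- simulateStudy(omega = 2, seed = 1, nTips = 20)
#' fx$substtree
#' @export
simulateStudy <- function(omega, seed, nTips = 100, dateRange = c(2010, 2020),
                          alpha = 5, mu = 5, genomeLength = 10000,
                          model = "arc", sequences = FALSE) {
  stopifnot(omega >= 0)
  clock <- switch(model,
    sc = , csc = clockModel(model, mu = mu),
    rc = , crc = clockModel(model, mu = mu, sigma2 = omega),
    arc = , carc = clockModel(model, mu = mu, omega = omega))
  dates <- seq(dateRange[1], dateRange[2], length.out = nTips)
  names(dates) <- sprintf("t%03d_%.4f", seq_len(nTips), dates)
  cfg <- simConfig(nTips, dates, alpha = alpha, clock = clock,
                   genomeLength = genomeLength, seed = seed)
  set.seed(seed)
  tt <- sampleCoalescentTree(cfg)
  st <- simulateObservedTree(tt, clock, genomeLength = genomeLength)
  aln <- if (sequences) simulateAlignment(tt, clock, genomeLength) else NULL
  list(timetree = tt, substtree = st, alignment = aln, config = cfg)
}
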