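# Tree I/O, tip-date handling and unit conversions.

.parseDates <- function(labels, dates = NULL, pattern = NULL,
                        delim = "_", field = c("last", "first")) {
  field <- match.arg(field)
  if (!is.null(dates)) {
    if (is.character(dates) && length(dates) == 1L) { # a file path
      sep <- if (grepl(",", readLines(dates, n = 1L))) "," else ""
      tab <- read.csv(dates, header = FALSE, sep = sep,
                      stringsAsFactors = FALSE, comment.char = "#")
      if (suppressWarnings(is.na(as.numeric(tab[1, 2]))))
        tab <- tab[-1, , drop = FALSE] # header line
      dates <- setNames(suppressWarnings(as.numeric(tab[, 2])),
                        as.character(tab[, 1]))
      if (anyNA(dates))
        stop("could not parse dates for: ",
             paste(names(dates)[is.na(dates)], collapse = ", "))
    } else if (is.data.frame(dates)) {
      dates <- setNames(as.numeric(dates[, 2]), as.character(dates[, 1]))
    }
    missing <- setdiff(labels, names(dates))
    if (length(missing))
      stop("no sampling date for tip(s): ", paste(missing, collapse = ", "))
    return(dates[labels])
  }
  if (!is.null(pattern)) {
    m <- regmatches(labels, regexec(pattern, labels))
    val <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                  character(1))
  } else {
    parts <- strsplit(labels, delim, fixed = TRUE)
    val <- vapply(parts, function(p)
      if (length(p) >= 2) p[if (field == "last") length(p) else 1L]
      else NA_character_, character(1))
  }
  num <- suppressWarnings(as.numeric(val))
  if (any(is.na(num)))
    stop("could not parse a sampling date from tip label(s): ",
         paste(labels[is.na(num)], collapse = ", "))
  setNames(num, labels)
}

#' Read a substitution-scaled tree with tip dates
#'
#' Parses a rooted Newick tree (branch lengths in substitution units) and
#' attaches a decimal-year sampling date to every tip. Dates are taken, in
#' order of precedence, from an external two-column table (\code{dates}: a
#' data frame or the path of a tab/comma-separated file, label then year,
#' header optional), from a regex \code{pattern} whose first capture group is
#' the year, or from a field of the label split on \code{delim} (default:
#' the last \code{"_"}-separated field, e.g. \code{"A_2010.0"}).
#'
#' Polytomies are accepted and resolved into binary nodes joined by
#' zero-length branches (with a notice); under additive clock models the
#' likelihood is unchanged by this resolution.
#'
#' @param source Newick string or path to a Newick file.
#' @param dates optional two-column table (or its file path): label, year.
#' @param pattern optional regex with the date as first capture group.
#' @param delim,field label-splitting fallback: delimiter and which field.
#' @param units \code{"per-site"} or \code{"per-genome"} (what the branch
#'   lengths measure).
#' @param genomeLength genome length in bp, if known.
#' @return A [SubstTree-class].
#' @examples
#' tr <- readDatedTree("(A_2010.0:0.001,B_2020.0:0.002);", units = "per-site")
#' tipDates(tr)
#' @export
readDatedTree <- function(source, dates = NULL, pattern = NULL,
                          delim = "_", field = "last",
                          units = "per-genome", genomeLength = NA_real_) {
  txt <- if (grepl("\\(", source)) source else paste(readLines(source), collapse = "")
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("could not parse Newick input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length))
    stop("Newick input has no branch lengths")
  # trees are taken as rooted as given; a trifurcating root counts as a
  # polytomy here even though ape would call the tree "unrooted binary"
  if (phy$Nnode < length(phy$tip.label) - 1L) {
    message("resolving polytomies with zero-length branches")
    phy <- ape::multi2di(phy)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  td <- .parseDates(phy$tip.label, dates = dates, pattern = pattern,
                    delim = delim, field = field)
  substTree(phy, td, units = units, genomeLength = genomeLength)
}

#' Write a tree to Newick
#'
#' A [SubstTree-class] is written with its substitution branch lengths; a
#' [TimeTree-class] is written with branch lengths equal to durations in
#' years. Lengths are written at full precision (15 significant digits).
#'
#' @param x a \code{SubstTree} or \code{TimeTree}.
#' @param file output path, or \code{NULL} to return the Newick string.
#' @return The Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(x, file = NULL) {
  if (is(x, "TimeTree")) {
    phy <- x@tree
    phy$edge.length <- x@dates[phy$edge[, 2]] - x@dates[phy$edge[, 1]]
  } else if (is(x, "SubstTree")) {
    phy <- x@tree
  } else stop("x must be a SubstTree or TimeTree")
  if (is.null(phy$tip.label) || length(phy$tip.label) == 0L)
    stop("empty tree")
  txt <- ape::write.tree(phy, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Convert per-site branch lengths to per-genome substitutions
#'
#' Multiplies every branch length by the genome length. With
#' \code{rounding = "nearest"} the products are rounded to integers (ties,
#' e.g. 0.5, round half away from zero), as required before evaluating the
#' discrete-model likelihoods; \code{"none"} keeps fractional lengths for
#' the continuous models.
#'
#' @param x a [SubstTree-class] in \code{"per-site"} units.
#' @param genomeLength genome length in bp (> 0); defaults to the length
#'   stored in \code{x}.
#' @param rounding \code{"none"} or \code{"nearest"}.
#' @return A [SubstTree-class] in \code{"per-genome"} units.
#' @export
toGenomeUnits <- function(x, genomeLength = NULL,
                          rounding = c("none", "nearest")) {
  stopifnot(is(x, "SubstTree"))
  rounding <- match.arg(rounding)
  if (x@units == "per-genome") stop("tree is already in per-genome units")
  if (is.null(genomeLength)) genomeLength <- x@genomeLength
  if (is.na(genomeLength) || genomeLength <= 0)
    stop("genomeLength must be > 0")
  phy <- x@tree
  len <- phy$edge.length * genomeLength
  if (rounding == "nearest") len <- floor(len + 0.5) # half away from zero
  phy$edge.length <- len
  substTree(phy, x@tipDates, units = "per-genome", genomeLength = genomeLength)
}

#' Root-to-tip path lengths
#'
#' Sum of substitution branch lengths from the root to each tip.
#'
#' @param x a [SubstTree-class] (rooted).
#' @return Named numeric vector, one entry per tip.
#' @export
rootToTip <- function(x) {
  stopifnot(is(x, "SubstTree"))
  # the tree is taken as rooted as given (node ntip+1), even when the root
  # trifurcates and ape's degree heuristic would call it unrooted
  phy <- x@tree
  d <- ape::node.depth.edgelength(phy)
  setNames(d[seq_along(phy$tip.label)], phy$tip.label)
}

#' Branch durations of a dated tree
#'
#' Returns \eqn{l_i =} date(child) \eqn{-} date(parent) for every edge of a
#' [TimeTree-class], in the tree's edge order, named by child node number.
#'
#' @param x a [TimeTree-class].
#' @return Numeric vector of durations in years (all >= 0).
#' @export
branchDurations <- function(x) {
  stopifnot(is(x, "TimeTree"))
  e <- x@tree$edge
  d <- x@dates[e[, 2]] - x@dates[e[, 1]]
  if (any(d < 0)) {
    bad <- e[which(d < 0)[1], 2]
    stop("node ", bad, " is dated before its parent")
  }
  setNames(d, e[, 2])
}
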