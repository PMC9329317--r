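#' @importFrom stats optim optimize setNames rnorm runif rexp dpois qpois
#'   pt p.adjust sd qt var quantile
#' @importFrom utils head tail read.csv write.csv combn
NULL

#' Time-calibrated phylogeny
#'
#' A `timeTree` wraps an [ape::phylo] tree whose edge lengths are durations in
#' millions of years (Myr) together with the age of the root in Ma before
#' present. Tip ages (Ma) are derived as `root age - root-to-tip path length`,
#' so extant tips have age 0 and fossil tips positive ages. A tree without
#' edge lengths is admitted as an undated topology (e.g. a cladogram awaiting
#' time-scaling with [dateTreeEqual()]).
#'
#' @param phy an [ape::phylo] object. Polytomies are allowed.
#' @param root_age age of the root in Ma before present. Defaults to the
#'   maximum root-to-tip path length, which makes the deepest tip extant.
#' @return an object of class `timeTree`: the `phylo` object with a
#'   `root.age` attribute and, when edge lengths are present, a `dated` flag.
#' @examples
#' tr <- readNewickTree("((A:1,B:1):1,C:2);")
#' tipAges(tr)
#' @export
timeTree <- function(phy, root_age = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  dated <- !is.null(phy$edge.length)
  if (dated && any(phy$edge.length < 0)) stop("negative branch durations")
  if (dated) {
    depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
    if (is.null(root_age)) root_age <- max(depths)
    if (root_age < max(depths) - 1e-9) {
      stop("root_age is younger than the deepest tip allows")
    }
  } else {
    root_age <- NA_real_
  }
  structure(phy, class = c("timeTree", "phylo"),
            root.age = root_age, dated = dated)
}

#' @rdname timeTree
#' @param x,tree a `timeTree`
#' @export
isDated <- function(tree) isTRUE(attr(tree, "dated"))

#' @rdname timeTree
#' @export
rootAge <- function(tree) attr(tree, "root.age")

#' Tip ages in Ma before present
#'
#' @param tree a dated `timeTree`
#' @return named numeric vector of tip ages (0 = extant)
#' @export
tipAges <- function(tree) {
  .assertDated(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  ages <- rootAge(tree) - depths
  ages[abs(ages) < 1e-12] <- 0
  setNames(ages, tree$tip.label)
}

.assertDated <- function(tree) {
  if (!isDated(tree)) stop("tree is undated; run dateTreeEqual() first")
  invisible(tree)
}

#' Validate the internal consistency of a timeTree
#'
#' Checks: single root, unique tip labels, strictly positive durations (when
#' dated), and that root age minus the root-to-tip path length reproduces each
#' tip age to 1e-9.
#'
#' @param tree a `timeTree`
#' @param strict_positive require all durations > 0 (default TRUE for dated trees)
#' @return `TRUE` invisibly, or an error describing the violation
#' @export
validateTimeTree <- function(tree, strict_positive = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo-based tree")
  ntip <- ape::Ntip(tree)
  kids <- tabulate(tree$edge[, 2], nbins = ntip + tree$Nnode)
  if (any(kids > 1)) stop("node with multiple parents: not a tree")
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1) stop("tree must have exactly one root")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (isDated(tree)) {
    if (strict_positive && any(tree$edge.length <= 0)) {
      stop("non-positive branch duration")
    }
    ages <- tipAges(tree)
    depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    if (any(abs(rootAge(tree) - depths - ages) > 1e-9)) {
      stop("tip ages inconsistent with root age and path durations")
    }
  }
  invisible(TRUE)
}

#' @export
print.timeTree <- function(x, ...) {
  cat("timeTree with", ape::Ntip(x), "tips and", x$Nnode, "internal nodes\n")
  if (isDated(x)) {
    ages <- tipAges(x)
    cat(sprintf("  root age %.4g Ma; %d extant, %d fossil tips\n",
                rootAge(x), sum(ages == 0), sum(ages > 0)))
  } else {
    cat("  undated topology (no branch durations)\n")
  }
  invisible(x)
}

#' Read a Newick tree
#'
#' Parses a Newick string or file via [ape::read.tree()]. Branch lengths are
#' optional; a lengthless topology is returned as an undated `timeTree`.
#' Duplicate tip labels are an error.
#'
#' @param text Newick string (mutually exclusive with `file`)
#' @param file path to a Newick file
#' @param root_age optional root age in Ma (passed to [timeTree()])
#' @return a `timeTree`
#' @export
readNewickTree <- function(text = NULL, file = NULL, root_age = NULL) {
  if (is.null(text) == is.null(file)) stop("supply exactly one of 'text' or 'file'")
  phy <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("malformed Newick input")
  timeTree(phy, root_age = root_age)
}

#' Write a timeTree as Newick
#'
#' @param tree a `timeTree`
#' @param file optional path; when `NULL` the Newick string is returned
#' @export
writeNewickTree <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' Fossil occurrence ranges
#'
#' Constructs and validates a table of stratigraphic ranges: first appearance
#' datum (FAD) and last appearance datum (LAD), both in Ma before present with
#' `fad >= lad >= 0`.
#'
#' @param taxon character vector of taxon labels
#' @param fad,lad numeric vectors of ages (Ma)
#' @return a `data.frame` of class `occurrenceRanges`
#' @export
occurrenceRanges <- function(taxon, fad, lad = fad) {
  if (anyDuplicated(taxon)) stop("duplicate taxa in occurrence table")
  if (any(!is.finite(fad)) || any(!is.finite(lad))) stop("non-finite ages")
  if (any(lad < 0)) stop("negative ages are not allowed")
  if (any(fad < lad)) stop("fad must be >= lad for every taxon")
  structure(data.frame(taxon = as.character(taxon), fad = fad, lad = lad,
                       stringsAsFactors = FALSE),
            class = c("occurrenceRanges", "data.frame"))
}

#' Read an occurrence CSV (columns taxon, fad, lad)
#' @param file path to CSV
#' @return an `occurrenceRanges` data.frame
#' @export
readOccurrences <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("taxon", "fad")
  if (!all(need %in% names(d))) stop("occurrence CSV needs columns taxon, fad[, lad]")
  if (is.null(d$lad)) d$lad <- d$fad
  occurrenceRanges(d$taxon, d$fad, d$lad)
}

#' Time-scale a cladogram with the 'equal' method
#'
#' Node ages are initialised to the oldest first-appearance datum (FAD) among
#' the node's descendant tips; tip ages are set to their own FADs; the root age
#' is the oldest FAD plus `root_extension`. Zero-duration branches (created
#' wherever a tip's FAD equals its ancestor's age) are then removed by locating
#' the nearest ancestral branch of positive duration and dividing its span
#' equally among itself and the maximal chain of consecutive zero-duration
#' branches below it. The result has strictly positive durations everywhere.
#'
#' @param tree a `timeTree` (dated or not; only the topology is used)
#' @param occurrences an `occurrenceRanges` table covering every tip
#' @param root_extension extra root length in Myr (> 0), default 10
#' @return a dated `timeTree` whose tip ages equal the FADs
#' @examples
#' topo <- readNewickTree("((A,B),C);")
#' occ <- occurrenceRanges(c("A", "B", "C"), fad = c(10, 20, 30))
#' dateTreeEqual(topo, occ, root_extension = 10)
#' @export
dateTreeEqual <- function(tree, occurrences, root_extension = 10) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a timeTree/phylo")
  if (!is.numeric(root_extension) || length(root_extension) != 1 ||
      root_extension <= 0) stop("root_extension must be a single value > 0")
  missing <- setdiff(tree$tip.label, occurrences$taxon)
  if (length(missing)) {
    stop("occurrence table missing taxa: ", paste(missing, collapse = ", "))
  }
  fad <- setNames(occurrences$fad, occurrences$taxon)[tree$tip.label]
  if (any(fad < 0)) stop("negative FAD")

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edge <- tree$edge
  age <- numeric(ntip + nnode)
  age[seq_len(ntip)] <- fad
  # postorder: internal node age = oldest descendant FAD
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    age[p] <- max(age[p], age[ch])
  }
  root <- ntip + 1L
  age[root] <- age[root] + root_extension

  parent_of <- integer(ntip + nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  children_of <- split(edge[, 2], factor(edge[, 1], levels = seq_len(ntip + nnode)))

  repeat {
    dur <- age[edge[, 1]] - age[edge[, 2]]
    zero <- which(dur <= 1e-12)
    if (!length(zero)) break
    child0 <- edge[zero[1], 2]
    # ascend through zero-duration branches to the nearest positive ancestor branch
    top <- child0
    while (parent_of[top] != 0 &&
           age[parent_of[top]] - age[top] <= 1e-12) {
      top <- parent_of[top]
    }
    anc <- parent_of[top]          # positive branch anc -> top (root branch is
    stopifnot(anc != 0)            # always positive: root age exceeds all FADs)
    # descend from child0 extending the chain through further zero branches
    bottom <- child0
    repeat {
      kids <- children_of[[bottom]]
      zkid <- kids[age[bottom] - age[kids] <= 1e-12]
      if (!length(zkid)) break
      bottom <- zkid[1]
    }
    chain <- bottom
    while (chain[1] != top) chain <- c(parent_of[chain[1]], chain)
    k <- length(chain) - 1L        # number of zero branches in the chain
    span <- age[anc] - age[bottom]
    # divide span into k+1 equal parts; bottom keeps its age
    new_ages <- age[anc] - seq_len(k) * span / (k + 1)
    age[chain[seq_len(k)]] <- new_ages
  }

  out <- tree
  attr(out, "class") <- "phylo"
  out$edge.length <- age[edge[, 1]] - age[edge[, 2]]
  tt <- timeTree(out, root_age = age[root])
  validateTimeTree(tt)
  tt
}

#' Brownian-motion phylogenetic covariance
#'
#' Expected trait covariances under Brownian motion: entry (i, j) is the
#' duration of the shared root-to-MRCA path of tips i and j, the diagonal the
#' root-to-tip path durations (Myr; multiply by a rate to get trait units).
#'
#' @param tree a dated `timeTree`
#' @return a symmetric positive semi-definite matrix with tip-label dimnames
#' @export
bmCovariance <- function(tree) {
  .assertDated(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda` in `[0, 1]` while leaving
#' the diagonal untouched; `lambda = 1` is pure Brownian covariance, 0 a star
#' phylogeny (no phylogenetic signal in residuals).
#'
#' @param C covariance matrix from [bmCovariance()]
#' @param lambda scalar in `[0, 1]`
#' @export
lambdaTransform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) stop("lambda must be a single value in [0, 1]")
  d <- diag(C)
  out <- C * lambda
  diag(out) <- d
  out
}

#' Export a covariance matrix as labelled CSV
#' @param C matrix with dimnames
#' @param file output path
#' @export
writeCovarianceCSV <- function(C, file) {
  write.csv(as.data.frame(C), file = file, row.names = TRUE)
}
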