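#' Regime painting: a piecewise-constant character history on a tree
#'
#' Stores, for every edge of the tree (ordered as `tree$edge` rows), the
#' ordered list of (state, duration) segments from the rootward end of the
#' branch to its tipward end, plus the per-tip terminal states and the state
#' at every node. Segment durations are positive and tile each branch length;
#' consecutive segments differ in state.
#'
#' @param tree a dated [timeTree()]
#' @param maps list (one element per edge row) of named numeric vectors:
#'   values are durations (Myr), names are states, ordered root -> tip
#' @param states the full state set
#' @param node_states named/indexed character vector of states at every node
#'   (tips first, then internal nodes, ape numbering)
#' @return object of class `regimePainting`
#' @export
regimePainting <- function(tree, maps, states = NULL, node_states = NULL) {
  if (length(maps) != nrow(tree$edge)) stop("one map per edge required")
  if (is.null(states)) states <- sort(unique(unlist(lapply(maps, names))))
  obj <- structure(list(tree = tree, maps = maps, states = states,
                        node_states = node_states),
                   class = "regimePainting")
  validatePainting(obj)
  obj
}

#' @rdname regimePainting
#' @param painting a `regimePainting`
#' @param tol tolerance for the branch-tiling check
#' @export
validatePainting <- function(painting, tol = 1e-9) {
  tree <- painting$tree
  for (i in seq_along(painting$maps)) {
    m <- painting$maps[[i]]
    if (!length(m)) stop("empty map on edge ", i)
    if (any(m <= 0)) stop("non-positive segment duration on edge ", i)
    if (abs(sum(m) - tree$edge.length[i]) > tol * max(1, tree$edge.length[i])) {
      stop("segments do not tile branch length on edge ", i)
    }
    nm <- names(m)
    if (is.null(nm) || any(!nm %in% painting$states)) {
      stop("segment state outside the state set on edge ", i)
    }
    if (length(nm) > 1 && any(nm[-1] == nm[-length(nm)])) {
      stop("consecutive segments share a state on edge ", i)
    }
  }
  invisible(TRUE)
}

#' @rdname regimePainting
#' @export
tipStates <- function(painting) {
  tree <- painting$tree
  ntip <- ape::Ntip(tree)
  tip_edges <- match(seq_len(ntip), tree$edge[, 2])
  st <- vapply(painting$maps[tip_edges],
               function(m) names(m)[length(m)], character(1))
  setNames(st, tree$tip.label)
}

#' @export
print.regimePainting <- function(x, ...) {
  ntrans <- sum(vapply(x$maps, length, 1L) - 1L)
  cat(sprintf("regimePainting: %d states (%s), %d transitions on %d edges\n",
              length(x$states), paste(x$states, collapse = ", "),
              ntrans, length(x$maps)))
  invisible(x)
}

#' Count state transitions in a painting
#' @param painting a `regimePainting`
#' @return total number of state changes across all branches
#' @export
countTransitions <- function(painting) {
  sum(vapply(painting$maps, length, 1L) - 1L)
}

#' Time spent in each state across the whole painting
#' @param painting a `regimePainting`
#' @return named numeric vector of summed durations (Myr)
#' @export
stateDurations <- function(painting) {
  all <- unlist(painting$maps)
  out <- tapply(all, names(all), sum)
  res <- setNames(numeric(length(painting$states)), painting$states)
  res[names(out)] <- out
  res
}

# endpoint-conditioned CTMC path on one branch by uniformization
# returns named duration vector (states as names), root -> tip order
.samplePath <- function(Q, t, a, b, states, Rpow_env) {
  s <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) {
    if (a != b) stop("impossible endpoint pair under a zero rate matrix")
    return(setNames(t, states[a]))
  }
  R <- diag(s) + Q / mu
  P <- .expQt(Q, t)
  pab <- P[a, b]
  if (pab <= 0) stop("numerically zero endpoint probability")
  # R powers are cached in Rpow_env across calls with the same (Q, mu)
  getR <- function(m) {
    key <- as.character(m)
    if (!exists(key, envir = Rpow_env, inherits = FALSE)) {
      assign(key, if (m == 0) diag(s) else getR(m - 1) %*% R, envir = Rpow_env)
    }
    get(key, envir = Rpow_env)
  }
  # sample the number of uniformized events
  u <- runif(1) * pab
  nmax <- max(10, qpois(1 - 1e-12, mu * t) + 10)
  nev <- NA_integer_
  acc <- 0
  for (m in 0:nmax) {
    acc <- acc + dpois(m, mu * t) * getR(m)[a, b]
    if (acc >= u) { nev <- m; break }
  }
  if (is.na(nev)) nev <- nmax
  if (nev == 0) return(setNames(t, states[a]))
  # sample the uniformized chain conditional on endpoints
  chain <- integer(nev + 1); chain[1] <- a; chain[nev + 1] <- b
  if (nev > 1) {
    for (i in 2:nev) {
      prev <- chain[i - 1]
      w <- R[prev, ] * getR(nev - i + 1)[, b]
      chain[i] <- sample.int(s, 1, prob = w)
    }
  } else {
    # single event: chain is (a, b) by construction
  }
  times <- sort(runif(nev)) * t
  # collapse virtual (self) transitions
  keep <- c(TRUE, chain[-1] != chain[-length(chain)])
  st <- chain[keep]
  bounds <- c(0, times[keep[-1]], t)
  durs <- diff(bounds)
  pos <- durs > 0
  setNames(durs[pos], states[st][pos])
}

#' Simulate stochastic character maps (SIMMAP)
#'
#' Samples full character histories conditional on the tip states and a
#' fitted Mk model: node states are drawn from their joint conditional
#' distribution (backward pruning, forward sampling), then each branch
#' history is sampled conditional on its endpoint states by uniformization
#' (guaranteed termination, no rejection). Reproducible under `seed`.
#'
#' @param tree dated [timeTree()]
#' @param model an [mkModel()] or `mkFit`
#' @param tip_states named character vector of observed states
#' @param n_maps number of histories to simulate
#' @param seed optional RNG seed
#' @param root_sample `"conditional"` (default: the root state is drawn from
#'   its joint conditional posterior under the model's root policy) or
#'   `"prior"` (drawn afresh from the root policy weights without
#'   conditioning on the data below)
#' @return list of [regimePainting()] objects, with attribute `root_states`
#' @export
simulateStochasticMaps <- function(tree, model, tip_states, n_maps = 100,
                                   seed = NULL,
                                   root_sample = c("conditional", "prior")) {
  root_sample <- match.arg(root_sample)
  .assertDated(tree)
  if (n_maps < 1) stop("n_maps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Q <- model$Q
  states <- model$states
  policy <- if (!is.null(model$root_policy)) model$root_policy else "fitzjohn"
  pr <- .mkPrune(tree, tip_states, Q)
  if (pr$impossible) stop("tip data are impossible under this model")
  ntip <- ape::Ntip(tree)
  root <- pr$root
  w <- .rootWeights(pr$L[root, ], Q, policy)
  root_post <- if (root_sample == "conditional") w * pr$L[root, ] else w
  if (sum(root_post) <= 0) stop("numerically zero conditional likelihood at the root")
  root_post <- root_post / sum(root_post)

  # preorder edges for forward sampling; P matrices from pruning are in
  # postorder, so re-key them by child node
  P_by_child <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(pr$edge))) P_by_child[[pr$edge[i, 2]]] <- pr$P[[i]]
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_row <- match(paste(pre[, 1], pre[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  Rpow_env <- new.env(parent = emptyenv())

  out <- vector("list", n_maps)
  roots <- character(n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(ntip + tree$Nnode)
    node_state[root] <- sample.int(length(states), 1, prob = root_post)
    maps <- vector("list", nrow(tree$edge))
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1]; ch <- pre[i, 2]
      P <- P_by_child[[ch]]
      wch <- P[node_state[p], ] * pr$L[ch, ]
      if (sum(wch) <= 0) stop("numerically zero conditional likelihood on an edge")
      node_state[ch] <- sample.int(length(states), 1, prob = wch)
      maps[[edge_row[i]]] <- .samplePath(Q, tree$edge.length[edge_row[i]],
                                         node_state[p], node_state[ch],
                                         states, Rpow_env)
    }
    out[[m]] <- regimePainting(tree, maps, states = states,
                               node_states = states[node_state])
    roots[m] <- states[node_state[root]]
  }
  attr(out, "root_states") <- roots
  out
}

#' Subsample stochastic maps without replacement
#'
#' @param paintings list of `regimePainting`s
#' @param m number to keep (`m <= length(paintings)`)
#' @param seed optional RNG seed (fixed seed gives an identical subset)
#' @return list of `m` paintings
#' @export
sampleMaps <- function(paintings, m, seed = NULL) {
  if (m > length(paintings)) stop("cannot sample more maps than available")
  if (m == length(paintings)) return(paintings)
  if (!is.null(seed)) set.seed(seed)
  paintings[sort(sample.int(length(paintings), m))]
}

#' Serialise a painting as a per-branch segment table
#'
#' One row per segment: edge index, parent and child node, start offset from
#' the rootward end of the branch, duration and state.
#'
#' @param painting a `regimePainting`
#' @param file optional CSV path; when `NULL` the data.frame is returned
#' @export
paintingToTable <- function(painting, file = NULL) {
  tree <- painting$tree
  rows <- lapply(seq_along(painting$maps), function(i) {
    m <- painting$maps[[i]]
    data.frame(edge = i, parent = tree$edge[i, 1], child = tree$edge[i, 2],
               start = cumsum(c(0, unname(m)))[seq_along(m)],
               duration = unname(m), state = names(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(file)) out else write.csv(out, file, row.names = FALSE)
}

#' Export a painting as SIMMAP-annotated Newick
#'
#' Branches are annotated `{state,duration:state,duration:...}` from the
#' tipward to the rootward end (the SIMMAP v1.0 convention;
#' `phytools::read.simmap(..., version = 1)` parses it).
#'
#' @param painting a `regimePainting`
#' @return a single Newick string
#' @export
paintingToNewick <- function(painting) {
  tree <- painting$tree
  ntip <- ape::Ntip(tree)
  child_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(e) {
    m <- rev(painting$maps[[e]])  # tipward first in the SIMMAP convention
    paste0("{", paste(sprintf("%s,%.9g", names(m), unname(m)), collapse = ":"), "}")
  }
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- child_edges[[as.character(node)]]
    paste0("(", paste(vapply(kids, function(e) {
      paste0(rec(tree$edge[e, 2]), ":", lab(e))
    }, character(1)), collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}
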