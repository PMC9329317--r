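#' Mk model of discrete character evolution
#'
#' Builds a continuous-time Markov rate matrix Q (per Myr) over an ordered
#' state set under one of three constraint classes: ER (equal rates, one free
#' rate), SYM (symmetric exchange rates, s(s-1)/2 free) or ARD (all s(s-1)
#' off-diagonal rates free). Rows of Q sum to zero.
#'
#' @param states character vector of state labels
#' @param constraint "ER", "SYM" or "ARD"
#' @param rates free-rate vector in the constraint's canonical order: ER a
#'   single rate; SYM the upper triangle column-wise (pairs (1,2), (1,3),
#'   (2,3), ...); ARD the off-diagonal entries column-wise
#' @param root_policy root-state treatment for likelihoods: "fitzjohn"
#'   (conditional-likelihood-weighted, default), "flat" or "stationary"
#' @return object of class `mkModel` with elements `states`, `constraint`,
#'   `Q`, `rates`, `root_policy`
#' @export
mkModel <- function(states, constraint = c("ER", "SYM", "ARD"), rates,
                    root_policy = c("fitzjohn", "flat", "stationary")) {
  constraint <- match.arg(constraint)
  root_policy <- match.arg(root_policy)
  s <- length(states)
  if (s < 2) stop("need at least 2 states")
  if (any(rates < 0)) stop("rates must be non-negative")
  np <- nMkParams(s, constraint)
  if (length(rates) != np) {
    stop(sprintf("%s with %d states needs %d rate(s), got %d",
                 constraint, s, np, length(rates)))
  }
  Q <- matrix(0, s, s, dimnames = list(states, states))
  if (constraint == "ER") {
    Q[] <- rates[1]
  } else if (constraint == "SYM") {
    Q[upper.tri(Q)] <- rates
    Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
  } else {
    off <- !diag(s)
    Q[off] <- rates  # column-wise over off-diagonal entries
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(states = states, constraint = constraint, Q = Q,
                 rates = rates, root_policy = root_policy),
            class = "mkModel")
}

#' @rdname mkModel
#' @param s number of states
#' @export
nMkParams <- function(s, constraint) {
  switch(constraint, ER = 1L, SYM = as.integer(s * (s - 1) / 2),
         ARD = as.integer(s * (s - 1)), stop("unknown constraint"))
}

#' @export
print.mkModel <- function(x, ...) {
  cat(sprintf("Mk model (%s) over %d states: %s\n", x$constraint,
              length(x$states), paste(x$states, collapse = ", ")))
  print(round(x$Q, 6))
  invisible(x)
}

# transition probability matrix exp(Q t); eigendecomposition with a
# scaling-and-squaring fallback for defective Q. A precomputed
# eigendecomposition (.eigQ) can be reused across many branch lengths.
.eigQ <- function(Q) {
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  list(V = eg$vectors, values = eg$values, Vi = Vi)
}

.expQt <- function(Q, t, eg = NULL) {
  s <- nrow(Q)
  if (t == 0 || all(Q == 0)) return(diag(s))
  if (is.null(eg)) eg <- .eigQ(Q)
  P <- if (is.null(eg)) NULL else {
    M <- Re(eg$V %*% (exp(eg$values * t) * eg$Vi))
    if (any(!is.finite(M))) NULL else M
  }
  if (is.null(P) || any(P < -1e-8)) {
    # scaling and squaring with a Taylor core
    A <- Q * t
    j <- max(0L, ceiling(log2(max(abs(A)) + 1e-300)) + 4L)
    A <- A / 2^j
    P <- diag(s); term <- diag(s)
    for (m in 1:16) { term <- term %*% A / m; P <- P + term }
    for (m in seq_len(j)) P <- P %*% P
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

.stationaryDist <- function(Q) {
  s <- nrow(Q)
  if (all(Q == 0)) return(rep(1 / s, s))
  A <- rbind(t(Q), rep(1, s))
  pi_ <- qr.solve(A, c(rep(0, s), 1))
  pi_[pi_ < 0] <- 0
  pi_ / sum(pi_)
}

# Felsenstein pruning; returns per-node scaled partials and log scale factors.
# tip_states: named character vector; tree: dated timeTree; Q with dimnames.
.mkPrune <- function(tree, tip_states, Q) {
  states <- rownames(Q)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tip_states <- .alignToTips(tip_states, tree, "tip states")
  bad <- setdiff(unique(tip_states), states)
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  L <- matrix(0, ntip + nnode, length(states))
  L[cbind(seq_len(ntip), match(tip_states, states))] <- 1
  L[(ntip + 1):(ntip + nnode), ] <- 1
  logscale <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge; elen <- po$edge.length
  eg <- .eigQ(Q)
  Pmats <- vector("list", nrow(edge))
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    P <- .expQt(Q, elen[i], eg = eg)
    Pmats[[i]] <- P
    L[p, ] <- L[p, ] * as.vector(P %*% L[ch, ])
    sc <- sum(L[p, ])
    if (sc <= 0) return(list(impossible = TRUE, logscale = -Inf))
    L[p, ] <- L[p, ] / sc
    logscale <- logscale + log(sc)
  }
  root <- ntip + 1L
  list(impossible = FALSE, L = L, logscale = logscale, root = root,
       edge = edge, elen = elen, P = Pmats, states = states)
}

.rootWeights <- function(Lroot, Q, policy) {
  switch(policy,
    fitzjohn = if (sum(Lroot) > 0) Lroot / sum(Lroot) else Lroot,
    flat = rep(1 / length(Lroot), length(Lroot)),
    stationary = .stationaryDist(Q))
}

#' Mk log-likelihood of tip states on a dated tree
#'
#' Felsenstein pruning with per-branch transition probabilities
#' `P(t) = exp(Q t)`; the root is combined under the model's root policy
#' (default FitzJohn-style conditional-likelihood weighting).
#'
#' @param tree dated [timeTree()]
#' @param tip_states named character vector of observed states
#' @param model an [mkModel()] (or a rate matrix with dimnames)
#' @return log-likelihood (`-Inf` when the data are impossible, e.g. q = 0
#'   with differing tip states)
#' @export
mkLoglik <- function(tree, tip_states, model) {
  .assertDated(tree)
  Q <- if (inherits(model, "mkModel")) model$Q else model
  policy <- if (inherits(model, "mkModel")) model$root_policy else "fitzjohn"
  pr <- .mkPrune(tree, tip_states, Q)
  if (pr$impossible) return(-Inf)
  Lroot <- pr$L[pr$root, ]
  w <- .rootWeights(Lroot, Q, policy)
  lik <- sum(w * Lroot)
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Maximum-likelihood Mk model fit
#'
#' Rates are optimised on the log scale with a small multi-start budget.
#' Parameter counts for AICc (n = number of tips): ER 1, SYM s(s-1)/2,
#' ARD s(s-1).
#'
#' @inheritParams mkLoglik
#' @param states optional state set (default: observed states, sorted)
#' @param constraint "ER", "SYM" or "ARD"
#' @param root_policy see [mkModel()]
#' @param n_starts number of multi-starts around the heuristic initial rate
#' @return object of class `mkFit`: the fitted `mkModel` plus `logL`, `k`,
#'   `n`, `AICc`, `root` (posterior state weights at the root and the ML
#'   root state), `convergence`
#' @export
fitMkModel <- function(tree, tip_states, constraint = c("ER", "SYM", "ARD"),
                       states = NULL, root_policy = "fitzjohn", n_starts = 3) {
  constraint <- match.arg(constraint)
  .assertDated(tree)
  tip_states <- .alignToTips(tip_states, tree, "tip states")
  if (is.null(states)) states <- sort(unique(tip_states))
  if (length(unique(tip_states)) < 2) {
    # degenerate data: the ML rate is 0
    model <- mkModel(states, constraint,
                     rates = rep(0, nMkParams(length(states), constraint)),
                     root_policy = root_policy)
    ll <- mkLoglik(tree, tip_states, model)
    k <- nMkParams(length(states), constraint)
    n <- ape::Ntip(tree)
    return(structure(c(model, list(logL = ll, k = k, n = n,
                                   AICc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
                                   root = .mkRoot(tree, tip_states, model),
                                   convergence = 0L)),
                     class = c("mkFit", "mkModel")))
  }
  s <- length(states)
  np <- nMkParams(s, constraint)
  n <- ape::Ntip(tree)
  treelen <- sum(tree$edge.length)
  q0 <- s / treelen  # one expected change per state over the whole tree

  nll <- function(logr) {
    m <- try(mkModel(states, constraint, exp(logr), root_policy), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    ll <- mkLoglik(tree, tip_states, m)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # coarse grid on a shared rate guards against the q -> Inf saturation
  # plateau, where gradient methods stall
  grid <- log(q0) + seq(-4, 6, length.out = 21) * log(10) / 2
  gval <- vapply(grid, function(g) nll(rep(g, np)), 0)
  gbest <- grid[which.min(gval)]
  starts <- c(list(rep(gbest, np)),
              lapply(seq_len(max(0, n_starts - 1)), function(i) {
                rep(gbest + (-1)^i * ceiling(i / 2) * log(10) / 2, np)
              }))
  best <- NULL
  for (start in starts) {
    opt <- try(optim(start, nll, method = "L-BFGS-B",
                     lower = log(1e-9), upper = log(1e4),
                     control = list(maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("Mk optimisation failed to converge")
  model <- mkModel(states, constraint, exp(best$par), root_policy)
  ll <- -best$value
  structure(c(model, list(logL = ll, k = np, n = n,
                          AICc = if (n > np + 1) aicc(ll, np, n) else NA_real_,
                          root = .mkRoot(tree, tip_states, model),
                          convergence = best$convergence)),
            class = c("mkFit", "mkModel"))
}

# root-state posterior weights under the model's root policy + ML root state
.mkRoot <- function(tree, tip_states, model) {
  pr <- .mkPrune(tree, tip_states, model$Q)
  if (pr$impossible) return(list(posterior = NULL, ml_state = NA_character_))
  Lroot <- pr$L[pr$root, ]
  w <- .rootWeights(Lroot, model$Q, model$root_policy)
  post <- w * Lroot
  if (sum(post) > 0) post <- post / sum(post)
  names(post) <- model$states
  list(posterior = post, ml_state = model$states[which.max(post)])
}

#' @export
print.mkFit <- function(x, ...) {
  cat(sprintf("Mk %s fit: logL = %.4f, k = %d, AICc = %.4f, ML root state = %s\n",
              x$constraint, x$logL, x$k, x$AICc, x$root$ml_state))
  print(round(x$Q, 6))
  invisible(x)
}

#' Compare ER, SYM and ARD Mk fits by AICc
#'
#' @inheritParams fitMkModel
#' @return a [akaikeWeights()] `modelComparison` with attribute `fits`
#'   (the three `mkFit` objects); ties resolve to fewer parameters
#' @export
selectMkModel <- function(tree, tip_states, states = NULL,
                          root_policy = "fitzjohn", n_starts = 3) {
  fits <- lapply(c(ER = "ER", SYM = "SYM", ARD = "ARD"), function(con) {
    fitMkModel(tree, tip_states, con, states = states,
               root_policy = root_policy, n_starts = n_starts)
  })
  cmp <- akaikeWeights(vapply(fits, `[[`, 0, "AICc"),
                       k = vapply(fits, `[[`, 0L, "k"))
  attr(cmp, "fits") <- fits
  cmp
}

#' Read tip states from CSV (columns taxon, state)
#' @param file path to CSV
#' @return named character vector
#' @export
readTipStates <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(d))) {
    stop("tip-state CSV needs columns taxon, state")
  }
  setNames(as.character(d$state), d$taxon)
}
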