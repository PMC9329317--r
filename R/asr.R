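#' Ancestral state reconstruction of a continuous trait under Brownian motion
#'
#' Maximum-likelihood (equivalently GLS) estimates of the trait at every
#' internal node under single-rate Brownian motion. The root estimate is the
#' GLS phylogenetic mean; internal-node estimates are the conditional
#' expectations given the tip values; sigma^2 is estimated by REML and
#' scales the node variances (which include the uncertainty in the
#' phylogenetic mean). Estimates are invariant to adding a constant to all
#' tip values.
#'
#' @param tree dated [timeTree()]
#' @param trait named numeric vector of tip values (all tips required)
#' @return object of class `ancestralEstimates`: data.frame `nodes`
#'   (node id, estimate, variance; ape numbering, root first) plus `root`,
#'   `sigma2` (REML) and `logL`
#' @examples
#' tr <- readNewickTree("((A:1,B:1):1,C:2);")
#' asrBM(tr, c(A = 0, B = 2, C = 1))
#' @export
asrBM <- function(tree, trait) {
  .assertDated(tree)
  y <- .alignToTips(trait, tree, "trait")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  depths <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)   # over all nodes
  Call <- matrix(depths[M], nrow(M), ncol(M))
  tip_i <- seq_len(ntip)
  int_i <- setdiff(seq_len(ntip + nnode), c(tip_i, root))
  Cyy <- Call[tip_i, tip_i]
  one <- rep(1, ntip)

  U <- chol(Cyy)
  wy <- backsolve(U, y, transpose = TRUE)
  w1 <- backsolve(U, one, transpose = TRUE)
  denom <- sum(w1^2)
  mu <- sum(w1 * wy) / denom          # GLS phylogenetic mean = root estimate
  r <- y - mu
  wr <- backsolve(U, r, transpose = TRUE)
  sigma2 <- sum(wr^2) / (ntip - 1)    # REML scale
  logL <- -ntip / 2 * log(2 * pi) - sum(log(diag(U))) -
    ntip / 2 * log(max(sum(wr^2) / ntip, .Machine$double.xmin)) - ntip / 2

  est <- numeric(nnode); v <- numeric(nnode)
  est[1] <- mu
  v[1] <- sigma2 / denom              # variance of the phylogenetic mean
  if (length(int_i)) {
    Czy <- Call[int_i, tip_i, drop = FALSE]
    Wz <- t(backsolve(U, t(Czy), transpose = TRUE))  # Czy Uinv'
    cond_mean <- mu + as.vector(Wz %*% wr)
    czz <- depths[int_i]
    cond_var <- czz - rowSums(Wz^2)
    # add uncertainty from estimating the phylogenetic mean
    h <- 1 - as.vector(Wz %*% w1)
    var_full <- sigma2 * pmax(cond_var, 0) + h^2 * (sigma2 / denom)
    idx <- int_i - ntip
    est[idx] <- cond_mean
    v[idx] <- var_full
  }
  nodes <- data.frame(node = (ntip + 1L):(ntip + nnode),
                      estimate = est, variance = v)
  structure(list(nodes = nodes, root = mu, sigma2 = sigma2, logL = logL),
            class = "ancestralEstimates")
}

#' @export
print.ancestralEstimates <- function(x, ...) {
  cat(sprintf("BM ancestral state estimates at %d nodes (sigma2 REML = %.6g)\n",
              nrow(x$nodes), x$sigma2))
  print(utils::head(x$nodes, 10))
  if (nrow(x$nodes) > 10) cat("...\n")
  invisible(x)
}

#' Export ancestral estimates
#'
#' `asrToCSV` writes the node table; `asrAnnotatedNewick` returns a Newick
#' string with node labels set to the estimates (along-branch interpolation
#' for gradient plots is linear in time between node estimates and is
#' export-only, not part of the inference).
#'
#' @param asr an `ancestralEstimates`
#' @param tree the tree used for the reconstruction
#' @param file CSV path
#' @param digits label precision
#' @export
asrToCSV <- function(asr, file) {
  write.csv(asr$nodes, file, row.names = FALSE)
}

#' @rdname asrToCSV
#' @export
asrAnnotatedNewick <- function(asr, tree, digits = 6) {
  phy <- tree
  attr(phy, "class") <- "phylo"
  phy$node.label <- formatC(asr$nodes$estimate, digits = digits, format = "g")
  ape::write.tree(phy)
}
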