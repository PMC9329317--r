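# small fixtures shared across test files; everything is built in code

cherryTree <- function(t = 1) {
  readNewickTree(sprintf("(A:%g,B:%g);", t, t))
}

balanced4 <- function() {
  readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
}

starTree <- function(n, depth = 1) {
  readNewickTree(paste0("(", paste(sprintf("t%d:%g", seq_len(n), depth),
                                   collapse = ","), ");"))
}

unitCube <- function() {
  as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
}

# whole tree painted with a single regime
onePainting <- function(tree, state = "all") {
  skelevol:::.singleRegimePainting(tree, state)
}

# brute-force Mk likelihood by summing over all internal-node assignments
enumMkLoglik <- function(tree, tip_states, Q, root = c("flat", "fitzjohn")) {
  root <- match.arg(root)
  states <- rownames(Q)
  s <- length(states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  Ps <- lapply(tree$edge.length, function(t) skelevol:::.expQt(Q, t))
  tipidx <- match(tip_states[tree$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), nnode)))
  per_root <- numeric(s)
  for (r in seq_len(nrow(grid))) {
    st <- c(tipidx, grid[r, ])
    lik <- 1
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    per_root[grid[r, 1]] <- per_root[grid[r, 1]] + lik
  }
  # grid column 1 is the root (node ntip + 1) by expand.grid construction
  if (root == "flat") {
    log(sum(per_root / s))
  } else {
    log(sum(per_root * per_root / sum(per_root)))
  }
}
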