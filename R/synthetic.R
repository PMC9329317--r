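#' Simulate a pure-birth (Yule) time tree, optionally with fossil tips
#'
#' Forward simulation: two lineages from the root, exponential waits
#' (rate k x birth_rate while k lineages are extant) until `n_tips`
#' lineages exist, plus a final observation wait of Exp(n x birth_rate), so
#' the expected root-to-tip depth is
#' `sum(1/(k b), k = 2..n-1) + 1/(n b)`. A fraction of tips can then be
#' truncated to positive ages to emulate non-contemporaneous fossil tips
#' (the default study preset uses the 92/410 extinct/total ratio of a large
#' tetrapod skeletal dataset).
#'
#' @param n_tips number of tips (>= 2)
#' @param birth_rate speciation rate per Myr (> 0)
#' @param seed optional RNG seed
#' @param extinct_fraction fraction of tips truncated to positive age, in
#'   `[0, 1)`
#' @return a dated [timeTree()]
#' @export
simYuleTree <- function(n_tips, birth_rate = 0.25, seed = NULL,
                        extinct_fraction = 0) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (extinct_fraction < 0 || extinct_fraction >= 1) {
    stop("extinct_fraction must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  # grow the tree: nodes are created at split times; active lineages carry
  # their birth time until they split or the simulation stops
  max_nodes <- 2L * n_tips
  parent <- integer(max_nodes); birth <- numeric(max_nodes)
  split_time <- rep(NA_real_, max_nodes)
  nn <- 3L
  parent[2:3] <- 1L; birth[2:3] <- 0; birth[1] <- 0
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + rexp(1, k * birth_rate)
    who <- active[sample.int(k, 1)]
    split_time[who] <- t
    c1 <- nn + 1L; c2 <- nn + 2L; nn <- nn + 2L
    parent[c(c1, c2)] <- who; birth[c(c1, c2)] <- t
    active <- c(setdiff(active, who), c1, c2)
  }
  t <- t + rexp(1, n_tips * birth_rate)
  depth <- t

  is_tip <- seq_len(nn) %in% active
  tip_ids <- which(is_tip); int_ids <- which(!is_tip)
  new_id <- integer(nn)
  new_id[tip_ids] <- seq_len(n_tips)
  new_id[int_ids] <- n_tips + seq_along(int_ids)
  end_time <- ifelse(is_tip, depth, split_time)
  keep <- seq_len(nn)[-1]
  edge <- cbind(new_id[parent[keep]], new_id[keep])
  elen <- end_time[keep] - birth[keep]
  phy <- structure(list(edge = edge, edge.length = elen,
                        Nnode = length(int_ids),
                        tip.label = paste0("t", seq_len(n_tips))),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")

  if (extinct_fraction > 0) {
    m <- round(extinct_fraction * n_tips)
    if (m > 0) {
      fossil <- sample.int(n_tips, m)
      term <- match(fossil, phy$edge[, 2])
      cut <- runif(m, 0.1, 0.9)
      phy$edge.length[term] <- phy$edge.length[term] * cut
    }
  }
  timeTree(phy, root_age = depth)
}

#' Simulate a discrete regime character forward along a tree
#'
#' Forward continuous-time Markov simulation from a root state drawn from
#' the stationary distribution of Q (uniform when Q = 0). Returns both the
#' observed tip states and the true branch-by-branch painting, so regime
#' inference can be validated against a known history.
#'
#' @param tree dated [timeTree()]
#' @param Q rate matrix with state dimnames (e.g. from [mkModel()])
#' @param seed optional RNG seed
#' @return list with `tip_states` (named character) and `painting`
#'   ([regimePainting()])
#' @export
simDiscrete <- function(tree, Q, seed = NULL) {
  if (inherits(Q, "mkModel")) Q <- Q$Q
  if (is.null(rownames(Q))) stop("Q needs state dimnames")
  if (any(Q[!diag(nrow(Q)) == 1] < 0) || any(abs(rowSums(Q)) > 1e-8)) {
    stop("invalid rate matrix")
  }
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q)
  s <- length(states)
  .assertDated(tree)
  ntip <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_row <- match(paste(pre[, 1], pre[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  root_state <- sample.int(s, 1, prob = .stationaryDist(Q))
  node_state <- integer(ntip + tree$Nnode)
  node_state[ntip + 1L] <- root_state
  maps <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; ch <- pre[i, 2]
    t_total <- tree$edge.length[edge_row[i]]
    cur <- node_state[p]
    segs <- numeric(0); labs <- integer(0)
    remaining <- t_total
    repeat {
      rate <- -Q[cur, cur]
      w <- if (rate > 0) rexp(1, rate) else Inf
      if (w >= remaining) {
        segs <- c(segs, remaining); labs <- c(labs, cur)
        break
      }
      segs <- c(segs, w); labs <- c(labs, cur)
      remaining <- remaining - w
      cur <- sample.int(s, 1, prob = pmax(Q[cur, ], 0) * (seq_len(s) != cur))
    }
    maps[[edge_row[i]]] <- setNames(segs, states[labs])
    node_state[ch] <- cur
  }
  painting <- regimePainting(tree, maps, states = states,
                             node_states = states[node_state])
  list(tip_states = tipStates(painting), painting = painting)
}

#' Simulate a continuous trait under a regime model
#'
#' Recursive simulation using the exact per-epoch OU transition
#' distribution: over an epoch of duration d in regime r,
#' `x' = x e^(-a d) + theta (1 - e^(-a d)) + N(0, s2 (1 - e^(-2 a d))/(2 a))`
#' with the Brownian limit at a = 0. The sample moments converge to
#' [ouMoments()], which is the cornerstone cross-validation of the regime
#' model likelihoods.
#'
#' @inheritParams ouMoments
#' @param model model name used to validate the parameter sharing pattern
#'   (optional, see [regimeModelNames])
#' @param seed optional RNG seed
#' @return named numeric vector of tip values
#' @export
simTrait <- function(tree, painting, params, model = NULL, seed = NULL) {
  prep <- .regimePrep(tree, painting)
  p <- regimeParams(params$sigma2, params$alpha, params$theta, params$y0,
                    regimes = prep$states)
  if (!is.null(model)) {
    sh <- .modelSharing(model)
    eq <- function(v) diff(range(v)) <= 1e-12 * max(1, max(abs(v)))
    if (!sh$multi_sigma && !eq(p$sigma2)) stop(model, " requires shared sigma2")
    if (!sh$multi_alpha && !eq(p$alpha)) stop(model, " requires shared alpha")
    if (!sh$ou && any(p$alpha != 0)) stop(model, " requires alpha = 0")
  }
  if (!is.null(seed)) set.seed(seed)
  y0 <- if (is.null(p$y0)) p$theta[prep$root_regime] else p$y0
  if (is.na(y0)) stop("root value y0 undefined")
  nn <- prep$ntip + prep$nnode
  val <- numeric(nn)
  val[prep$root] <- y0
  for (i in seq_len(nrow(prep$pre))) {
    pa <- prep$pre[i, 1]; ch <- prep$pre[i, 2]
    x <- val[pa]
    sg <- prep$segs[[prep$edge_row[i]]]
    for (k in seq_along(sg$d)) {
      st <- sg$st[k]; d <- sg$d[k]
      a <- p$alpha[st]; s2 <- p$sigma2[st]; th <- p$theta[st]
      if (a > 0) {
        e1 <- exp(-a * d)
        x <- x * e1 + th * (1 - e1) +
          rnorm(1, 0, sqrt(s2 * (1 - e1^2) / (2 * a)))
      } else {
        x <- x + rnorm(1, 0, sqrt(s2 * d))
      }
    }
    val[ch] <- x
  }
  setNames(val[seq_len(prep$ntip)], tree$tip.label)
}

#' Simulate a log-log allometric relationship with phylogenetic residuals
#'
#' log-size `x` evolves under Brownian motion on the tree;
#' `y = intercept + slope x + e` with `e` itself Brownian-distributed
#' (rate `sigma2_resid`), so PGLS with lambda = 1 is the correctly specified
#' estimator. The preset `slope = 1/3` mimics isometric scaling of a linear
#' segment measure against a volumetric size proxy on log-log axes.
#'
#' @param tree dated [timeTree()]
#' @param slope,intercept regression parameters on the log-log scale
#' @param sigma2_resid Brownian rate of the residuals (> 0)
#' @param sigma2_x Brownian rate of log-size (default 1)
#' @param x0 root value of log-size (default 0)
#' @param seed optional RNG seed
#' @return list with named vectors `x` and `y`
#' @export
simAllometry <- function(tree, slope = 1 / 3, intercept = 0,
                         sigma2_resid = 0.01, sigma2_x = 1, x0 = 0,
                         seed = NULL) {
  if (sigma2_resid <= 0 || sigma2_x <= 0) stop("variances must be > 0")
  if (!is.null(seed)) set.seed(seed)
  one <- .singleRegimePainting(tree)
  x <- simTrait(tree, one, regimeParams(sigma2 = sigma2_x, alpha = 0,
                                        theta = 0, y0 = x0))
  e <- simTrait(tree, one, regimeParams(sigma2 = sigma2_resid, alpha = 0,
                                        theta = 0, y0 = 0))
  list(x = x, y = intercept + slope * x + e)
}

# trivial painting: the whole tree in one regime
.singleRegimePainting <- function(tree, state = "all") {
  maps <- lapply(tree$edge.length, function(d) setNames(d, state))
  regimePainting(tree, maps, states = state)
}

#' Synthetic meshes with known hull volume
#'
#' `cuboid`: the 8 corners of a box (volume = product of dimensions, exact).
#' `ellipsoid`: a Fibonacci-lattice tessellation of the surface; the hull
#' volume approaches `4/3 pi a b c` from below with relative tolerance about
#' 1e-3 at the default 10,000 surface points. `frustum`: two parallel
#' regular n-gon rings (volume exact for the polygonal frustum:
#' `h/3 (A1 + A2 + sqrt(A1 A2))`). Optional interior noise points never
#' change the hull volume.
#'
#' @param shape "cuboid", "ellipsoid" or "frustum"
#' @param dimensions cuboid: c(lx, ly, lz); ellipsoid: semi-axes c(a, b, c);
#'   frustum: c(r_bottom, r_top, height)
#' @param n_noise_points interior points to add (uniform in an inscribed box)
#' @param n_surface surface points for the ellipsoid (default 10000) or
#'   vertices per ring for the frustum (default 96)
#' @param seed optional RNG seed
#' @return list with `mesh` ([hullMesh()]), `volume` (known value) and
#'   `rel_tol` (guaranteed relative accuracy of `volume` for the hull)
#' @export
simMesh <- function(shape = c("cuboid", "ellipsoid", "frustum"),
                    dimensions, n_noise_points = 0, n_surface = NULL,
                    seed = NULL) {
  shape <- match.arg(shape)
  if (any(dimensions <= 0)) stop("dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (shape == "cuboid") {
    if (length(dimensions) != 3) stop("cuboid needs c(lx, ly, lz)")
    v <- as.matrix(expand.grid(c(0, dimensions[1]), c(0, dimensions[2]),
                               c(0, dimensions[3])))
    vol <- prod(dimensions); tol <- 0
    inner <- dimensions
  } else if (shape == "ellipsoid") {
    if (length(dimensions) != 3) stop("ellipsoid needs semi-axes c(a, b, c)")
    if (is.null(n_surface)) n_surface <- 10000L
    i <- seq_len(n_surface) - 0.5
    phi <- acos(1 - 2 * i / n_surface)
    th <- pi * (1 + sqrt(5)) * i
    v <- cbind(dimensions[1] * sin(phi) * cos(th),
               dimensions[2] * sin(phi) * sin(th),
               dimensions[3] * cos(phi))
    vol <- 4 / 3 * pi * prod(dimensions)
    tol <- 1e-3
    inner <- dimensions / sqrt(3)
  } else {
    if (length(dimensions) != 3) stop("frustum needs c(r_bottom, r_top, height)")
    if (is.null(n_surface)) n_surface <- 96L
    ang <- 2 * pi * (seq_len(n_surface) - 1) / n_surface
    v <- rbind(cbind(dimensions[1] * cos(ang), dimensions[1] * sin(ang), 0),
               cbind(dimensions[2] * cos(ang), dimensions[2] * sin(ang),
                     dimensions[3]))
    apoly <- function(r) n_surface / 2 * r^2 * sin(2 * pi / n_surface)
    a1 <- apoly(dimensions[1]); a2 <- apoly(dimensions[2])
    vol <- dimensions[3] / 3 * (a1 + a2 + sqrt(a1 * a2))
    tol <- 0
    inner <- c(min(dimensions[1:2]) / 2, min(dimensions[1:2]) / 2,
               dimensions[3]) * 0.9
  }
  if (n_noise_points > 0) {
    centre <- colMeans(v)
    noise <- sweep(matrix(runif(3 * n_noise_points, -0.5, 0.5),
                          ncol = 3) %*% diag(inner * 0.9), 2, centre, `+`)
    v <- rbind(v, noise)
  }
  list(mesh = hullMesh(v), volume = vol, rel_tol = tol, shape = shape)
}

#' Simulate fossil occurrence ranges consistent with a dated tree
#'
#' FAD = tip age plus a small positive jitter, LAD = tip age; stripping the
#' branch lengths and re-dating with [dateTreeEqual()] then yields a tree
#' whose tip ages equal the FADs.
#'
#' @param tree dated [timeTree()]
#' @param jitter upper bound of the uniform FAD jitter (Myr; 0 = FAD equals
#'   tip age)
#' @param seed optional RNG seed
#' @return an [occurrenceRanges()] table
#' @export
simOccurrences <- function(tree, jitter = 0, seed = NULL) {
  .assertDated(tree)
  if (!is.null(seed)) set.seed(seed)
  ages <- tipAges(tree)
  fad <- ages + if (jitter > 0) runif(length(ages), 0, jitter) else 0
  occurrenceRanges(names(ages), fad = unname(fad), lad = unname(ages))
}

#' Generate a complete synthetic study
#'
#' Produces a mutually consistent set of inputs with the statistical
#' structure the analysis pipeline assumes: a Yule tree with fossil tips
#' (default 200 tips, extinct fraction 92/410), an ER diet character with
#' about `target_transitions` expected transitions, a body-size trait
#' (log10 WBCHV) evolving under a chosen regime model, allometrically
#' related segment measures with Brownian residuals, and a segment table
#' whose per-segment volumes sum to WBCHV.
#'
#' @param n_tips number of taxa
#' @param states diet regime labels
#' @param model regime model generating log10 body size (default "OUM")
#' @param params [regimeParams()] for the body-size trait; default: theta
#'   spread over regimes, shared alpha scaled so alpha x depth is about 3
#' @param target_transitions expected number of diet transitions on the tree
#' @param extinct_fraction fraction of fossil tips
#' @param birth_rate Yule speciation rate
#' @param seed RNG seed (the whole study is reproducible from it)
#' @return object of class `syntheticStudy`: `tree`, `diet` (tip states),
#'   `painting` (true history), `trait` (log10 WBCHV), `segments`
#'   (a [assembleSegmentTable()] table), `allometry` (true slopes and
#'   intercepts), `params`, `seed`
#' @export
makeSyntheticStudy <- function(n_tips = 200,
                               states = c("carnivore", "herbivore",
                                          "insectivore", "omnivore",
                                          "piscivore"),
                               model = "OUM", params = NULL,
                               target_transitions = 15,
                               extinct_fraction = 92 / 410,
                               birth_rate = 0.25, seed = 1) {
  set.seed(seed)
  tree <- simYuleTree(n_tips, birth_rate, extinct_fraction = extinct_fraction)
  depth <- max(ape::node.depth.edgelength(tree))
  s <- length(states)
  q <- target_transitions / ((s - 1) * sum(tree$edge.length))
  Q <- mkModel(states, "ER", rates = q)$Q
  disc <- simDiscrete(tree, Q)
  if (is.null(params)) {
    params <- regimeParams(sigma2 = 0.02, alpha = 3 / depth,
                           theta = seq(-0.5, 0.5, length.out = s),
                           regimes = states)
  }
  trait <- simTrait(tree, disc$painting, params, model = model)

  # segment allometries around log10 WBCHV: lengths isometric at 1/3 with
  # mild deviations, volumes isometric at 1
  one <- .singleRegimePainting(tree)
  lin_slopes <- c(GA = 0.34, FL = 0.33, SL = 0.32, MtL = 0.30, PL = 0.29,
                  HL = 0.33, FaL = 0.32, McL = 0.30, ML = 0.29)
  lin_inter <- c(GA = -0.3, FL = -0.5, SL = -0.55, MtL = -0.8, PL = -0.85,
                 HL = -0.5, FaL = -0.55, McL = -0.85, ML = -0.9)
  wbchv <- 10^trait
  linear <- data.frame(taxon = tree$tip.label)
  for (nm in names(lin_slopes)) {
    e <- simTrait(tree, one, regimeParams(sigma2 = 0.003, alpha = 0,
                                          theta = 0, y0 = 0))
    linear[[nm]] <- 10^(lin_inter[[nm]] + lin_slopes[[nm]] * trait + e)
  }
  shares <- c(skull = 0.12, neck = 0.06, trunk = 0.45, tail = 0.08,
              humerus = 0.04, forearm = 0.03, metacarpal = 0.01,
              manus = 0.01, femur = 0.09, shank = 0.06, metatarsal = 0.03,
              pes = 0.02)
  volumes <- data.frame(taxon = tree$tip.label)
  sharemat <- vapply(names(shares), function(nm) {
    shares[[nm]] * exp(rnorm(n_tips, 0, 0.15))
  }, numeric(n_tips))
  sharemat <- sharemat / rowSums(sharemat)
  for (nm in names(shares)) volumes[[nm]] <- wbchv * sharemat[, nm]
  segments <- assembleSegmentTable(linear, volumes)

  structure(list(tree = tree, diet = disc$tip_states,
                 painting = disc$painting, trait = trait,
                 segments = segments,
                 allometry = list(slopes = lin_slopes, intercepts = lin_inter,
                                  sigma2_resid = 0.003),
                 Q = Q, params = params, model = model, seed = seed),
            class = "syntheticStudy")
}

#' @export
print.syntheticStudy <- function(x, ...) {
  cat("syntheticStudy:", ape::Ntip(x$tree), "taxa, seed", x$seed, "\n")
  cat("  diet states:", paste(names(table(x$diet)), collapse = ", "), "\n")
  cat("  true diet transitions:", countTransitions(x$painting), "\n")
  cat("  body-size model:", x$model, "\n")
  invisible(x)
}

#' Materialise a synthetic study as a fixture directory
#'
#' Writes the tree (Newick), occurrences, segment table, ecology labels and
#' true trait values in the CSV/Newick schemas the pipeline consumes.
#'
#' @param study a [makeSyntheticStudy()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNewickTree(study$tree, file.path(dir, "tree.nwk"))
  occ <- simOccurrences(study$tree)
  write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  writeSegmentTable(study$segments, file.path(dir, "segments.csv"))
  write.csv(data.frame(taxon = names(study$diet), state = unname(study$diet)),
            file.path(dir, "diet.csv"), row.names = FALSE)
  write.csv(data.frame(taxon = names(study$trait),
                       log10_wbchv = unname(study$trait)),
            file.path(dir, "trait.csv"), row.names = FALSE)
  invisible(dir)
}
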