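#' The seven regime models of continuous trait evolution
#'
#' `BM1` single-rate Brownian motion; `OU1` single-optimum
#' Ornstein-Uhlenbeck; `BMS` multi-rate BM; `OUM` multi-optimum OU (shared
#' sigma^2 and alpha); `OUMV` multi-rate multi-optimum OU; `OUMA` multi-alpha
#' multi-optimum OU; `OUMVA` everything per regime.
#' @export
regimeModelNames <- c("BM1", "OU1", "BMS", "OUM", "OUMV", "OUMA", "OUMVA")

#' Per-regime OU/BM parameters
#'
#' @param sigma2 diffusion rate(s), squared-trait-units per Myr (> 0); a
#'   scalar is shared across regimes
#' @param alpha attraction strength(s) per Myr (>= 0; 0 = Brownian motion)
#' @param theta long-term mean(s) in trait units (ignored when alpha = 0)
#' @param y0 root value; `NULL` means the theta of the root regime
#'   (stationary-start analogue) for OU models, and is required for BM models
#' @param regimes regime labels the vectors are named by / recycled over
#' @return object of class `regimeParams`
#' @export
regimeParams <- function(sigma2, alpha = 0, theta = 0, y0 = NULL,
                         regimes = NULL) {
  expand <- function(v) {
    if (is.null(regimes)) return(v)
    if (length(v) == 1 && is.null(names(v))) return(setNames(rep(v, length(regimes)), regimes))
    if (is.null(names(v))) { names(v) <- regimes; return(v) }
    v[regimes]
  }
  sigma2 <- expand(sigma2); alpha <- expand(alpha); theta <- expand(theta)
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  structure(list(sigma2 = sigma2, alpha = alpha, theta = theta, y0 = y0),
            class = "regimeParams")
}

# --- shared machinery -------------------------------------------------------

# tree/painting quantities that do not depend on parameters
.regimePrep <- function(tree, painting) {
  if (!identical(dim(painting$tree$edge), dim(tree$edge)) ||
      any(painting$tree$edge != tree$edge)) {
    stop("painting does not cover this tree")
  }
  ntip <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_row <- match(paste(pre[, 1], pre[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  states <- painting$states
  segs <- lapply(painting$maps, function(m) {
    list(d = unname(m), st = match(names(m), states))
  })
  # root regime = state at the rootward end of any root edge
  root <- ntip + 1L
  root_edge <- which(tree$edge[, 1] == root)[1]
  root_regime <- segs[[root_edge]]$st[1]
  mrca_mat <- ape::mrca(tree)
  list(tree = tree, ntip = ntip, nnode = tree$Nnode, pre = pre,
       edge_row = edge_row, states = states, R = length(states),
       segs = segs, root = root, root_regime = root_regime,
       mrca = mrca_mat)
}

# per-node accumulators given per-regime alpha: A = integrated alpha along the
# root path; w0 = exp(-A); W = theta weights per regime; VC = variance
# components per regime at unit sigma2
.ouNodeQuantities <- function(prep, alpha) {
  nn <- prep$ntip + prep$nnode
  R <- prep$R
  A <- numeric(nn); w0 <- numeric(nn)
  W <- matrix(0, nn, R); VC <- matrix(0, nn, R)
  w0[prep$root] <- 1
  for (i in seq_len(nrow(prep$pre))) {
    p <- prep$pre[i, 1]; ch <- prep$pre[i, 2]
    a_ <- A[p]; w0_ <- w0[p]; W_ <- W[p, ]; VC_ <- VC[p, ]
    sg <- prep$segs[[prep$edge_row[i]]]
    for (k in seq_along(sg$d)) {
      st <- sg$st[k]; d <- sg$d[k]; al <- alpha[st]
      if (al > 0) {
        e1 <- exp(-al * d); e2 <- e1 * e1
        W_ <- W_ * e1; w0_ <- w0_ * e1
        W_[st] <- W_[st] + (1 - e1)
        VC_ <- VC_ * e2
        VC_[st] <- VC_[st] + (1 - e2) / (2 * al)
        a_ <- a_ + al * d
      } else {
        VC_[st] <- VC_[st] + d
      }
    }
    A[ch] <- a_; w0[ch] <- w0_; W[ch, ] <- W_; VC[ch, ] <- VC_
  }
  list(A = A, w0 = w0, W = W, VC = VC)
}

# per-regime pairwise covariance components over tips:
# cov(i,j) = sum_r sigma2_r * VC[mrca, r] * exp(-(A_i + A_j - 2 A_mrca))
.ouCovComponents <- function(prep, nq) {
  tips <- seq_len(prep$ntip)
  At <- nq$A[tips]
  Am <- matrix(nq$A[prep$mrca], prep$ntip, prep$ntip)
  D <- exp(-(outer(At, At, "+") - 2 * Am))
  lapply(seq_len(prep$R), function(r) {
    matrix(nq$VC[prep$mrca, r], prep$ntip, prep$ntip) * D
  })
}

#' Exact tip moments of a piecewise-constant OU process on a painted tree
#'
#' First two moments of an Ornstein-Uhlenbeck process whose (alpha, sigma2,
#' theta) switch at the regime boundaries of a painting, with a deterministic
#' root value: tip means accumulate the exp(-integral alpha)-discounted root
#' value plus epoch-wise theta contributions; variances propagate per epoch as
#' `V <- V e^(-2 a d) + s2 (1 - e^(-2 a d)) / (2 a)` (with the Brownian limit
#' `s2 d` at a = 0); tip covariances equal the variance at the MRCA discounted
#' along both descending paths. Fossil (non-contemporaneous) tips are handled
#' by their true path lengths.
#'
#' @param tree dated [timeTree()]
#' @param painting a [regimePainting()] covering the tree
#' @param params a [regimeParams()] (vectors named by the painting's states)
#' @return list with `mean` (named tip vector) and `cov` (tip matrix)
#' @export
ouMoments <- function(tree, painting, params) {
  prep <- .regimePrep(tree, painting)
  p <- regimeParams(params$sigma2, params$alpha, params$theta, params$y0,
                    regimes = prep$states)
  if (any(is.na(p$theta))) {
    if (any(p$alpha > 0)) stop("theta is NA for a regime with alpha > 0")
    p$theta[is.na(p$theta)] <- 0  # theta is irrelevant under pure BM
  }
  nq <- .ouNodeQuantities(prep, p$alpha)
  tips <- seq_len(prep$ntip)
  y0 <- if (is.null(p$y0)) p$theta[prep$root_regime] else p$y0
  mu <- nq$w0[tips] * y0 + as.vector(nq$W[tips, , drop = FALSE] %*% p$theta)
  G <- .ouCovComponents(prep, nq)
  V <- Reduce(`+`, Map(function(g, s2) g * s2, G, p$sigma2))
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  list(mean = setNames(mu, tree$tip.label), cov = V)
}

# declared parameter-sharing pattern of each model
.modelSharing <- function(model) {
  switch(model,
    BM1   = list(multi_sigma = FALSE, multi_alpha = FALSE, multi_theta = FALSE, ou = FALSE),
    OU1   = list(multi_sigma = FALSE, multi_alpha = FALSE, multi_theta = FALSE, ou = TRUE),
    BMS   = list(multi_sigma = TRUE,  multi_alpha = FALSE, multi_theta = FALSE, ou = FALSE),
    OUM   = list(multi_sigma = FALSE, multi_alpha = FALSE, multi_theta = TRUE,  ou = TRUE),
    OUMV  = list(multi_sigma = TRUE,  multi_alpha = FALSE, multi_theta = TRUE,  ou = TRUE),
    OUMA  = list(multi_sigma = FALSE, multi_alpha = TRUE,  multi_theta = TRUE,  ou = TRUE),
    OUMVA = list(multi_sigma = TRUE,  multi_alpha = TRUE,  multi_theta = TRUE,  ou = TRUE),
    stop("unknown model: ", model))
}

#' Parameter count of a regime model
#'
#' Convention (R regimes): BM1 2; OU1 3; BMS R+1; OUM R+2; OUMV 2R+1;
#' OUMA 2R+1; OUMVA 3R. The root value is tied to the root regime's theta
#' for OU models and counted via y0 for BM models.
#'
#' @param model model name, see [regimeModelNames]
#' @param R number of regimes
#' @export
regimeModelK <- function(model, R) {
  R <- as.integer(R)
  switch(model, BM1 = 2L, OU1 = 3L, BMS = R + 1L, OUM = R + 2L,
         OUMV = 2L * R + 1L, OUMA = 2L * R + 1L, OUMVA = 3L * R,
         stop("unknown model: ", model))
}

#' Log-likelihood of tip values under a regime model
#'
#' Multivariate-normal log-density of the tip trait values under the exact
#' [ouMoments()] of the painted tree. Parameters must conform to the model's
#' sharing pattern (e.g. OUM requires shared sigma2 and alpha).
#'
#' @inheritParams ouMoments
#' @param trait named numeric vector of tip values
#' @param model model name, see [regimeModelNames]
#' @export
regimeModelLoglik <- function(tree, painting, trait, model, params) {
  sh <- .modelSharing(model)
  states <- painting$states
  p <- regimeParams(params$sigma2, params$alpha, params$theta, params$y0,
                    regimes = states)
  eq <- function(v) diff(range(v)) <= 1e-12 * max(1, max(abs(v)))
  if (!sh$multi_sigma && !eq(p$sigma2)) stop(model, " requires a shared sigma2")
  if (!sh$multi_alpha && !eq(p$alpha)) stop(model, " requires a shared alpha")
  if (!sh$ou && any(p$alpha != 0)) stop(model, " is a Brownian model: alpha must be 0")
  if (!sh$ou && is.null(p$y0)) stop(model, " needs an explicit root value y0")
  mom <- ouMoments(tree, painting, p)
  trait <- .alignToTips(trait, tree, "trait")
  .dmvn(trait, mom$mean, mom$cov)
}

.dmvn <- function(y, mu, V) {
  n <- length(y)
  U <- tryCatch(chol(V), error = function(e)
    stop("covariance is not positive definite (numerical failure)"))
  z <- backsolve(U, y - mu, transpose = TRUE)
  -n / 2 * log(2 * pi) - sum(log(diag(U))) - sum(z^2) / 2
}

#' Fit one regime model by maximum likelihood
#'
#' Nonlinear parameters (alphas, sigma2 ratios) are optimised on the log
#' scale with multi-starts; the optima/root value and the overall sigma2
#' scale are profiled out analytically (GLS). The alpha upper bound is
#' 50 / tree depth to avoid numerically flat likelihoods; bound hits are
#' flagged in the diagnostics.
#'
#' @inheritParams regimeModelLoglik
#' @param seed RNG seed for the multi-start draws
#' @param n_starts number of random starts (default 4) in addition to a
#'   deterministic moment-based start
#' @param root_policy `"stationary_theta"` (OU root value tied to the root
#'   regime's theta, default) or `"free"` (y0 estimated)
#' @param prep precomputed structures from repeated fits on one painting
#'   (internal use by [fitAllRegimeModels()])
#' @return object of class `regimeModelFit`: `model`, `params`
#'   ([regimeParams()]), `logL`, `k`, `n`, `AICc`, `convergence` (optim code
#'   plus boundary flags)
#' @export
fitRegimeModel <- function(tree, painting, trait, model, seed = NULL,
                           n_starts = 4,
                           root_policy = c("stationary_theta", "free"),
                           prep = NULL) {
  root_policy <- match.arg(root_policy)
  sh <- .modelSharing(model)
  if (is.null(prep)) prep <- .regimePrep(tree, painting)
  trait <- .alignToTips(trait, tree, "trait")
  n <- prep$ntip
  R <- prep$R
  k <- regimeModelK(model, R)
  if (n <= k) stop("n tips must exceed the parameter count k = ", k)
  Tdepth <- max(ape::node.depth.edgelength(tree))
  na <- if (!sh$ou) 0L else if (sh$multi_alpha) R else 1L
  nr <- if (sh$multi_sigma) R - 1L else 0L

  # psi = c(log alphas, log sigma ratios); evaluate the profile logL
  evalProfile <- function(psi) {
    alpha <- if (!sh$ou) rep(0, R)
             else if (sh$multi_alpha) exp(psi[seq_len(R)])
             else rep(exp(psi[1]), R)
    ratio <- c(1, if (nr > 0) exp(psi[na + seq_len(nr)]) else rep(1, R - 1))
    nq <- .ouNodeQuantities(prep, alpha)
    tips <- seq_len(n)
    G <- .ouCovComponents(prep, nq)
    V0 <- Reduce(`+`, Map(`*`, G, ratio))
    X <- if (!sh$ou) {
      cbind(y0 = nq$w0[tips])                      # identically 1 for BM
    } else if (sh$multi_theta) {
      W <- nq$W[tips, , drop = FALSE]
      colnames(W) <- prep$states
      if (root_policy == "stationary_theta") {
        W[, prep$root_regime] <- W[, prep$root_regime] + nq$w0[tips]
        W
      } else cbind(W, y0 = nq$w0[tips])
    } else {                                       # OU1: shared theta
      if (root_policy == "stationary_theta") {
        cbind(theta = rowSums(nq$W[tips, , drop = FALSE]) + nq$w0[tips])
      } else cbind(theta = rowSums(nq$W[tips, , drop = FALSE]),
                   y0 = nq$w0[tips])
    }
    core <- .glsCore(X, trait, V0)
    list(logL = core$logL, core = core, alpha = alpha, ratio = ratio, X = X)
  }

  decode <- function(ev, conv) {
    s <- ev$core$sigma2_ml
    sigma2 <- setNames(s * ev$ratio, prep$states)
    alpha <- setNames(ev$alpha, prep$states)
    beta <- ev$core$beta
    if (!sh$ou) {
      theta <- setNames(rep(NA_real_, R), prep$states)
      y0 <- beta[1]
    } else if (sh$multi_theta) {
      if (root_policy == "stationary_theta") {
        theta <- setNames(beta[seq_len(R)], prep$states)
        y0 <- theta[[prep$states[prep$root_regime]]]
      } else {
        theta <- setNames(beta[seq_len(R)], prep$states)
        y0 <- beta[R + 1]
      }
    } else {
      theta <- setNames(rep(beta[1], R), prep$states)
      y0 <- if (root_policy == "stationary_theta") beta[1] else beta[2]
    }
    flags <- character(0)
    if (s < 1e-10) flags <- c(flags, "sigma2_boundary")
    if (sh$ou && any(alpha > 0.999 * 50 / Tdepth)) flags <- c(flags, "alpha_upper_bound")
    if (sh$ou && any(alpha < 1.001 * 1e-6 / Tdepth)) flags <- c(flags, "alpha_lower_bound")
    structure(list(model = model,
                   params = structure(list(sigma2 = sigma2, alpha = alpha,
                                           theta = theta, y0 = unname(y0)),
                                      class = "regimeParams"),
                   logL = ev$logL, k = k, n = n,
                   AICc = aicc(ev$logL, k, n),
                   root_policy = root_policy,
                   convergence = list(code = conv, flags = flags)),
              class = "regimeModelFit")
  }

  npsi <- na + nr
  if (npsi == 0) return(decode(evalProfile(numeric(0)), 0L))

  lo <- c(rep(log(1e-6 / Tdepth), na), rep(-13.8, nr))
  hi <- c(rep(log(50 / Tdepth), na), rep(13.8, nr))
  obj <- function(psi) {
    ev <- tryCatch(evalProfile(psi), error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$logL)) 1e10 else -ev$logL
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- list(c(rep(log(2 / Tdepth), na), rep(0, nr)))
  for (i in seq_len(n_starts)) {
    starts[[i + 1]] <- c(runif(na, log(0.05 / Tdepth), log(30 / Tdepth)),
                         runif(nr, -3, 3))
  }
  best <- NULL
  for (st in starts) {
    opt <- try(optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(maxit = 500, factr = 1e4)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("regime model optimisation failed to converge for ", model)
  }
  decode(evalProfile(best$par), best$convergence)
}

#' @export
print.regimeModelFit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$model, x$logL, x$k, x$n, x$AICc))
  tab <- rbind(sigma2 = x$params$sigma2, alpha = x$params$alpha,
               theta = x$params$theta)
  print(round(tab, 6))
  cat("y0 =", round(x$params$y0, 6), "\n")
  if (length(x$convergence$flags)) {
    cat("flags:", paste(x$convergence$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit all seven regime models and compare by AICc
#'
#' @inheritParams fitRegimeModel
#' @param models subset of [regimeModelNames] (default all seven)
#' @return list with `fits` (per model; failed fits carry the error message),
#'   `comparison` ([akaikeWeights()]; ties resolve to fewer parameters) and
#'   `best` (name of the preferred model)
#' @export
fitAllRegimeModels <- function(tree, painting, trait, seed = NULL,
                               models = regimeModelNames, n_starts = 4,
                               root_policy = "stationary_theta") {
  prep <- .regimePrep(tree, painting)
  fits <- list(); errs <- list()
  for (m in models) {
    f <- tryCatch(fitRegimeModel(tree, painting, trait, m, seed = seed,
                                 n_starts = n_starts,
                                 root_policy = root_policy, prep = prep),
                  error = function(e) e)
    if (inherits(f, "error")) errs[[m]] <- conditionMessage(f) else fits[[m]] <- f
  }
  if (!length(fits)) stop("all regime model fits failed")
  av <- vapply(fits, `[[`, 0, "AICc")
  kv <- vapply(fits, `[[`, 0L, "k")
  cmp <- if (length(fits) >= 2) akaikeWeights(av, kv) else NULL
  best <- if (is.null(cmp)) names(fits)[1] else preferredModel(cmp)
  list(fits = fits, failed = errs, comparison = cmp, best = best)
}

#' Summarise regime-model fits across a stochastic-map ensemble
#'
#' Raw parameter estimates are not directly comparable between stochastic
#' maps (each map has its own likelihood surface), so the ensemble is
#' summarised by within-map pairwise differences: for each parameter and
#' ordered regime pair, the difference inside each map, and the count of maps
#' in which each qualitative pattern (a focal regime exceeding all others)
#' holds. Per-map estimates are retained for export; no cross-map averaging
#' of raw parameters is performed.
#'
#' @param fits list of per-map best `regimeModelFit`s (e.g. the `fits[[best]]`
#'   of [fitAllRegimeModels()] applied to each sampled map)
#' @return object of class `mapEnsembleSummary`: `best_models` (table),
#'   `estimates` (long data.frame: map, model, param, regime, value),
#'   `pairwise` (map, param, regime1, regime2, diff) and `patterns`
#'   (param, regime, n_highest out of n_maps)
#' @export
acrossMapSummary <- function(fits) {
  if (!length(fits)) stop("empty fit list")
  regimes <- names(fits[[1]]$params$sigma2)
  params <- c("sigma2", "alpha", "theta")
  est <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    do.call(rbind, lapply(params, function(pp) {
      data.frame(map = i, model = f$model, param = pp, regime = regimes,
                 value = as.numeric(f$params[[pp]][regimes]),
                 stringsAsFactors = FALSE)
    }))
  }))
  prs <- utils::combn(regimes, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    do.call(rbind, lapply(params, function(pp) {
      v <- f$params[[pp]][regimes]
      data.frame(map = i, param = pp,
                 regime1 = vapply(prs, `[`, "", 1),
                 regime2 = vapply(prs, `[`, "", 2),
                 diff = vapply(prs, function(pr) v[[pr[1]]] - v[[pr[2]]], 0),
                 stringsAsFactors = FALSE)
    }))
  }))
  patterns <- do.call(rbind, lapply(params, function(pp) {
    counts <- vapply(regimes, function(r) {
      sum(vapply(fits, function(f) {
        v <- f$params[[pp]][regimes]
        if (any(is.na(v))) return(FALSE)
        all(v[[r]] > v[setdiff(regimes, r)])
      }, logical(1)))
    }, 0)
    data.frame(param = pp, regime = regimes, n_highest = as.integer(counts),
               n_maps = length(fits), row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(best_models = table(vapply(fits, `[[`, "", "model")),
                 estimates = est, pairwise = pairwise, patterns = patterns,
                 n_maps = length(fits)),
            class = "mapEnsembleSummary")
}

#' @export
print.mapEnsembleSummary <- function(x, ...) {
  cat("Across-map summary of", x$n_maps, "stochastic maps\n")
  cat("Best models:\n"); print(x$best_models)
  cat("Maps in which a regime's parameter exceeds all others:\n")
  print(x$patterns)
  invisible(x)
}
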