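# Generalised least squares core shared by pglsFit / olsFit / phylAncova.
# V is the (unscaled) residual covariance; the residual scale sigma2 is
# profiled out analytically.
.glsCore <- function(X, y, V = NULL) {
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("fewer observations than coefficients")
  if (is.null(V)) {
    U <- NULL; Xw <- X; yw <- y; logdetV <- 0
  } else {
    U <- tryCatch(chol(V), error = function(e) stop("residual covariance is not positive definite"))
    Xw <- backsolve(U, X, transpose = TRUE)
    yw <- backsolve(U, y, transpose = TRUE)
    logdetV <- 2 * sum(log(diag(U)))
  }
  qr_ <- qr(Xw)
  if (qr_$rank < p) stop("singular design matrix")
  beta <- qr.coef(qr_, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  XtX_inv <- chol2inv(qr.R(qr_))
  sigma2_ml <- rss / n
  logL <- -n / 2 * (log(2 * pi) + log(max(sigma2_ml, .Machine$double.xmin)) + 1) -
    logdetV / 2
  list(beta = as.vector(beta), cov_unscaled = XtX_inv, rss = rss,
       sigma2_ml = sigma2_ml, sigma2 = rss / (n - p),
       logL = logL, logdetV = logdetV, n = n, p = p,
       fitted = as.vector(X %*% beta), residuals = as.vector(y - X %*% beta))
}

.alignToTips <- function(v, tree, what = "values") {
  if (is.null(names(v))) {
    if (length(v) != ape::Ntip(tree)) stop(what, " length differs from tip count")
    return(setNames(v, tree$tip.label))
  }
  miss <- setdiff(tree$tip.label, names(v))
  if (length(miss)) stop(what, " missing for tips: ", paste(miss, collapse = ", "))
  v[tree$tip.label]
}

.designPoly <- function(x, degree) {
  if (degree == 1) {
    list(X = cbind(b0 = 1, b1 = x), L = diag(2))
  } else {
    # centre x before squaring to tame collinearity; L maps centred
    # coefficients back to the uncentred scale
    m <- mean(x); xc <- x - m
    L <- rbind(c(1, -m, m^2), c(0, 1, -2 * m), c(0, 0, 1))
    rownames(L) <- colnames(L) <- c("b0", "b1", "b2")
    list(X = cbind(b0 = 1, b1 = xc, b2 = xc^2), L = L)
  }
}

#' Phylogenetic generalised least squares regression
#'
#' Fits `y ~ x` (degree 1) or `y ~ x + x^2` (degree 2) by GLS under a
#' lambda-transformed Brownian-motion covariance. Pagel's lambda is estimated
#' by profile maximum likelihood on `[0, 1]` (flat-likelihood ties resolve
#' toward lambda = 1) or held fixed. Intended for log-scale data: in this
#' package size metrics enter as base-10 logarithms.
#'
#' @param x,y named numeric vectors aligned to the tree tips (typically
#'   log10 size and log10 metric)
#' @param tree a dated [timeTree()]
#' @param degree 1 (linear) or 2 (quadratic)
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`
#' @param conf confidence level for intervals (default 0.95)
#' @return an object of class `pglsFit` with elements `coefficients`
#'   (uncentred scale, names b0, b1[, b2]), `se`, `ci`, `lambda`, `logL`,
#'   `k` (coefficients + residual variance + lambda when estimated), `n`,
#'   `AICc`, `sigma2`, `residuals`, `fitted`
#' @examples
#' tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
#' x <- c(A = 1, B = 2, C = 3, D = 4)
#' y <- 0.33 * x
#' pglsFit(x, y, tr)$coefficients
#' @export
pglsFit <- function(x, y, tree, degree = 1, lambda = "ML", conf = 0.95) {
  .assertDated(tree)
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  x <- .alignToTips(x, tree, "x"); y <- .alignToTips(y, tree, "y")
  n <- length(y)
  if (n < degree + 2) stop("need at least degree + 2 taxa")
  if (stats::var(x) == 0) stop("singular design: x is constant")
  C <- bmCovariance(tree)
  des <- .designPoly(x, degree)

  fit_at <- function(lam) .glsCore(des$X, y, lambdaTransform(C, lam))
  if (identical(lambda, "ML")) {
    prof <- function(lam) fit_at(lam)$logL
    opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, prof(0), prof(1))
    lam <- cand[which.max(ll)]
    if (ll[3] >= max(ll) - 1e-8) lam <- 1   # ties toward lambda = 1
    lambda_est <- TRUE
  } else {
    lam <- lambda
    if (!is.numeric(lam) || lam < 0 || lam > 1) stop("fixed lambda must be in [0, 1]")
    lambda_est <- FALSE
  }
  core <- fit_at(lam)

  beta_u <- as.vector(des$L %*% core$beta)
  cov_u <- core$sigma2 * des$L %*% core$cov_unscaled %*% t(des$L)
  se <- sqrt(diag(cov_u))
  df <- core$n - core$p
  tq <- qt(1 - (1 - conf) / 2, df)
  ci <- cbind(lower = beta_u - tq * se, upper = beta_u + tq * se)
  nm <- c("b0", "b1", "b2")[seq_len(degree + 1)]
  names(beta_u) <- names(se) <- rownames(ci) <- nm

  k <- core$p + 1 + as.integer(lambda_est)
  structure(list(degree = degree, coefficients = beta_u, se = se, ci = ci,
                 lambda = lam, lambda_estimated = lambda_est,
                 logL = core$logL, k = k, n = core$n,
                 AICc = aicc(core$logL, k, core$n),
                 sigma2 = core$sigma2_ml, df = df,
                 residuals = core$residuals, fitted = core$fitted,
                 conf = conf),
            class = "pglsFit")
}

#' Ordinary least squares fit (no evolutionary model)
#'
#' Identical contract to [pglsFit()] but with an identity residual
#' covariance; equivalent to PGLS with lambda = 0 on a star phylogeny.
#'
#' @inheritParams pglsFit
#' @export
olsFit <- function(x, y, degree = 1, conf = 0.95) {
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  n <- length(y)
  if (n < degree + 2) stop("need at least degree + 2 observations")
  if (stats::var(x) == 0) stop("singular design: x is constant")
  des <- .designPoly(x, degree)
  core <- .glsCore(des$X, y, NULL)
  beta_u <- as.vector(des$L %*% core$beta)
  cov_u <- core$sigma2 * des$L %*% core$cov_unscaled %*% t(des$L)
  se <- sqrt(diag(cov_u))
  df <- core$n - core$p
  tq <- qt(1 - (1 - conf) / 2, df)
  ci <- cbind(lower = beta_u - tq * se, upper = beta_u + tq * se)
  nm <- c("b0", "b1", "b2")[seq_len(degree + 1)]
  names(beta_u) <- names(se) <- rownames(ci) <- nm
  k <- core$p + 1
  structure(list(degree = degree, coefficients = beta_u, se = se, ci = ci,
                 lambda = NA_real_, lambda_estimated = FALSE,
                 logL = core$logL, k = k, n = core$n,
                 AICc = aicc(core$logL, k, core$n),
                 sigma2 = core$sigma2_ml, df = df,
                 residuals = core$residuals, fitted = core$fitted,
                 conf = conf),
            class = "pglsFit")
}

#' @export
print.pglsFit <- function(x, ...) {
  cat(sprintf("%s fit (degree %d), n = %d\n",
              if (is.na(x$lambda)) "OLS" else "PGLS", x$degree, x$n))
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(tab, 6))
  cat(sprintf("lambda = %s   logL = %.4f   k = %d   AICc = %.4f\n",
              ifelse(is.na(x$lambda), "-", format(round(x$lambda, 4))),
              x$logL, x$k, x$AICc))
  invisible(x)
}

#' Akaike information criterion for small samples
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`; requires `n > k + 1`.
#'
#' @param logL maximised log-likelihood
#' @param k number of estimated parameters
#' @param n sample size
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights across candidate models
#'
#' Weights are proportional to exp(-delta AICc / 2). The preferred model has
#' minimal AICc; exact ties resolve toward fewer parameters when `k` is
#' supplied.
#'
#' @param aicc_values named numeric vector of AICc values (>= 2 finite)
#' @param k optional named vector of parameter counts used to break ties
#' @return object of class `modelComparison`: data.frame (model, k, AICc,
#'   delta, weight) with attribute `preferred`
#' @export
akaikeWeights <- function(aicc_values, k = NULL) {
  if (length(aicc_values) < 2) stop("need at least two models to compare")
  if (all(!is.finite(aicc_values))) stop("all AICc values are infinite")
  if (is.null(names(aicc_values))) {
    names(aicc_values) <- paste0("model", seq_along(aicc_values))
  }
  delta <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  best <- which(delta < 1e-8)
  if (length(best) > 1 && !is.null(k)) best <- best[order(k[best])]
  preferred <- names(aicc_values)[best[1]]
  out <- data.frame(model = names(aicc_values),
                    k = if (is.null(k)) NA_integer_ else as.integer(k),
                    AICc = as.numeric(aicc_values), delta = as.numeric(delta),
                    weight = as.numeric(w), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("modelComparison", "data.frame"), preferred = preferred)
}

#' @rdname akaikeWeights
#' @param comparison a `modelComparison`
#' @export
preferredModel <- function(comparison) attr(comparison, "preferred")

#' Classify allometry against an expected (isometric) slope
#'
#' Isometric if the expected slope lies inside the fit's confidence interval;
#' otherwise positive or negative allometry by the sign of
#' (estimate - expected). Conventional expectations: 1/3 for length vs volume
#' and 1 for volume vs volume on log-log axes.
#'
#' @param fit a degree-1 `pglsFit`
#' @param expected_slope the isometric expectation
#' @return list with `classification` ("isometric", "positive allometry" or
#'   "negative allometry"), `slope`, `ci`, `expected`
#' @export
isometryTest <- function(fit, expected_slope) {
  if (!inherits(fit, "pglsFit") || fit$degree != 1) {
    stop("isometryTest needs a degree-1 pglsFit")
  }
  ci <- fit$ci["b1", ]
  if (!all(is.finite(ci)) || diff(range(ci)) <= 0) stop("degenerate confidence interval")
  cls <- if (expected_slope >= ci[1] && expected_slope <= ci[2]) "isometric"
         else if (fit$coefficients["b1"] > expected_slope) "positive allometry"
         else "negative allometry"
  list(classification = cls, slope = unname(fit$coefficients["b1"]),
       ci = ci, expected = expected_slope)
}

#' Convert a body-mass threshold to the log-WBCHV scale
#'
#' Size bins are specified in kg but measured in WBCHV; conversion assumes
#' mass = density_coefficient x WBCHV (default 1000 kg m^-3, i.e. WBCHV in
#' m^3 and a water-like whole-body density).
#'
#' @param mass_kg body mass threshold(s) in kg
#' @param density_coefficient kg per unit WBCHV (default 1000)
#' @param log_base base of the log scale x is on (default 10)
#' @return threshold(s) on the log-WBCHV scale
#' @export
wbchvThreshold <- function(mass_kg, density_coefficient = 1000, log_base = 10) {
  log(mass_kg / density_coefficient, base = log_base)
}

#' Per-size-bin PGLS slopes
#'
#' Splits taxa at each threshold (on the same scale as `x`, see
#' [wbchvThreshold()]), prunes the tree to each bin, fits an independent
#' degree-1 PGLS per bin and reports the between-bin slope contrast.
#'
#' @inheritParams pglsFit
#' @param thresholds numeric vector of split points on the `x` scale
#' @param min_n minimum taxa per bin (default 4)
#' @return list of class `binnedSlopes`: per threshold, the `below`/`above`
#'   fits and a contrast (slope difference, SE, z, p)
#' @export
binnedSlopes <- function(x, y, tree, thresholds, lambda = "ML", min_n = 4) {
  .assertDated(tree)
  x <- .alignToTips(x, tree, "x"); y <- .alignToTips(y, tree, "y")
  out <- lapply(thresholds, function(thr) {
    lo <- names(x)[x < thr]; hi <- names(x)[x >= thr]
    if (length(lo) < min_n || length(hi) < min_n) {
      stop(sprintf("threshold %g leaves a bin with fewer than %d taxa", thr, min_n))
    }
    fit_bin <- function(keep) {
      sub <- timeTree(ape::keep.tip(tree, keep),
                      root_age = NULL)
      pglsFit(x[keep], y[keep], sub, degree = 1, lambda = lambda)
    }
    below <- fit_bin(lo); above <- fit_bin(hi)
    d <- above$coefficients["b1"] - below$coefficients["b1"]
    se <- sqrt(above$se["b1"]^2 + below$se["b1"]^2)
    z <- d / se
    list(threshold = thr, below = below, above = above,
         contrast = c(slope_diff = unname(d), se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z)))))
  })
  names(out) <- paste0("thr_", format(thresholds))
  structure(out, class = "binnedSlopes")
}

#' @export
print.binnedSlopes <- function(x, ...) {
  for (b in x) {
    cat(sprintf("threshold %g: slope below = %.4f, above = %.4f, diff = %.4f (p = %.4g)\n",
                b$threshold, b$below$coefficients["b1"], b$above$coefficients["b1"],
                b$contrast["slope_diff"], b$contrast["p"]))
  }
  invisible(x)
}

#' Phylogenetic ANCOVA
#'
#' Fits a single PGLS model with per-group intercepts and per-group slopes
#' (`y ~ group + x + group:x`) under one shared ML lambda, then reports all
#' pairwise between-group contrasts on slopes and intercepts as Wald t tests
#' (df = n - p), with Holm-adjusted p-values alongside the raw ones. On a
#' star phylogeny this reproduces a classical ANCOVA.
#'
#' @inheritParams pglsFit
#' @param groups named character/factor of group labels, >= 2 groups with
#'   >= 4 taxa each
#' @param min_n minimum taxa per group (default 4)
#' @return object of class `ancovaResult`: data.frame of contrasts with
#'   attributes `lambda`, `logL`, `n`, `groups`
#' @export
phylAncova <- function(x, y, groups, tree, lambda = "ML", min_n = 4) {
  .assertDated(tree)
  x <- .alignToTips(x, tree, "x"); y <- .alignToTips(y, tree, "y")
  groups <- .alignToTips(groups, tree, "groups")
  g <- factor(as.character(groups))
  lv <- levels(g)
  if (length(lv) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < min_n)) {
    stop("group(s) with fewer than ", min_n, " taxa: ",
         paste(names(sizes)[sizes < min_n], collapse = ", "))
  }
  X <- stats::model.matrix(~ g * x)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  C <- bmCovariance(tree)

  fit_at <- function(lam) .glsCore(X, y, lambdaTransform(C, lam))
  if (identical(lambda, "ML")) {
    prof <- function(lam) fit_at(lam)$logL
    opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1); ll <- c(opt$objective, prof(0), prof(1))
    lam <- cand[which.max(ll)]
    if (ll[3] >= max(ll) - 1e-8) lam <- 1
  } else lam <- lambda
  core <- fit_at(lam)
  covb <- core$sigma2 * core$cov_unscaled
  df <- core$n - core$p

  # per-group intercepts/slopes as linear maps of the treatment-coded betas
  cn <- colnames(X)
  sel <- function(level, what) {
    v <- numeric(length(cn))
    if (what == "intercept") {
      v[cn == "(Intercept)"] <- 1
      if (level != lv[1]) v[cn == paste0("g", level)] <- 1
    } else {
      v[cn == "x"] <- 1
      if (level != lv[1]) v[cn == paste0("g", level, ":x")] <- 1
    }
    v
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  one <- function(pair, what) {
    cvec <- sel(pair[1], what) - sel(pair[2], what)
    est <- sum(cvec * core$beta)
    se <- sqrt(drop(t(cvec) %*% covb %*% cvec))
    tval <- est / se
    c(diff = est, se = se, t = tval, p = 2 * pt(-abs(tval), df))
  }
  slope <- t(vapply(pairs, one, numeric(4), what = "slope"))
  inter <- t(vapply(pairs, one, numeric(4), what = "intercept"))
  out <- data.frame(group1 = vapply(pairs, `[`, "", 1),
                    group2 = vapply(pairs, `[`, "", 2),
                    slope_diff = slope[, "diff"], slope_se = slope[, "se"],
                    slope_t = slope[, "t"], slope_p = slope[, "p"],
                    slope_p_adj = p.adjust(slope[, "p"], "holm"),
                    intercept_diff = inter[, "diff"], intercept_se = inter[, "se"],
                    intercept_t = inter[, "t"], intercept_p = inter[, "p"],
                    intercept_p_adj = p.adjust(inter[, "p"], "holm"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ancovaResult", "data.frame"),
            lambda = lam, logL = core$logL, n = core$n, groups = lv)
}
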