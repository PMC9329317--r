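# two-regime painting + simulated trait shared by several tests
regimeFixture <- function(n = 60, seed = 120, alpha = 2, theta = c(A = 0, B = 3),
                          sigma2 = 1, model = "OUM", birth_rate = 1) {
  tr <- simYuleTree(n, birth_rate = birth_rate, seed = seed)
  Q <- mkModel(names(theta), "ER", rates = 8 / sum(tr$edge.length))$Q
  sim <- simDiscrete(tr, Q, seed = seed + 1)
  pars <- regimeParams(sigma2 = sigma2, alpha = alpha, theta = theta)
  y <- simTrait(tr, sim$painting, pars, seed = seed + 2)
  list(tree = tr, painting = sim$painting, trait = y, params = pars)
}

test_that("OU moments reduce to BM at alpha = 0", {
  tr <- simYuleTree(20, seed = 111, extinct_fraction = 0.3)
  one <- onePainting(tr)
  mom <- ouMoments(tr, one, regimeParams(sigma2 = 1.7, alpha = 0, theta = 0,
                                         y0 = 2.5))
  expect_equal(unname(mom$mean), rep(2.5, 20))
  expect_equal(mom$cov, 1.7 * bmCovariance(tr), tolerance = 1e-12)
})

test_that("OU moments match single-regime closed forms on a 3-tip tree", {
  tr <- readNewickTree("((A:2,B:2):1,C:3);")  # depth 3, A-B split at time 1
  one <- onePainting(tr)
  a <- 0.7; s2 <- 1.3; th <- 2; y0 <- 5; Td <- 3; tsplit <- 1
  mom <- ouMoments(tr, one, regimeParams(s2, a, th, y0 = y0))
  expect_equal(unname(diag(mom$cov)), rep(s2 * (1 - exp(-2 * a * Td)) / (2 * a), 3),
               tolerance = 1e-12)
  expect_equal(mom$cov["A", "B"],
               exp(-2 * a * (Td - tsplit)) * s2 * (1 - exp(-2 * a * tsplit)) / (2 * a),
               tolerance = 1e-12)
  expect_equal(unname(mom$mean["A"]),
               y0 * exp(-a * Td) + th * (1 - exp(-a * Td)), tolerance = 1e-12)
})

test_that("equal per-regime parameters reproduce OU1 moments under any painting", {
  fx <- regimeFixture(n = 30, seed = 113)
  shared <- regimeParams(sigma2 = 0.8, alpha = 1.2, theta = 1, y0 = 1,
                         regimes = c("A", "B"))
  mom_multi <- ouMoments(fx$tree, fx$painting, shared)
  mom_one <- ouMoments(fx$tree, onePainting(fx$tree),
                       regimeParams(0.8, 1.2, 1, y0 = 1))
  expect_equal(mom_multi$mean, mom_one$mean, tolerance = 1e-10)
  expect_equal(mom_multi$cov, mom_one$cov, tolerance = 1e-10)
})

test_that("OU covariances stay symmetric positive semi-definite", {
  set.seed(114)
  fx <- regimeFixture(n = 25, seed = 115)
  for (r in 1:20) {
    p <- regimeParams(sigma2 = runif(2, 0.1, 3), alpha = runif(2, 0, 5),
                      theta = rnorm(2), y0 = 0, regimes = c("A", "B"))
    V <- ouMoments(fx$tree, fx$painting, p)$cov
    expect_equal(V, t(V), tolerance = 1e-12)
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("BM1 regime likelihood equals an independent dense-GLS computation", {
  tr <- simYuleTree(35, seed = 116, extinct_fraction = 0.2)
  one <- onePainting(tr)
  y <- simTrait(tr, one, regimeParams(1.5, 0, 0, y0 = 0.3), seed = 117)
  ll <- regimeModelLoglik(tr, one, y, "BM1", regimeParams(1.5, 0, 0, y0 = 0.3))
  V <- 1.5 * bmCovariance(tr)
  r <- y[tr$tip.label] - 0.3
  ll2 <- -35 / 2 * log(2 * pi) - as.numeric(determinant(V)$modulus) / 2 -
    drop(t(r) %*% solve(V) %*% r) / 2
  expect_equal(ll, ll2, tolerance = 1e-8)
})

test_that("OU likelihood converges to BM as alpha -> 0", {
  tr <- simYuleTree(30, seed = 118)
  one <- onePainting(tr)
  y <- simTrait(tr, one, regimeParams(1, 0, 0, y0 = 0.5), seed = 119)
  llbm <- regimeModelLoglik(tr, one, y, "BM1", regimeParams(1, 0, 0, y0 = 0.5))
  llou <- regimeModelLoglik(tr, one, y, "OU1",
                            regimeParams(1, 1e-10, 0.5, y0 = NULL))
  expect_lt(abs(llou - llbm), 1e-6)
})

test_that("likelihood is invariant to tip order and regime relabelling", {
  fx <- regimeFixture(n = 30, seed = 121)
  p <- regimeParams(sigma2 = c(A = 1, B = 2), alpha = c(A = 1, B = 2),
                    theta = c(A = 0, B = 3))
  ll <- regimeModelLoglik(fx$tree, fx$painting, fx$trait, "OUMVA", p)
  # permute tip order in the trait vector
  perm <- sample(names(fx$trait))
  expect_equal(regimeModelLoglik(fx$tree, fx$painting, fx$trait[perm],
                                 "OUMVA", p), ll, tolerance = 1e-12)
  # relabel regimes A<->B with correspondingly permuted parameters
  relabel <- fx$painting
  relabel$maps <- lapply(relabel$maps, function(m) {
    names(m) <- c(A = "B", B = "A")[names(m)]
    m
  })
  relabel$states <- c("A", "B")
  p2 <- regimeParams(sigma2 = c(A = 2, B = 1), alpha = c(A = 2, B = 1),
                     theta = c(A = 3, B = 0))
  expect_equal(regimeModelLoglik(fx$tree, relabel, fx$trait, "OUMVA", p2),
               ll, tolerance = 1e-10)
})

test_that("sharing violations are rejected", {
  fx <- regimeFixture(n = 20, seed = 122)
  bad <- regimeParams(sigma2 = c(A = 1, B = 2), alpha = 1, theta = c(A = 0, B = 1))
  expect_error(regimeModelLoglik(fx$tree, fx$painting, fx$trait, "OUM", bad),
               "shared sigma2")
  bad2 <- regimeParams(sigma2 = 1, alpha = c(A = 1, B = 2), theta = 0)
  expect_error(regimeModelLoglik(fx$tree, fx$painting, fx$trait, "OU1", bad2),
               "shared alpha")
})

test_that("multi-regime models collapse to their single-regime forms", {
  tr <- simYuleTree(40, seed = 123)
  one <- onePainting(tr)
  y <- simTrait(tr, one, regimeParams(1, 1.5, 2, y0 = NULL), seed = 124)
  f_ou1 <- fitRegimeModel(tr, one, y, "OU1", seed = 7)
  for (m in c("OUM", "OUMV", "OUMA", "OUMVA")) {
    f <- fitRegimeModel(tr, one, y, m, seed = 7)
    expect_equal(f$logL, f_ou1$logL, tolerance = 1e-8)
  }
  f_bm1 <- fitRegimeModel(tr, one, y, "BM1", seed = 7)
  f_bms <- fitRegimeModel(tr, one, y, "BMS", seed = 7)
  expect_equal(f_bms$logL, f_bm1$logL, tolerance = 1e-8)
})

test_that("parameter counts follow the declared convention", {
  expect_equal(vapply(regimeModelNames, regimeModelK, 0L, R = 5),
               c(BM1 = 2L, OU1 = 3L, BMS = 6L, OUM = 7L, OUMV = 11L,
                 OUMA = 11L, OUMVA = 15L))
})

test_that("a noise-free constant trait flags the sigma2 boundary", {
  tr <- simYuleTree(20, seed = 125)
  y <- setNames(rep(1.7, 20), tr$tip.label)
  f <- fitRegimeModel(tr, onePainting(tr), y, "BM1")
  expect_true("sigma2_boundary" %in% f$convergence$flags)
})

test_that("OUM recovers its optima on a desk-scale fixture", {
  fx <- regimeFixture(n = 150, seed = 126, alpha = 2, theta = c(A = 0, B = 5))
  f <- fitRegimeModel(fx$tree, fx$painting, fx$trait, "OUM", seed = 127)
  expect_lt(abs(f$params$theta[["A"]] - 0), 0.5)
  expect_lt(abs(f$params$theta[["B"]] - 5), 0.5)
  expect_equal(f$k, 4L)
  expect_equal(f$AICc, aicc(f$logL, 4, 150))
})

test_that("theta bias shrinks as depth x alpha grows", {
  err <- function(birth_rate, seed) {
    fx <- regimeFixture(n = 80, seed = seed, alpha = 1.5,
                        theta = c(A = 0, B = 4), birth_rate = birth_rate)
    f <- fitRegimeModel(fx$tree, fx$painting, fx$trait, "OUM", seed = seed)
    mean(abs(f$params$theta - c(0, 4)))
  }
  shallow <- stats::median(vapply(1:6, function(i) err(2, 130 + i), 0))
  deep <- stats::median(vapply(1:6, function(i) err(0.5, 140 + i), 0))
  expect_lt(deep, shallow)
})

test_that("fitAllRegimeModels returns consistent fits and a comparison", {
  fx <- regimeFixture(n = 60, seed = 150)
  all <- fitAllRegimeModels(fx$tree, fx$painting, fx$trait, seed = 151)
  expect_setequal(names(all$fits), regimeModelNames)
  for (f in all$fits) {
    expect_equal(f$n, 60)
    expect_equal(f$AICc, aicc(f$logL, f$k, f$n), tolerance = 1e-10)
  }
  expect_s3_class(all$comparison, "modelComparison")
  expect_equal(all$best, preferredModel(all$comparison))
})

test_that("across-map summaries tally patterns exactly", {
  mkfit <- function(s2, al, th) {
    structure(list(model = "OUMVA",
                   params = structure(list(
                     sigma2 = c(A = s2[1], B = s2[2], C = s2[3]),
                     alpha = c(A = al[1], B = al[2], C = al[3]),
                     theta = c(A = th[1], B = th[2], C = th[3]), y0 = 0),
                     class = "regimeParams"),
                   logL = 0, k = 9, n = 50, AICc = 0),
              class = "regimeModelFit")
  }
  fits <- list(mkfit(c(3, 1, 2), c(5, 1, 2), c(0, 1, 2)),
               mkfit(c(9, 2, 1), c(4, 2, 1), c(2, 1, 0)),
               mkfit(c(1, 5, 2), c(9, 0, 1), c(0, 2, 1)))
  s <- acrossMapSummary(fits)
  pat <- s$patterns
  # hand tally: sigma2 highest for A in maps 1,2; alpha highest for A in all 3
  expect_equal(pat$n_highest[pat$param == "sigma2" & pat$regime == "A"], 2L)
  expect_equal(pat$n_highest[pat$param == "alpha" & pat$regime == "A"], 3L)
  expect_equal(pat$n_highest[pat$param == "theta" & pat$regime == "C"], 1L)
  expect_true(all(pat$n_highest <= pat$n_maps))
  # within-map pairwise differences: check one by hand
  d <- s$pairwise
  expect_equal(d$diff[d$map == 1 & d$param == "sigma2" &
                        d$regime1 == "A" & d$regime2 == "B"], 2)
  single <- acrossMapSummary(fits[1])
  expect_true(all(single$patterns$n_highest %in% c(0L, 1L)))
  expect_error(acrossMapSummary(list()), "empty")
})

test_that("simulated trait moments agree with ouMoments", {
  # cornerstone cross-validation: forward simulation vs analytic moments
  fx <- regimeFixture(n = 6, seed = 160, alpha = 1, theta = c(A = 0, B = 2),
                      sigma2 = 0.5)
  p <- regimeParams(sigma2 = c(A = 0.5, B = 1.5), alpha = c(A = 1, B = 0),
                    theta = c(A = 0, B = 2), y0 = 1)
  mom <- ouMoments(fx$tree, fx$painting, p)
  nrep <- 2000
  sims <- vapply(seq_len(nrep), function(i) {
    simTrait(fx$tree, fx$painting, p, seed = 20000 + i)
  }, numeric(6))
  mhat <- rowMeans(sims)
  mc_se <- sqrt(diag(mom$cov) / nrep)
  expect_true(all(abs(mhat - mom$mean) < 4 * mc_se + 1e-12))
  vhat <- stats::cov(t(sims))
  # sampling error of a covariance entry is O(V/sqrt(n))
  expect_lt(max(abs(vhat - mom$cov)), 6 * max(diag(mom$cov)) / sqrt(nrep))
})
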