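test_that("PGLS equals OLS on a star tree", {
  set.seed(1)
  star <- starTree(25)
  x <- setNames(rnorm(25), star$tip.label)
  y <- 0.4 * x + rnorm(25, 0, 0.3); names(y) <- names(x)
  fp <- pglsFit(x, y, star)
  fo <- olsFit(x, y)
  expect_equal(fp$coefficients, fo$coefficients, tolerance = 1e-8)
  expect_equal(fp$se, fo$se, tolerance = 1e-8)
})

test_that("exact linear data give the exact slope with zero residual variance", {
  tr <- simYuleTree(15, seed = 4)
  x <- setNames(seq(0, 3, length.out = 15), tr$tip.label)
  y <- 0.33 * x
  f <- pglsFit(x, y, tr)
  expect_equal(unname(f$coefficients["b1"]), 0.33, tolerance = 1e-9)
  expect_lt(f$sigma2, 1e-20)
  fo <- olsFit(x, y)
  expect_lt(max(abs(fo$residuals)), 1e-12)
})

test_that("fixed-lambda endpoints reproduce OLS and raw-BM GLS", {
  # lambda = 0 on an ultrametric tree (equal tip depths) is exactly OLS
  tru <- simYuleTree(30, seed = 6)
  sau <- simAllometry(tru, slope = 0.5, sigma2_resid = 0.1, seed = 7)
  f0 <- pglsFit(sau$x, sau$y, tru, lambda = 0)
  fo <- olsFit(sau$x[tru$tip.label], sau$y[tru$tip.label])
  expect_equal(f0$coefficients, fo$coefficients, tolerance = 1e-8)

  tr <- simYuleTree(30, seed = 6, extinct_fraction = 0.2)
  sa <- simAllometry(tr, slope = 0.5, sigma2_resid = 0.1, seed = 7)
  f1 <- pglsFit(sa$x, sa$y, tr, lambda = 1)
  # independent GLS under the raw BM covariance
  C <- bmCovariance(tr)
  X <- cbind(1, sa$x[tr$tip.label])
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% sa$y[tr$tip.label])
  expect_equal(unname(f1$coefficients), as.vector(beta), tolerance = 1e-8)
})

test_that("quadratic fits recover exact curvature and win by AICc", {
  tr <- simYuleTree(40, seed = 9)
  set.seed(10)
  x <- setNames(rnorm(40, 0, 2), tr$tip.label)
  y <- 1 + 2 * x + 0.5 * x^2
  f2 <- pglsFit(x, y, tr, degree = 2)
  expect_equal(unname(f2$coefficients), c(1, 2, 0.5), tolerance = 1e-6)
  f1 <- pglsFit(x, y, tr, degree = 1)
  expect_lt(f2$AICc, f1$AICc)
})

test_that("slope estimates are invariant to the logarithm base", {
  tr <- simYuleTree(30, seed = 12)
  sa <- simAllometry(tr, slope = 0.33, intercept = 1, sigma2_resid = 0.05,
                     seed = 13)
  f10 <- pglsFit(sa$x, sa$y, tr)
  conv <- log(10)   # base-10 logs -> natural logs
  fln <- pglsFit(sa$x * conv, sa$y * conv, tr)
  expect_equal(unname(fln$coefficients["b1"]),
               unname(f10$coefficients["b1"]), tolerance = 1e-8)
  expect_equal(unname(fln$coefficients["b0"]),
               unname(f10$coefficients["b0"]) * conv, tolerance = 1e-8)
  expect_equal(fln$lambda, f10$lambda, tolerance = 1e-4)
})

test_that("degenerate designs are rejected", {
  tr <- simYuleTree(10, seed = 1)
  x <- setNames(rep(1, 10), tr$tip.label)
  y <- setNames(rnorm(10), tr$tip.label)
  expect_error(pglsFit(x, y, tr), "constant")
  expect_error(olsFit(x, y), "constant")
  tr3 <- readNewickTree("((A:1,B:1):1,C:2);")
  expect_error(pglsFit(c(A = 1, B = 2, C = 3), c(A = 1, B = 2, C = 3),
                       tr3, degree = 2), "degree \\+ 2")
})

test_that("AICc follows its formula and guards its domain", {
  expect_equal(aicc(0, 1, 3), 6)
  expect_equal(aicc(-10, 2, 1e7), -2 * (-10) + 4, tolerance = 1e-4)
  expect_error(aicc(0, 2, 3), "exceed")
})

test_that("Akaike weights normalise and break ties toward fewer parameters", {
  w <- akaikeWeights(c(m1 = 10, m2 = 10))
  expect_equal(w$weight, c(0.5, 0.5))
  w2 <- akaikeWeights(c(a = 4, b = 6))
  expect_equal(w2$weight, c(0.7310586, 0.2689414), tolerance = 1e-6)
  expect_equal(sum(w2$weight), 1)
  expect_error(akaikeWeights(5), "two models")
  expect_error(akaikeWeights(c(Inf, Inf)), "infinite")
  tie <- akaikeWeights(c(big = 3, small = 3), k = c(big = 5, small = 2))
  expect_equal(preferredModel(tie), "small")
})

test_that("isometry classification follows the confidence interval", {
  mk_fit <- function(slope, lo, hi) {
    structure(list(degree = 1, coefficients = c(b0 = 0, b1 = slope),
                   ci = rbind(b0 = c(-1, 1), b1 = c(lo, hi))),
              class = "pglsFit")
  }
  expect_equal(isometryTest(mk_fit(0.33, 0.30, 0.36), 1 / 3)$classification,
               "isometric")
  expect_equal(isometryTest(mk_fit(0.27, 0.25, 0.30), 1 / 3)$classification,
               "negative allometry")
  expect_equal(isometryTest(mk_fit(1.2, 1.1, 1.3), 1)$classification,
               "positive allometry")
  # volume-vs-volume convention: expected slope 1
  tr <- simYuleTree(40, seed = 3)
  sa <- simAllometry(tr, slope = 1, sigma2_resid = 0.01, seed = 4)
  f <- pglsFit(sa$x, sa$y, tr)
  expect_equal(isometryTest(f, 1)$classification, "isometric")
})

test_that("binned slopes recover a piecewise allometry and reject empty bins", {
  tr <- simYuleTree(200, seed = 21)
  sa <- simAllometry(tr, slope = 1, sigma2_resid = 1e-8, seed = 22)
  x <- sa$x
  thr <- stats::median(x)
  ylo <- 1.0 * x; yhi <- 0.6 * (x - thr) + 1.0 * thr
  y <- ifelse(x < thr, ylo, yhi); names(y) <- names(x)
  bs <- binnedSlopes(x, y, tr, thr)
  expect_equal(unname(bs[[1]]$below$coefficients["b1"]), 1.0, tolerance = 0.05)
  expect_equal(unname(bs[[1]]$above$coefficients["b1"]), 0.6, tolerance = 0.05)
  expect_lt(bs[[1]]$contrast["p"], 0.05)
  expect_error(binnedSlopes(x, y, tr, max(x) + 1), "fewer than")

  # identical slopes on both sides: contrast near zero
  y2 <- 0.8 * x; names(y2) <- names(x)
  bs2 <- binnedSlopes(x, y2, tr, thr)
  expect_equal(unname(bs2[[1]]$contrast["slope_diff"]), 0, tolerance = 1e-6)
})

test_that("mass thresholds convert to the log-WBCHV scale", {
  expect_equal(wbchvThreshold(1000), 0)                  # 1000 kg ~ 1 m^3
  expect_equal(wbchvThreshold(25), log10(0.025))
  expect_equal(wbchvThreshold(100, density_coefficient = 100), 0)
})
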