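test_that("Yule trees have the expected shape and are seed-reproducible", {
  tr <- simYuleTree(2, seed = 201)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(tr$Nnode, 1)

  t1 <- simYuleTree(20, seed = 202, extinct_fraction = 0.3)
  t2 <- simYuleTree(20, seed = 202, extinct_fraction = 0.3)
  expect_identical(writeNewickTree(t1), writeNewickTree(t2))

  expect_true(all(tipAges(simYuleTree(30, seed = 203)) == 0))
  ages <- tipAges(simYuleTree(30, seed = 204, extinct_fraction = 0.4))
  expect_equal(sum(ages > 0), 12)
  expect_error(simYuleTree(1), ">= 2")
  expect_error(simYuleTree(5, birth_rate = 0), "> 0")
  expect_error(simYuleTree(5, extinct_fraction = 1), "extinct_fraction")
})

test_that("mean Yule depth matches the analytic expectation", {
  n <- 10; b <- 1
  expected <- sum(1 / (b * (2:(n - 1)))) + 1 / (b * n)
  depths <- vapply(1:400, function(i) {
    max(ape::node.depth.edgelength(simYuleTree(n, b, seed = 30000 + i)))
  }, 0)
  mcse <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * mcse)
})

test_that("discrete simulation is consistent and returns a valid painting", {
  tr <- simYuleTree(30, seed = 211)
  Q0 <- mkModel(c("A", "B"), "ER", rates = 0)$Q
  sim0 <- simDiscrete(tr, Q0, seed = 212)
  expect_equal(length(unique(sim0$tip_states)), 1)
  expect_equal(countTransitions(sim0$painting), 0)

  Q <- mkModel(c("A", "B", "C"), "SYM", rates = c(0.05, 0.1, 0.02))$Q
  sim <- simDiscrete(tr, Q, seed = 213)
  expect_true(validatePainting(sim$painting, tol = 1e-12))
  expect_equal(tipStates(sim$painting), sim$tip_states)
  expect_identical(simDiscrete(tr, Q, seed = 213)$tip_states, sim$tip_states)
})

test_that("trait simulation is deterministic under a seed and concentrates under strong pull", {
  fxtree <- simYuleTree(15, seed = 221)
  one <- onePainting(fxtree)
  p <- regimeParams(sigma2 = 0.5, alpha = 8, theta = 3, y0 = -5)
  y1 <- simTrait(fxtree, one, p, seed = 222)
  y2 <- simTrait(fxtree, one, p, seed = 222)
  expect_identical(y1, y2)
  # stationary sd = sqrt(s2/(2a)) ~ 0.18; all tips should sit near theta
  expect_true(all(abs(y1 - 3) < 1.5))
})

test_that("BM cherry trait moments match theory", {
  tr <- cherryTree(1)
  one <- onePainting(tr)
  p <- regimeParams(1, 0, 0, y0 = 0)
  sims <- vapply(1:2000, function(i) simTrait(tr, one, p, seed = 40000 + i),
                 numeric(2))
  v <- stats::var(t(sims))
  expect_equal(v[1, 1], 1, tolerance = 0.15)
  expect_equal(v[1, 2], 0, tolerance = 0.15)  # no shared path on a cherry
})

test_that("allometry simulation behaves as specified", {
  tr <- simYuleTree(50, seed = 231)
  sa <- simAllometry(tr, slope = 1 / 3, intercept = -0.5,
                     sigma2_resid = 1e-10, seed = 232)
  f <- pglsFit(sa$x, sa$y, tr)
  expect_equal(unname(f$coefficients["b1"]), 1 / 3, tolerance = 1e-4)
  expect_equal(unname(f$coefficients["b0"]), -0.5, tolerance = 1e-4)
  expect_error(simAllometry(tr, sigma2_resid = 0), "> 0")
})

test_that("occurrence simulation round-trips through equal dating", {
  tr <- simYuleTree(20, seed = 241, extinct_fraction = 0.3)
  occ0 <- simOccurrences(tr, jitter = 0)
  expect_equal(setNames(occ0$fad, occ0$taxon), tipAges(tr))

  occ <- simOccurrences(tr, jitter = 2, seed = 242)
  expect_true(all(occ$fad >= occ$lad))
  topo <- tr; topo$edge.length <- NULL
  redated <- dateTreeEqual(timeTree(topo), occ, root_extension = 5)
  expect_true(all(redated$edge.length > 0))
  expect_equal(unname(tipAges(redated)[occ$taxon]), occ$fad, tolerance = 1e-9)
})

test_that("a full synthetic study is coherent and bit-reproducible", {
  st1 <- makeSyntheticStudy(n_tips = 40, seed = 251)
  st2 <- makeSyntheticStudy(n_tips = 40, seed = 251)
  expect_identical(st1$trait, st2$trait)
  expect_identical(st1$segments$WBCHV, st2$segments$WBCHV)
  expect_true(validatePainting(st1$painting))
  expect_equal(sort(unique(names(st1$diet))), sort(st1$tree$tip.label))
  # WBCHV is the sum of the generated segment volumes
  vm <- as.matrix(st1$segments[, skelevol:::.volumeCols])
  expect_equal(st1$segments$WBCHV, unname(rowSums(vm)), tolerance = 1e-9)
  expect_equal(log10(st1$segments$WBCHV),
               unname(st1$trait[st1$segments$taxon]), tolerance = 1e-9)
})

test_that("study fixtures are written in consumable formats", {
  st <- makeSyntheticStudy(n_tips = 20, seed = 261)
  dir <- tempfile("study")
  writeStudy(st, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "occurrences.csv",
                                               "segments.csv", "diet.csv",
                                               "trait.csv")))))
  tr <- readNewickTree(file = file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(st$tree$tip.label))
  seg <- readSegmentTable(file.path(dir, "segments.csv"))
  expect_equal(seg$WBCHV, st$segments$WBCHV, tolerance = 1e-6)
  diet <- readTipStates(file.path(dir, "diet.csv"))
  expect_equal(diet[names(st$diet)], st$diet)
})
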