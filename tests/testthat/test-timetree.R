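test_that("Newick parsing handles dated trees, cladograms and bad input", {
  tr <- readNewickTree("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "timeTree")
  expect_true(isDated(tr))
  expect_equal(ape::Ntip(tr), 3)
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(d, c(2, 2, 2))

  topo <- readNewickTree("((A,B),C);")
  expect_false(isDated(topo))
  expect_error(.assertDated <- tipAges(topo), "undated")

  expect_error(readNewickTree("((A:1,A:1):1);"), "duplicate")
})

test_that("Newick round-trip preserves topology and durations", {
  tr <- simYuleTree(25, seed = 11, extinct_fraction = 0.2)
  txt <- writeNewickTree(tr)
  back <- readNewickTree(txt)
  expect_true(ape::all.equal.phylo(structure(tr, class = "phylo"),
                                   structure(back, class = "phylo"),
                                   tolerance = 1e-9))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
})

test_that("equal-method dating reproduces the hand-derived worked example", {
  topo <- readNewickTree("((A,B),C);")
  occ <- occurrenceRanges(c("A", "B", "C"), fad = c(10, 20, 30))
  tr <- dateTreeEqual(topo, occ, root_extension = 10)
  expect_equal(rootAge(tr), 40)
  expect_equal(tipAges(tr), c(A = 10, B = 20, C = 30))
  # durations keyed by child node label where tips, else by parent
  get_dur <- function(child_label) {
    tr$edge.length[match(match(child_label, tr$tip.label), tr$edge[, 2])]
  }
  expect_equal(get_dur("A"), 20)
  expect_equal(get_dur("B"), 10)
  expect_equal(get_dur("C"), 10)
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(tr$edge.length[match(ab, tr$edge[, 2])], 10)
})

test_that("nodes off the zero chains keep their oldest-descendant-FAD ages", {
  # the node above the oldest tip always starts on a zero branch and is
  # raised by equal sharing; other branches are left untouched
  topo <- readNewickTree("((A,B),C);")
  occ <- occurrenceRanges(c("A", "B", "C"), fad = c(5, 15, 30))
  tr <- dateTreeEqual(topo, occ, root_extension = 7)
  expect_equal(rootAge(tr), 37)
  # C keeps its position: branch root -> C spans 37 - 30
  cdur <- tr$edge.length[match(match("C", tr$tip.label), tr$edge[, 2])]
  expect_equal(cdur, 7)
  # node (A,B) starts at 15 (tied with B) and is raised to the midpoint of
  # the root-to-B span: (37 + 15) / 2 = 26
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(rootAge(tr) - ape::node.depth.edgelength(tr)[ab], 26)
  expect_true(all(tr$edge.length > 0))
})

test_that("dating errors on missing taxa and invalid root extension", {
  topo <- readNewickTree("((A,B),C);")
  occ <- occurrenceRanges(c("A", "B"), fad = c(10, 20))
  expect_error(dateTreeEqual(topo, occ), "missing")
  occ3 <- occurrenceRanges(c("A", "B", "C"), fad = c(10, 20, 30))
  expect_error(dateTreeEqual(topo, occ3, root_extension = 0), "> 0")
  expect_error(occurrenceRanges("A", fad = -1), "negative|fad")
})

test_that("equal dating always yields strictly positive durations", {
  set.seed(42)
  for (r in 1:200) {
    phy <- ape::rtree(8, br = NULL)
    topo <- timeTree(phy)
    occ <- occurrenceRanges(phy$tip.label, fad = round(runif(8, 0, 50), 1))
    tr <- dateTreeEqual(topo, occ, root_extension = runif(1, 0.5, 20))
    expect_true(all(tr$edge.length > 0))
    expect_equal(unname(tipAges(tr)[occ$taxon]), occ$fad, tolerance = 1e-9)
  }
})

test_that("BM covariance matches hand-derived path sums and invariants", {
  tr <- readNewickTree("((A:1,B:1):1,C:2);")
  C <- bmCovariance(tr)
  expect_equal(C["A", "A"], 2); expect_equal(C["B", "B"], 2)
  expect_equal(C["C", "C"], 2); expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0); expect_equal(C["B", "C"], 0)

  tr2 <- simYuleTree(40, seed = 2, extinct_fraction = 0.25)
  C2 <- bmCovariance(tr2)
  expect_equal(C2, t(C2))
  expect_true(min(eigen(C2, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  # diagonal equals independently computed root-to-tip depths
  expect_equal(unname(diag(C2)),
               ape::node.depth.edgelength(tr2)[seq_len(40)], tolerance = 1e-12)
})

test_that("lambda transform scales off-diagonals only and is monotone", {
  tr <- simYuleTree(10, seed = 5)
  C <- bmCovariance(tr)
  expect_equal(lambdaTransform(C, 1), C)
  expect_equal(lambdaTransform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  h <- lambdaTransform(C, 0.5)
  expect_equal(diag(h), diag(C))
  off <- row(C) != col(C)
  expect_equal(h[off], 0.5 * C[off])
  l1 <- lambdaTransform(C, 0.3); l2 <- lambdaTransform(C, 0.7)
  expect_true(all(l1[off] <= l2[off]))
  expect_error(lambdaTransform(C, 1.5), "\\[0, 1\\]")
  expect_error(lambdaTransform(C, -0.1), "\\[0, 1\\]")
})
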