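test_that("Newick parsing validates and round-trips", {
  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(ape::Ntip(tr), 4)
  expect_true(isUltrametric(tr))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  two <- parseNewick("(A:1,B:1);")
  expect_equal(crossgroupMPD(two, "A", "B"), 2)

  expect_error(parseNewick("((A:1,A:1):1,B:2);"), "duplicate tip")
  expect_error(parseNewick("not a tree((("))

  # round-trip preserves topology, names and lengths (patristic identity)
  for (s in 1:25) {
    tr <- randTree(sample(5:40, 1), seed = s)
    tr2 <- parseNewick(writeNewick(tr))
    D1 <- stats::cophenetic(tr)
    D2 <- stats::cophenetic(tr2)[rownames(D1), colnames(D1)]
    expect_lt(max(abs(D1 - D2)), 1e-8)
  }
})

test_that("edge-contribution MPD equals the brute-force patristic mean", {
  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(crossgroupMPD(tr, "A", c("C", "D")), 4)
  expect_equal(crossgroupMPD(tr, c("A", "B"), c("C", "D")), 4)

  for (s in 1:40) {
    tr <- randTree(sample(5:60, 1), seed = 100 + s)
    sets <- randDisjointSets(tr, seed = 200 + s)
    expect_equal(crossgroupMPD(tr, sets$aliens, sets$natives),
                 bruteMPD(tr, sets$aliens, sets$natives), tolerance = 1e-11)
    # symmetry
    expect_equal(crossgroupMPD(tr, sets$aliens, sets$natives),
                 crossgroupMPD(tr, sets$natives, sets$aliens))
    # linearity engine agrees
    S <- distancesToSet(tr, sets$natives)
    expect_equal(mean(S[sets$aliens]) / length(sets$natives),
                 crossgroupMPD(tr, sets$aliens, sets$natives),
                 tolerance = 1e-11)
  }

  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(crossgroupMPD(tr, character(0), "A"), "empty")
  expect_error(crossgroupMPD(tr, c("A", "B"), c("B", "C")), "overlap")
})

test_that("MPD agrees with picante's cross-community form", {
  skip_if_not_installed("picante")
  tr <- randTree(30, seed = 7)
  sets <- randDisjointSets(tr, seed = 8)
  comm <- matrix(0, 2, 30, dimnames = list(c("al", "na"), tr$tip.label))
  comm["al", sets$aliens] <- 1
  comm["na", sets$natives] <- 1
  ref <- as.numeric(picante::comdist(comm, stats::cophenetic(tr)))
  expect_equal(crossgroupMPD(tr, sets$aliens, sets$natives), ref,
               tolerance = 1e-9)
})

test_that("MPD scales with branch lengths and ignores the root position", {
  tr <- randTree(25, seed = 9)
  sets <- randDisjointSets(tr, seed = 10)
  m <- crossgroupMPD(tr, sets$aliens, sets$natives)
  for (c in c(0.5, 3)) {
    trc <- tr
    trc$edge.length <- trc$edge.length * c
    expect_equal(crossgroupMPD(trc, sets$aliens, sets$natives), c * m,
                 tolerance = 1e-12)
  }
  rerooted <- ape::root(ape::unroot(tr),
                        outgroup = sets$natives[1], resolve.root = TRUE)
  expect_equal(crossgroupMPD(rerooted, sets$aliens, sets$natives), m,
               tolerance = 1e-9)
})

test_that("MNTD matches the min-row oracle", {
  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(crossgroupMNTD(tr, "A", c("B", "C")), 2)
  expect_equal(crossgroupMNTD(tr, c("A", "B"), c("C", "D")), 4)
  for (s in 1:10) {
    tr <- randTree(sample(6:40, 1), seed = 300 + s)
    sets <- randDisjointSets(tr, seed = 400 + s)
    D <- stats::cophenetic(tr)
    ref <- mean(apply(D[sets$aliens, sets$natives, drop = FALSE], 1, min))
    expect_equal(crossgroupMNTD(tr, sets$aliens, sets$natives), ref,
                 tolerance = 1e-11)
  }
})

test_that("grafting attaches at crown nodes and keeps the tree ultrametric", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  tax <- taxonomyMap(c("A", "B", "C", "X", "Y"),
                     c("G1", "G1", "G2", "G1", "G3"),
                     c("F1", "F1", "F1", "F1", "F1"))
  g <- graftMissingSpecies(tr, tax, c("X", "Y"))
  expect_equal(graftReport(g),
               list(added_at_genus = 1, added_at_family = 1))
  d <- ape::node.depth.edgelength(g)[seq_len(5)]
  expect_lt(max(abs(d - 2)), 1e-12)
  # X shares the genus crown with A and B
  expect_equal(unname(stats::cophenetic(g)["X", "A"]), 2)
  # Y attaches at the family root spanning the whole tree
  expect_equal(unname(stats::cophenetic(g)["Y", "C"]), 4)

  expect_error(graftMissingSpecies(tr, tax, "A"), "already present")
  taxNo <- taxonomyMap(c("A", "B", "C", "Z"), c("G1", "G1", "G2", "G9"),
                       c("F1", "F1", "F1", "F9"))
  expect_error(graftMissingSpecies(tr, taxNo, "Z"), "Z")
})

test_that("monotypic-genus grafts split the pendant edge", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  tax <- taxonomyMap(c("A", "B", "C", "W"), c("G1", "G1", "G2", "G2"),
                     c("F1", "F1", "F1", "F1"))
  g <- graftMissingSpecies(tr, tax, "W")  # default: split at half length
  D <- stats::cophenetic(g)
  expect_equal(unname(D["W", "C"]), 2)     # joined at height 1
  expect_true(isUltrametric(g, tol = 1e-9))
  g2 <- graftMissingSpecies(tr, tax, "W", monotypic = "parent")
  expect_equal(unname(stats::cophenetic(g2)["W", "C"]), 4)
})

test_that("a depth audit passes after many congeneric grafts", {
  tr <- randTree(40, seed = 11)
  H <- max(ape::node.depth.edgelength(tr))
  genus <- paste0("G", rep(1:8, each = 5))
  extra <- sprintf("new%02d", 1:20)
  tax <- taxonomyMap(c(tr$tip.label, extra),
                     c(genus, sample(paste0("G", 1:8), 20, replace = TRUE)),
                     rep("F1", 60))
  g <- graftMissingSpecies(tr, tax, extra)
  depths <- ape::node.depth.edgelength(g)[seq_len(60)]
  expect_lt(max(abs(depths - H)), 1e-9)
  # graft-then-prune restores the original patristic matrix
  back <- ape::drop.tip(g, extra)
  D0 <- stats::cophenetic(tr)
  D1 <- stats::cophenetic(back)[rownames(D0), colnames(D0)]
  expect_lt(max(abs(D0 - D1)), 1e-9)
})

test_that("collapsing to a rank keeps crown structure and is idempotent", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  tax <- taxonomyMap(c("A", "B", "C"), c("G1", "G1", "G2"),
                     c("F1", "F1", "F1"))
  col <- collapseToRank(tr, tax, "genus")
  D0 <- stats::cophenetic(tr)
  D1 <- stats::cophenetic(col)[rownames(D0), colnames(D0)]
  expect_lt(max(abs(D0 - D1)), 1e-12)   # already genus-polytomous

  # species-level structure is removed; between-genus paths preserved
  sim <- simulateTree(40, 1, seed = 21, nGenera = 6, nFamilies = 2)
  colg <- collapseToRank(sim$tree, sim$taxonomy, "genus")
  expect_true(isUltrametric(colg, tol = 1e-8))
  expect_setequal(colg$tip.label, sim$tree$tip.label)
  again <- collapseToRank(colg, sim$taxonomy, "genus")
  Da <- stats::cophenetic(colg)
  Db <- stats::cophenetic(again)[rownames(Da), colnames(Da)]
  expect_lt(max(abs(Da - Db)), 1e-8)

  # MPD perturbation is bounded by twice the deepest within-genus crown
  depths <- ape::node.depth.edgelength(sim$tree)
  H <- max(depths[seq_len(40)])
  crowns <- vapply(split(sim$taxonomy@species, sim$taxonomy@genus),
                   function(tips) {
                     if (length(tips) < 2) return(0)
                     H - depths[ape::getMRCA(sim$tree, tips)]
                   }, numeric(1))
  sets <- randDisjointSets(sim$tree, seed = 22)
  dfull <- crossgroupMPD(sim$tree, sets$aliens, sets$natives)
  dcol <- crossgroupMPD(colg, sets$aliens, sets$natives)
  expect_lt(abs(dfull - dcol), 2 * max(crowns) + 1e-9)

  badTax <- taxonomyMap("A", "G1", "F1")
  expect_error(collapseToRank(tr, badTax, "genus"), "not mapped")
})
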