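test_that("variable transforms are monotone, replayable and normalizing", {
  x <- c(0, exp(1) - 1)
  expect_equal(transformVariable(x, list(name = "log1p_shift", shift = 0)),
               c(0, 1))
  expect_equal(transformVariable(x, list(name = "identity")), x)

  set.seed(1)
  ln <- exp(rnorm(500, 0, 1))          # strongly right-skewed
  spec <- fitTransform(ln, "power")
  y <- transformVariable(ln, spec)
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  expect_gt(abs(skew(ln)), 1)
  expect_lt(abs(skew(y)), 0.5)
  # monotone
  expect_true(all(diff(y[order(ln)]) >= 0))
  # replay on new data uses the stored exponent
  expect_identical(transformVariable(ln[1:5], spec),
                   transformVariable(ln, spec)[1:5])
})

test_that("the climate PCA explains variance and reconstructs the data", {
  # two perfectly correlated variables: one axis carries everything
  set.seed(2)
  g <- data.frame(region_id = "R1", cell_id = paste0("c", 1:30),
                  bio1 = rnorm(30))
  g$bio2 <- 2 * g$bio1
  pca <- fitClimatePCA(g, transforms = "identity", vars = c("bio1", "bio2"))
  expect_equal(pca@varExplained[1], 1, tolerance = 1e-10)

  # independent equal-variance pair: roughly even split
  g$bio2 <- rnorm(30)
  pca2 <- fitClimatePCA(g, transforms = "identity",
                        vars = c("bio1", "bio2"))
  expect_lt(abs(pca2@varExplained[1] - 0.5), 0.25)

  # full reconstruction from all components
  grid <- toyGrid(40)
  pca3 <- fitClimatePCA(grid, transforms = "identity")
  sc <- pcaScores(pca3, grid, comps = seq_along(pca3@sdev))
  rec <- sc %*% t(pca3@rotation)
  Z <- scale(as.matrix(grid[, bioclimVariables()]),
             center = pca3@center, scale = pca3@scale)
  expect_lt(max(abs(rec - Z)), 1e-8)

  # axis orientation: warm loads positive on 1, wet positive on 2
  expect_gte(pca3@rotation["bio1", 1], 0)
  expect_gte(pca3@rotation["bio12", 2], 0)

  g$bio2 <- 1  # constant after transform
  expect_error(fitClimatePCA(g, transforms = "identity",
                             vars = c("bio1", "bio2")),
               "zero-variance")
  expect_error(fitClimatePCA(grid[1:10, ], transforms = "identity"),
               "at least 20")
})

test_that("region scores average the cell scores", {
  grid <- toyGrid(40)
  pca <- fitClimatePCA(grid, transforms = "identity")
  sc <- pcaScores(pca, grid)
  byRegion <- regionPCScores(pca, grid)
  manual <- tapply(sc[, 1], grid$region_id, mean)
  expect_equal(byRegion$pc_temp, as.numeric(manual[byRegion$region_id]),
               tolerance = 1e-10)
  one <- regionPCScores(pca, grid, region = grid$region_id[1])
  idx <- grid$region_id == grid$region_id[1]
  expect_equal(unname(one["pc_temp"]), mean(sc[idx, 1]), tolerance = 1e-10)
  expect_error(regionPCScores(pca, grid, region = "nope"), "unknown region")

  # with identity transforms (linear), score of the mean equals mean score
  mr <- stats::aggregate(grid[, bioclimVariables()],
                         list(region_id = grid$region_id), mean)
  scMean <- pcaScores(pca, mr)
  expect_equal(unname(scMean[match(byRegion$region_id, mr$region_id), 1]),
               byRegion$pc_temp, tolerance = 1e-9)
})

test_that("AUC follows the rank-sum definition and its invariances", {
  expect_equal(evaluateAUC(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(evaluateAUC(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(3)
  for (i in 1:20) {
    pos <- sample(1:8, 12, replace = TRUE) / 8
    neg <- sample(1:8, 15, replace = TRUE) / 8
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(evaluateAUC(pos, neg), brute, tolerance = 1e-12)
    # invariant under a strictly monotone transform
    expect_equal(evaluateAUC(exp(3 * pos), exp(3 * neg)), brute,
                 tolerance = 1e-12)
  }
  expect_error(evaluateAUC(numeric(0), 1), "non-empty")
})

test_that("max-SSS threshold matches exhaustive enumeration", {
  expect_equal(maxSSSThreshold(c(0.9, 0.8, 0.2, 0.1),
                               c(TRUE, TRUE, FALSE, FALSE)), 0.8)
  # separable case: threshold is the smallest presence score
  expect_equal(maxSSSThreshold(c(0.7, 0.5, 0.4, 0.2), c(1, 1, 0, 0)), 0.5)
  bruteSSS <- function(scores, labels) {
    cand <- sort(unique(scores), decreasing = TRUE)
    best <- -Inf; bestT <- NA
    for (th in cand) {
      sens <- mean(scores[labels] >= th)
      spec <- mean(scores[!labels] < th)
      if (sens + spec > best + 1e-12) { best <- sens + spec; bestT <- th }
    }
    bestT
  }
  set.seed(4)
  for (i in 1:30) {
    scores <- sample(1:10, 25, replace = TRUE) / 10
    labels <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (!any(labels) || all(labels)) next
    th <- maxSSSThreshold(scores, labels)
    expect_equal(th, bruteSSS(scores, labels))
    # maximality over every candidate
    sssAt <- function(t) mean(scores[labels] >= t) + mean(scores[!labels] < t)
    expect_true(all(sssAt(th) >= vapply(unique(scores), sssAt,
                                        numeric(1)) - 1e-12))
  }
  expect_error(maxSSSThreshold(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("the envelope scorer peaks at the centroid and decays outward", {
  set.seed(5)
  n <- 40
  pres <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(pres) <- sdmVariables()
  bg <- as.data.frame(matrix(rnorm(3 * n * 6, mean = 4), 3 * n, 6))
  names(bg) <- sdmVariables()
  m <- fitEnvelopeModel(pres, bg, species = "sp1", seed = 1)
  # score 1 at the training mean
  mu <- as.data.frame(as.list(m@mu))
  expect_equal(envelopeScores(m, mu), 1)
  # monotone decay along a ray from the mean
  ray <- do.call(rbind, lapply(seq(0, 4, by = 0.5), function(t)
    mu + t * rep(1, 6)))
  expect_true(all(diff(envelopeScores(m, ray)) <= 1e-12))
  # linearly separable presences vs background: perfect AUC, retained
  expect_equal(m@auc, 1)
  expect_true(m@retained)

  expect_error(fitEnvelopeModel(pres[1:10, ], bg), "presence cells")
  expect_error(fitEnvelopeModel(pres, bg[1:5, ]), "background")
})

test_that("suitable regions grow monotonically as the threshold drops", {
  set.seed(6)
  # habitat regions R1..R5 sit at the niche centre; R6..R15 are displaced
  nCells <- 15 * 8
  grid <- data.frame(region_id = rep(paste0("R", 1:15), each = 8),
                     cell_id = paste0("c", seq_len(nCells)))
  shift <- rep(c(0, 4), c(5 * 8, 10 * 8))
  for (v in sdmVariables()) grid[[v]] <- rnorm(nCells) + shift
  inHab <- grid$region_id %in% paste0("R", 1:5)
  warm <- grid[inHab, ][sample(sum(inHab), 25), ]
  m <- fitEnvelopeModel(warm, grid[!grid$cell_id %in% warm$cell_id, ],
                        species = "warmSp", seed = 2)
  expect_true(m@retained)
  regs <- suitableRegions(m, grid)
  expect_true(warm$region_id[1] %in% regs)
  prev <- character(0)
  for (thr in sort(unique(envelopeScores(m, grid)), decreasing = TRUE)) {
    m2 <- m; m2@threshold <- thr
    cur <- suitableRegions(m2, grid)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  m3 <- m; m3@auc <- 0.5; m3@retained <- FALSE
  expect_error(suitableRegions(m3, grid), "not retained")
})

test_that("the suitability table keeps retained species and logs skips", {
  w <- generateWorld(tinyParams(seed = 30))
  occ <- natphylo:::occurrencesFromRegions(worldRegions(w), worldClimate(w))
  # restrict to a few species to keep this focused
  keep <- names(sort(table(occ$species), decreasing = TRUE))[c(1:3, 110:118)]
  suit <- buildSuitabilityTable(occ[occ$species %in% keep, ],
                                worldClimate(w), seed = 1)
  skipped <- attr(suit, "skipped")
  expect_true(all(names(suit) %in% keep))
  expect_s4_class(attr(suit, "models")[[1]], "EnvelopeModel")
  # every species is either retained or skipped with a reason
  expect_setequal(c(names(suit), skipped$species), unique(keep))
})
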