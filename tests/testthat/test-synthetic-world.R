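test_that("tree simulation is deterministic, ultrametric and Yule-like", {
  s4 <- simulateTree(4, 1, seed = 1)
  expect_equal(ape::Ntip(s4$tree), 4)
  expect_true(isUltrametric(s4$tree, tol = 1e-9))

  a <- simulateTree(30, 1, seed = 9)
  b <- simulateTree(30, 1, seed = 9)
  expect_identical(writeNewick(a$tree), writeNewick(b$tree))

  # E[lineages at depth t] = 2 exp(b t) for the unconditioned pure birth
  tcut <- 1.2; b1 <- 1
  counts <- vapply(1:300, function(s) {
    tr <- simulateTree(60, b1, seed = 5000 + s)$tree
    d <- ape::node.depth.edgelength(tr)
    ends <- ifelse(tr$edge[, 2] <= ape::Ntip(tr), max(d), d[tr$edge[, 2]])
    sum(d[tr$edge[, 1]] <= tcut & ends > tcut)
  }, numeric(1))
  expected <- 2 * exp(b1 * tcut)
  sdYule <- sqrt(2 * exp(b1 * tcut) * (exp(b1 * tcut) - 1))
  expect_lt(abs(mean(counts) - expected), 3 * sdYule / sqrt(300))
})

test_that("clade-cut taxonomy is monophyletic and nested", {
  sim <- simulateTree(80, 1, seed = 13, nGenera = 12, nFamilies = 4)
  tax <- sim$taxonomy
  expect_equal(length(unique(tax@genus)), 12)
  expect_equal(length(unique(tax@family)), 4)
  for (g in unique(tax@genus)) {
    tips <- tax@species[tax@genus == g]
    if (length(tips) < 2) next
    m <- ape::getMRCA(sim$tree, tips)
    expect_setequal(ape::extract.clade(sim$tree, m)$tip.label, tips)
  }
  # genera nest within families
  expect_true(all(tapply(tax@family, tax@genus,
                         function(f) length(unique(f))) == 1))
})

test_that("Brownian niche traits obey the variance/covariance identities", {
  tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  zero <- simulateNicheTraits(tr, 0, seed = 1)
  expect_equal(unname(zero), rep(0, 4))

  sims <- vapply(1:600, function(s)
    simulateNicheTraits(tr, traitSigma2 = 2, seed = s), numeric(4))
  v <- apply(sims, 1, var)
  expect_equal(mean(v), 2 * 2, tolerance = 0.15)     # sigma2 * depth
  covAB <- cov(sims["A", ], sims["B", ])              # shared path = 1
  expect_equal(covAB, 2 * 1, tolerance = 0.3)
  covAC <- cov(sims["A", ], sims["C", ])              # no shared path
  expect_lt(abs(covAC), 0.3)
})

test_that("regions carry a latitude-driven climate template", {
  p <- worldParams(n_regions = 30, cells_per_region = 5)
  rg <- buildRegions(p, seed = 3)
  expect_equal(nrow(rg$climate), 30 * 5)
  expect_true(all(table(rg$climate$region_id) == 5))
  info <- regionInfo(rg$regions)
  m1 <- tapply(rg$climate$bio1, rg$climate$region_id, mean)[info$region_id]
  expect_lt(stats::cor(m1, abs(info$latitude)), -0.9)

  # zero climate noise: bio1 is an exact monotone function of |latitude|
  p0 <- worldParams(n_regions = 30, cells_per_region = 4,
                    climate_noise_sd = 0, cell_lat_jitter = 0)
  rg0 <- buildRegions(p0, seed = 3)
  info0 <- regionInfo(rg0$regions)
  b1 <- tapply(rg0$climate$bio1, rg0$climate$region_id,
               mean)[info0$region_id]
  expect_equal(as.numeric(b1), 28 - 0.55 * abs(info0$latitude),
               tolerance = 1e-10)
})

test_that("poleward filtering clusters native assemblages", {
  p <- tinyParams(seed = 17)
  sim <- simulateTree(p$n_species, p$birth_rate, seed = 1,
                      nGenera = p$n_genera, nFamilies = p$n_families)
  opt <- simulateNicheTraits(sim$tree, 1, seed = 2)
  rg <- buildRegions(p, seed = 3)
  nat <- assembleNatives(rg$regions, rg$climate, opt, p, seed = 4)
  expect_true(all(lengths(nat) > 0))
  info <- regionInfo(rg$regions)
  withinMPD <- vapply(info$region_id, function(r) {
    tips <- nat[[r]]
    mean(distancesToSet(sim$tree, tips)[tips]) / (length(tips) - 1)
  }, numeric(1))
  expect_lt(stats::cor(withinMPD, abs(info$latitude)), -0.3)

  # flat filtering: no latitudinal trend in clustering (CI covers zero)
  pf <- tinyParams(seed = 18, filtering_latitude_coefficient = 0)
  natF <- assembleNatives(rg$regions, rg$climate, opt, pf, seed = 4)
  withinF <- vapply(info$region_id, function(r) {
    tips <- natF[[r]]
    mean(distancesToSet(sim$tree, tips)[tips]) / (length(tips) - 1)
  }, numeric(1))
  fit <- stats::lm(withinF ~ abs(info$latitude))
  ci <- stats::confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("the naturalization process matches its closed-form prevalence", {
  p <- tinyParams(seed = 19, beta_mpd = 0, beta_lat = 0, beta_int = 0,
                  sd_species = 0, sd_region = 0)
  w <- generateWorld(p)
  tab <- naturalizationTable(w)
  target <- 1 - exp(-exp(p$beta0))
  se <- sqrt(target * (1 - target) / nrow(tab))
  expect_lt(abs(mean(tab$naturalized) - target), 4 * se)

  # identical seeds give identical tables
  w2 <- generateWorld(p)
  expect_identical(naturalizationTable(w2), tab)
})

test_that("a negative interaction flattens the MPD effect toward the equator", {
  w <- generateWorld(worldParams(seed = 23))
  tab <- naturalizationTable(w)
  band <- cut(tab$abs_latitude, breaks = c(-1, 20, 40, 90),
              labels = c("low", "mid", "high"))
  slopes <- vapply(levels(band), function(b) {
    d <- tab[band == b, ]
    stats::coef(stats::glm(naturalized ~ scale(mpd_to_natives),
                           family = stats::binomial("cloglog"),
                           data = d))[2]
  }, numeric(1))
  expect_gt(slopes["low"], slopes["high"])   # preadaptation poleward
})

test_that("worlds are reproducible end-to-end and satisfy preconditions", {
  p <- tinyParams(seed = 29)
  w <- generateWorld(p)
  rs <- worldRegions(w)
  expect_true(all(lengths(rs@natives) >= 5))
  expect_true(all(lengths(rs@aliens) >= 1))
  expect_true(all(speciesNames(worldRegistry(w)) %in%
                    worldTree(w)$tip.label))

  d1 <- file.path(tempdir(), "wA"); d2 <- file.path(tempdir(), "wB")
  writeWorld(w, d1)
  writeWorld(generateWorld(p), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)

  back <- readWorld(d1)
  expect_identical(sort(back$tree$tip.label), sort(worldTree(w)$tip.label))
  expect_setequal(nativesOf(back$regions, regionIds(rs)[1]),
                  nativesOf(rs, regionIds(rs)[1]))
  unlink(c(d1, d2), recursive = TRUE)
})
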