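test_that("weighted linear fits recover exact and weighted structure", {
  x <- 1:10
  f <- suppressWarnings(fitWeightedLinear(2 * x + 1, list(x = x)))
  co <- coefTable(f)
  expect_equal(co$estimate[co$term == "x"], 2, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "(Intercept)"], 1, tolerance = 1e-10)
  expect_equal(f@r2adj, 1, tolerance = 1e-10)

  # duplicating an observation equals giving it weight 2
  set.seed(1)
  y <- 2 * x + rnorm(10)
  dup <- fitWeightedLinear(c(y, y[3]), list(x = c(x, x[3])))
  wt <- fitWeightedLinear(y, list(x = x),
                          weights = c(1, 1, 2, rep(1, 7)))
  expect_equal(coefTable(dup)$estimate, coefTable(wt)$estimate,
               tolerance = 1e-10)

  # weight rescaling leaves the fit unchanged
  w5 <- fitWeightedLinear(y, list(x = x), weights = rep(5, 10))
  un <- fitWeightedLinear(y, list(x = x))
  expect_equal(coefTable(w5)$estimate, coefTable(un)$estimate,
               tolerance = 1e-12)
  expect_equal(coefTable(w5)$se, coefTable(un)$se, tolerance = 1e-10)

  expect_error(fitWeightedLinear(y, list(x = x, x2 = 2 * x)),
               "rank-deficient")
})

test_that("interaction estimates ignore predictor centering", {
  set.seed(2)
  n <- 120
  lat <- runif(n, 0, 60); hm <- runif(n)
  y <- 1 - 0.05 * lat + 0.3 * hm - 0.02 * lat * hm + rnorm(n, 0, 0.2)
  f1 <- fitInteractionModel(y, lat, hm)
  f2 <- fitInteractionModel(y, lat - mean(lat), hm - mean(hm))
  i1 <- coefTable(f1)$estimate[coefTable(f1)$term == "latitude:hm"]
  i2 <- coefTable(f2)$estimate[coefTable(f2)$term == "latitude:hm"]
  expect_equal(i1, i2, tolerance = 1e-10)
  expect_lt(abs(i1 - (-0.02)),
            2 * coefTable(f1)$se[coefTable(f1)$term == "latitude:hm"])
})

test_that("partial predictions satisfy the interaction algebra", {
  set.seed(3)
  n <- 100
  lat <- runif(n, 0, 60); hm <- runif(n)
  y <- 2 - 0.04 * lat + 0.5 * hm - 0.03 * lat * hm + rnorm(n, 0, 0.1)
  f <- fitInteractionModel(y, lat, hm)
  pp <- partialPredictions(f, "latitude",
                           fixQuantiles = list(hm = c(0.1, 0.9)), grid = 11)
  q <- unname(stats::quantile(hm, c(0.1, 0.9)))
  co <- coefTable(f)
  b_int <- co$estimate[co$term == "latitude:hm"]
  lo <- pp[pp$hm == q[1], ]; hi <- pp[pp$hm == q[2], ]
  slope <- function(d) stats::coef(stats::lm(predicted ~ latitude, d))[2]
  expect_equal(unname(slope(hi) - slope(lo)), (q[2] - q[1]) * b_int,
               tolerance = 1e-8)

  # a predictor with zero effect yields identical curves at all quantiles
  y0 <- 3 + 2 * lat
  f0 <- suppressWarnings(fitInteractionModel(y0, lat, hm))
  pp0 <- partialPredictions(f0, "latitude",
                            fixQuantiles = list(hm = c(0.1, 0.5, 0.9)),
                            grid = 7)
  spread <- tapply(pp0$predicted, pp0$latitude, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-8)
  expect_error(partialPredictions(f, "nope"), "unknown predictor")
})

test_that("the climate mixed model recovers effects and degenerates safely", {
  set.seed(4)
  n <- 160
  pcT <- rnorm(n); pcP <- rnorm(n); hm <- runif(n)
  cont <- sample(paste0("C", 1:6), n, replace = TRUE)
  # zero between-continent variance in truth
  y <- 0.8 * pcT + 0.4 * pcP - 0.5 * hm + 0.3 * pcT * hm + rnorm(n, 0, 0.4)
  f <- fitLMMClimate(y, pcT, pcP, hm, cont)
  expect_true(f@converged)
  vcont <- f@ranef$variance[f@ranef$group == "continent"]
  expect_lt(vcont, 0.05)
  co <- coefTable(f)
  for (tm in c("pc_temp", "pc_prec")) {
    i <- which(co$term == tm)
    truth <- c(pc_temp = 0.8, pc_prec = 0.4)[[tm]]
    expect_lt(abs(co$estimate[i] - truth), 3 * co$se[i])
  }
  expect_equal(nrow(f@stdCoef), nrow(co))

  # single grouping level: documented fall-back to the fixed-effects fit
  expect_warning(f1 <- fitLMMClimate(y, pcT, pcP, hm, rep("C1", n)),
                 "single grouping")
  ref <- makeRef <- fitWeightedLinear(y, list(pc_temp = pcT, hm = hm,
                                              pc_prec = pcP))
  expect_s4_class(f1, "ModelFit")
  expect_true(all(c("pc_temp", "pc_prec", "hm") %in% coefTable(f1)$term))
})

test_that("the cloglog naturalization model matches its generating process", {
  set.seed(5)
  nSp <- 60; nRg <- 25
  tab <- expand.grid(species = paste0("s", 1:nSp),
                     region_id = paste0("r", 1:nRg))
  tab$mpd_to_natives <- rnorm(nrow(tab), 10, 2)
  tab$abs_latitude <- rep(runif(nRg, 0, 60), each = nSp)
  mz <- scale(tab$mpd_to_natives); lz <- scale(tab$abs_latitude)
  eta <- -1.8 - 0.5 * mz + 0.3 * lz - 0.4 * mz * lz
  tab$naturalized <- rbinom(nrow(tab), 1, 1 - exp(-exp(eta)))

  g <- fitGLMMNaturalization(tab, "intercepts_only", nAGQ = 0)
  co <- coefTable(g)
  glm0 <- fitGLMMNaturalization(tab, "none")
  co0 <- coefTable(glm0)
  # no random variance in truth: GLMM and plain GLM agree within 2 SE
  for (tm in c("mpd", "lat", "mpd:lat")) {
    i <- which(co$term == tm)
    expect_lt(abs(co$estimate[i] - co0$estimate[co0$term == tm]),
              2 * co$se[i])
  }
  expect_lt(co0$estimate[co0$term == "mpd:lat"] + 0.4,
            3 * co0$se[co0$term == "mpd:lat"])

  tab$naturalized <- 0
  expect_error(fitGLMMNaturalization(tab, "none"), "single class")
})

test_that("completeness sensitivity refits collapse to known equalities", {
  set.seed(6)
  n <- 50
  x <- runif(n); y <- 1 + 2 * x + rnorm(n, 0, 0.3)
  full <- completenessWeightedRefit(y, list(x = x), rep(1, n),
                                    minCompleteness = 0.5)
  base <- fitWeightedLinear(y, list(x = x))
  expect_equal(coefTable(full$subset)$estimate, coefTable(base)$estimate,
               tolerance = 1e-10)
  expect_equal(coefTable(full$weighted)$estimate, coefTable(base)$estimate,
               tolerance = 1e-10)

  comp <- runif(n)
  part <- completenessWeightedRefit(y, list(x = x), comp,
                                    minCompleteness = 0.5)
  ind <- fitWeightedLinear(y, list(x = x), weights = as.numeric(comp > 0.5))
  expect_equal(coefTable(part$subset)$estimate, coefTable(ind)$estimate,
               tolerance = 1e-10)
  expect_error(completenessWeightedRefit(y, list(x = x), rep(0.1, n),
                                         minCompleteness = 0.5),
               "no regions")
})
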