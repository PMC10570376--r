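#' Area under the ROC curve by rank statistic
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half (Mann-Whitney formulation).
#' Invariant under any strictly monotone transform of the scores.
#'
#' @param scoresPos,scoresNeg Numeric score vectors (both non-empty).
#' @return AUC in [0, 1].
#' @examples
#' evaluateAUC(c(0.9, 0.8), c(0.2, 0.1))  # 1
#' @export
evaluateAUC <- function(scoresPos, scoresNeg) {
  assertThat(length(scoresPos) > 0 && length(scoresNeg) > 0,
             "both score vectors must be non-empty")
  np <- length(scoresPos); nn <- length(scoresNeg)
  r <- rank(c(scoresPos, scoresNeg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Among candidate thresholds (the unique observed scores), returns the one
#' maximizing sensitivity + specificity under the rule "score >= threshold
#' predicts presence". Ties are broken toward the largest threshold.
#'
#' @param scores Numeric suitability scores.
#' @param labels Logical (or 0/1): TRUE for presence, FALSE for background.
#' @return The selected threshold.
#' @examples
#' maxSSSThreshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 0.8
#' @export
maxSSSThreshold <- function(scores, labels) {
  labels <- as.logical(labels)
  assertThat(any(labels) && any(!labels),
             "both presence and background scores are required")
  cand <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels); nNeg <- sum(!labels)
  # counts at each candidate: positives/negatives with score >= threshold
  posAbove <- cumsum(vapply(cand, function(th) sum(scores[labels] == th),
                            numeric(1)))
  negAbove <- cumsum(vapply(cand, function(th) sum(scores[!labels] == th),
                            numeric(1)))
  sss <- posAbove / nPos + (nNeg - negAbove) / nNeg
  best <- max(sss)
  # decreasing candidate order: the first maximum is the largest threshold
  cand[which(sss >= best - 1e-12)[1]]
}

# Gaussian envelope suitability: exp(-0.5 * squared Mahalanobis distance)
envelopeScore <- function(X, mu, sigma) {
  d2 <- stats::mahalanobis(as.matrix(X), mu, sigma)
  exp(-0.5 * d2)
}

#' Fit a climatic-envelope suitability model for one species
#'
#' Fits a Gaussian envelope (mean and covariance over the six distribution
#' bioclim variables, see \code{\link{sdmVariables}}) to the species'
#' presence cells: suitability of a cell is
#' \code{exp(-0.5 * Mahalanobis^2)}, 1 at the presence centroid and
#' decreasing along any ray away from it. Presences are split 80/20 into
#' training/testing; the model is retained when its test AUC against the
#' background exceeds 0.7. The presence threshold is the maximum training
#' sensitivity-plus-specificity score. A near-singular training covariance
#' is ridge-regularized (with a message).
#'
#' More than 15 presence cells are required; species below that are intended
#' to be skipped by the caller (the error carries class
#' \code{"natphylo_too_few_presences"}).
#'
#' @param presenceCells data.frame of climate rows for the presence cells.
#' @param backgroundCells data.frame of climate rows for background cells
#'   (at least as many as presences).
#' @param species Species name (metadata).
#' @param vars Climate variables (default \code{sdmVariables()}).
#' @param seed Seed for the train/test split.
#' @return An \linkS4class{EnvelopeModel}.
#' @export
fitEnvelopeModel <- function(presenceCells, backgroundCells,
                             species = "species", vars = sdmVariables(),
                             seed = 1L) {
  np <- nrow(presenceCells)
  if (np <= 15) {
    cond <- simpleError(sprintf(
      "species '%s' has only %d presence cells (need > 15)", species, np))
    class(cond) <- c("natphylo_too_few_presences", class(cond))
    stop(cond)
  }
  assertThat(nrow(backgroundCells) >= np,
             "need at least as many background as presence cells")
  assertThat(all(vars %in% names(presenceCells)) &&
               all(vars %in% names(backgroundCells)),
             "presence/background cells missing the model variables")
  P <- as.matrix(presenceCells[, vars, drop = FALSE])
  B <- as.matrix(backgroundCells[, vars, drop = FALSE])
  idxTrain <- withLocalSeed(seed, sample.int(np, size = ceiling(0.8 * np)))
  train <- P[idxTrain, , drop = FALSE]
  test <- P[-idxTrain, , drop = FALSE]
  mu <- colMeans(train)
  sigma <- stats::cov(train)
  ridge <- 0
  if (rcond(sigma) < 1e-10) {
    ridge <- 1e-6 * mean(diag(sigma))
    if (ridge <= 0) ridge <- 1e-8
    sigma <- sigma + diag(ridge, ncol(sigma))
    message(sprintf("envelope for '%s': singular covariance, ridge %.3g added",
                    species, ridge))
  }
  aucTest <- evaluateAUC(envelopeScore(test, mu, sigma),
                         envelopeScore(B, mu, sigma))
  trainScores <- envelopeScore(train, mu, sigma)
  bgScores <- envelopeScore(B, mu, sigma)
  thr <- maxSSSThreshold(c(trainScores, bgScores),
                         c(rep(TRUE, length(trainScores)),
                           rep(FALSE, length(bgScores))))
  new("EnvelopeModel", species = species, vars = vars, mu = mu,
      sigma = sigma, ridge = ridge, auc = aucTest, threshold = thr,
      retained = aucTest > 0.7)
}

#' Suitability scores of cells under an envelope model
#'
#' @param model An \linkS4class{EnvelopeModel}.
#' @param cells data.frame with the model's climate variables.
#' @return Numeric vector of suitability scores in (0, 1].
#' @export
envelopeScores <- function(model, cells) {
  envelopeScore(cells[, model@vars, drop = FALSE], model@mu, model@sigma)
}

#' Regions climatically suitable for a species
#'
#' A region qualifies when at least one of its grid cells scores at or above
#' the model threshold. Only retained models (test AUC > 0.7) may be used.
#'
#' @param model A retained \linkS4class{EnvelopeModel}.
#' @param grid Climate grid (region_id, cell_id, variables).
#' @return Character vector of suitable region ids.
#' @export
suitableRegions <- function(model, grid) {
  assertThat(model@retained,
             "model for '%s' was not retained (AUC %.3f <= 0.7)",
             model@species, model@auc)
  sc <- envelopeScores(model, grid)
  sort(unique(as.character(grid$region_id[sc >= model@threshold])))
}

#' Build the per-species climatic suitability table
#'
#' Runs the envelope stage for every species with occurrence cells: fits the
#' model on its presence cells against all other cells as background, keeps
#' species with more than \code{minOccurrences} presences and test AUC above
#' 0.7, and records the suitable-region set of each retained species.
#' Alternatively, precomputed external suitability scores can be supplied to
#' \code{\link{buildPool}} directly, bypassing this stage.
#'
#' @param occurrences data.frame (species, cell_id).
#' @param grid Climate grid (region_id, cell_id, variables).
#' @param vars Model variables.
#' @param minOccurrences Minimum presence count (strict; default 15).
#' @param seed Master seed (per-species substreams are derived from it).
#' @return Named list, species -> suitable region ids, with attributes
#'   \code{"skipped"} (data.frame species, reason) and \code{"models"} (the
#'   fitted \linkS4class{EnvelopeModel}s).
#' @export
buildSuitabilityTable <- function(occurrences, grid, vars = sdmVariables(),
                                  minOccurrences = 15, seed = 1L) {
  assertThat(all(c("species", "cell_id") %in% names(occurrences)),
             "occurrences need columns species, cell_id")
  out <- list(); models <- list(); skipped <- list()
  for (sp in unique(occurrences$species)) {
    cells <- unique(occurrences$cell_id[occurrences$species == sp])
    pres <- grid[grid$cell_id %in% cells, , drop = FALSE]
    bg <- grid   # background = the whole landscape, presences included
    if (nrow(pres) <= minOccurrences) {
      skipped[[sp]] <- sprintf("only %d occurrences (need > %d)",
                               nrow(pres), minOccurrences)
      next
    }
    if (nrow(bg) < nrow(pres)) {
      skipped[[sp]] <- "fewer background than presence cells"
      next
    }
    fit <- tryCatch(
      fitEnvelopeModel(pres, bg, species = sp, vars = vars,
                       seed = substreamSeed(seed, sp)),
      natphylo_too_few_presences = function(e) NULL)
    if (is.null(fit)) {
      skipped[[sp]] <- "too few presences"
      next
    }
    models[[sp]] <- fit
    if (!fit@retained) {
      skipped[[sp]] <- sprintf("test AUC %.3f <= 0.7", fit@auc)
      next
    }
    out[[sp]] <- suitableRegions(fit, grid)
  }
  attr(out, "skipped") <- if (length(skipped))
    data.frame(species = names(skipped), reason = unlist(skipped),
               row.names = NULL)
  else data.frame(species = character(0), reason = character(0))
  attr(out, "models") <- models
  out
}
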