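coefFromSummary <- function(tab, statName) {
  data.frame(term = rownames(tab), estimate = tab[, 1], se = tab[, 2],
             statistic = tab[, 3],
             p_value = 2 * stats::pnorm(-abs(tab[, 3])),
             row.names = NULL)
}

emptyDF <- function() data.frame()

# Refit a model on unit-variance-scaled numeric columns to obtain
# standardized coefficients (both predictors and response are scaled).
standardizedCoefs <- function(fitFun, data, numericCols) {
  sdata <- data
  for (v in numericCols) {
    if (stats::sd(sdata[[v]]) > 0)
      sdata[[v]] <- as.numeric(scale(sdata[[v]]))
  }
  fit <- fitFun(sdata)
  est <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  data.frame(term = names(est), std_estimate = as.numeric(est),
             row.names = NULL)
}

makeLmFit <- function(formula, data, weights = NULL, stdCols = NULL) {
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  assertThat(all(data$.w >= 0) && any(data$.w > 0),
             "weights must be non-negative with at least one positive")
  fit <- stats::lm(formula, data = data, weights = .w)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  tab <- sm$coefficients
  co <- data.frame(term = rownames(tab), estimate = tab[, 1], se = tab[, 2],
                   statistic = tab[, 3], p_value = tab[, 4],
                   row.names = NULL)
  std <- if (is.null(stdCols)) emptyDF() else
    standardizedCoefs(function(d) stats::lm(formula, data = d, weights = .w),
                      data, stdCols)
  new("ModelFit", formula = paste(deparse(formula), collapse = ""),
      coef = co, ranef = emptyDF(), stdCoef = std,
      r2adj = sm$adj.r.squared, converged = TRUE, fit = fit, data = data)
}

#' Weighted linear regression with adjusted R-squared
#'
#' Ordinary (or inverse-variance weighted) least squares of a response on one
#' or more predictors, with two-sided t-tests per coefficient. Used for the
#' region-level (Delta)MPD-versus-latitude regressions, where the weights are
#' the inverse null-model variances.
#'
#' @param response Numeric response vector.
#' @param predictors Named list or data.frame of predictor vectors.
#' @param weights Optional positive weights.
#' @return A \linkS4class{ModelFit}.
#' @examples
#' f <- fitWeightedLinear(2 * (1:10) + 1, list(x = 1:10))
#' coefTable(f)
#' @export
fitWeightedLinear <- function(response, predictors, weights = NULL) {
  data <- as.data.frame(predictors)
  vars <- names(data)
  data$.y <- response
  fml <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
  makeLmFit(fml, data, weights, stdCols = c(".y", vars))
}

#' Latitude-by-human-modification interaction model
#'
#' Linear model \code{response ~ latitude + hm + latitude:hm}, the region
#' level test of whether human landscape modification steepens the
#' latitudinal gradient of (Delta)MPD.
#'
#' @param response Numeric response.
#' @param latitude Numeric latitude (absolute or signed, as configured).
#' @param hm Human-modification index in [0, 1].
#' @param weights Optional positive weights.
#' @return A \linkS4class{ModelFit}.
#' @export
fitInteractionModel <- function(response, latitude, hm, weights = NULL) {
  data <- data.frame(.y = response, latitude = latitude, hm = hm)
  makeLmFit(.y ~ latitude * hm, data, weights,
            stdCols = c(".y", "latitude", "hm"))
}

#' Climate mixed model with continent random intercept
#'
#' Fits \code{response ~ pc_temp * hm + pc_prec * hm + (1 | continent)} by
#' REML, optionally inverse-variance weighted; p-values are two-sided Wald
#' tests. Standardized effect sizes (coefficients after unit-variance scaling
#' of response and numeric predictors) are stored in the fit. With a single
#' continent, or when the mixed fit fails to converge, the model falls back
#' to the weighted fixed-effects fit with a warning and the convergence flag
#' records the fallback.
#'
#' @param response Numeric response ((Delta)MPD per region).
#' @param pcTemp,pcPrec Region climate principal-component scores.
#' @param hm Human-modification index.
#' @param continent Grouping labels for the random intercept.
#' @param weights Optional positive weights.
#' @return A \linkS4class{ModelFit}; slot \code{ranef} holds the variance
#'   components.
#' @export
fitLMMClimate <- function(response, pcTemp, pcPrec, hm, continent,
                          weights = NULL) {
  data <- data.frame(.y = response, pc_temp = pcTemp, pc_prec = pcPrec,
                     hm = hm, continent = as.factor(continent))
  numCols <- c(".y", "pc_temp", "pc_prec", "hm")
  if (nlevels(data$continent) < 2) {
    warning("single grouping level: falling back to the fixed-effects model")
    fit <- makeLmFit(.y ~ pc_temp * hm + pc_prec * hm, data, weights,
                     stdCols = numCols)
    return(fit)
  }
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  assertThat(all(data$.w > 0), "mixed-model weights must be positive")
  fml <- .y ~ pc_temp * hm + pc_prec * hm + (1 | continent)
  fit <- tryCatch(
    lme4::lmer(fml, data = data, weights = .w, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    warning("mixed model did not converge: falling back to fixed effects")
    out <- makeLmFit(.y ~ pc_temp * hm + pc_prec * hm, data,
                     if (is.null(weights)) NULL else weights,
                     stdCols = numCols)
    out@converged <- FALSE
    return(out)
  }
  tab <- summary(fit)$coefficients
  co <- coefFromSummary(tab)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef <- data.frame(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)
  std <- standardizedCoefs(
    function(d) suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = d, weights = .w, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
    data, numCols)
  new("ModelFit",
      formula = "response ~ pc_temp * hm + pc_prec * hm + (1 | continent)",
      coef = co, ranef = ranef, stdCoef = std, r2adj = NA_real_,
      converged = TRUE, fit = fit, data = data)
}

#' Species-level naturalization model (cloglog binomial GLMM)
#'
#' Models the naturalization indicator of every (species, region) pair with
#' the species non-native to the region as a binomial GLMM with the
#' complementary log-log link, suited to the rarity of naturalization
#' events:
#' \code{naturalized ~ mpd * abs_latitude + (mpd * abs_latitude | species)
#' + (1 | region)} for the \code{"full"} structure, or random intercepts for
#' species and region only (\code{"intercepts_only"}), or a plain cloglog
#' GLM (\code{"none"}). MPD and absolute latitude are standardized
#' internally (scalings are kept with the model data). When the full
#' structure fails to converge the model is automatically refitted with
#' intercepts only, with a warning.
#'
#' @param table data.frame with columns species, region_id, mpd_to_natives,
#'   abs_latitude, naturalized (0/1).
#' @param randomStructure \code{"full"}, \code{"intercepts_only"} or
#'   \code{"none"}.
#' @param nAGQ Integr; passed to \code{lme4::glmer} (0 = fast penalized
#'   least-squares approximation, 1 = Laplace).
#' @return A \linkS4class{ModelFit}; Wald z-tests in the coefficient table.
#' @export
fitGLMMNaturalization <- function(table,
                                  randomStructure = c("full",
                                                      "intercepts_only",
                                                      "none"),
                                  nAGQ = 1) {
  randomStructure <- match.arg(randomStructure)
  need <- c("species", "region_id", "mpd_to_natives", "abs_latitude",
            "naturalized")
  assertThat(all(need %in% names(table)),
             "table needs columns %s", paste(need, collapse = ", "))
  y <- table$naturalized
  assertThat(any(y == 1) && any(y == 0),
             "outcome has a single class; both classes are required")
  data <- data.frame(
    naturalized = y,
    mpd = as.numeric(scale(table$mpd_to_natives)),
    lat = as.numeric(scale(table$abs_latitude)),
    species = as.factor(table$species),
    region_id = as.factor(table$region_id))
  attr(data, "scaling") <- list(
    mpd = c(center = mean(table$mpd_to_natives),
            scale = stats::sd(table$mpd_to_natives)),
    lat = c(center = mean(table$abs_latitude),
            scale = stats::sd(table$abs_latitude)))
  fam <- stats::binomial(link = "cloglog")

  fitOnce <- function(structure) {
    fml <- switch(structure,
      full = naturalized ~ mpd * lat + (1 + mpd * lat | species) +
        (1 | region_id),
      intercepts_only = naturalized ~ mpd * lat + (1 | species) +
        (1 | region_id),
      none = naturalized ~ mpd * lat)
    if (structure == "none")
      return(list(fit = stats::glm(fml, family = fam, data = data),
                  structure = structure))
    fit <- tryCatch(
      suppressMessages(lme4::glmer(
        fml, family = fam, data = data, nAGQ = nAGQ,
        control = lme4::glmerControl(check.conv.singular = "ignore",
                                     calc.derivs = FALSE))),
      error = function(e) NULL, warning = function(w) NULL)
    list(fit = fit, structure = structure)
  }

  res <- fitOnce(randomStructure)
  converged <- TRUE
  if (is.null(res$fit) && randomStructure == "full") {
    warning("full random-slope structure failed; refitting intercepts only")
    converged <- FALSE
    res <- fitOnce("intercepts_only")
  }
  if (is.null(res$fit)) {
    warning("mixed structure failed; falling back to plain cloglog GLM")
    converged <- FALSE
    res <- fitOnce("none")
  }
  fit <- res$fit
  if (inherits(fit, "merMod")) {
    tab <- summary(fit)$coefficients
    co <- coefFromSummary(tab)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef <- data.frame(group = vc$grp,
                        term = paste(vc$var1, vc$var2, sep = ":"),
                        variance = vc$vcov, sd = vc$sdcor)
  } else {
    tab <- summary(fit)$coefficients
    co <- coefFromSummary(tab)
    ranef <- emptyDF()
  }
  new("ModelFit",
      formula = sprintf("cloglog naturalized ~ mpd * abs_latitude [%s]",
                        res$structure),
      coef = co, ranef = ranef, stdCoef = emptyDF(), r2adj = NA_real_,
      converged = converged, fit = fit, data = data)
}

#' Partial predictions over a focal predictor
#'
#' Predicts the response over a grid of the focal predictor while other
#' predictors are fixed at stated sample quantiles (or at explicit values),
#' reproducing the "fix HM at its 10/50/90\% quantiles" and "fix latitude at
#' several values" presentation of interaction fits. Mixed-model predictions
#' are at the population level (random effects set to zero); binomial fits
#' are predicted on the response (probability) scale.
#'
#' @param fit A \linkS4class{ModelFit}.
#' @param focal Name of the focal predictor in the model data.
#' @param fixQuantiles Named list: predictor -> quantile levels (e.g.
#'   \code{list(hm = c(0.1, 0.5, 0.9))}).
#' @param fixValues Named list: predictor -> explicit values (overrides
#'   quantiles for that predictor).
#' @param grid Number of focal grid points.
#' @return data.frame: focal name/value, one column per fixed predictor, and
#'   \code{predicted}.
#' @export
partialPredictions <- function(fit, focal, fixQuantiles = list(),
                               fixValues = list(), grid = 100) {
  data <- fit@data
  assertThat(focal %in% names(data), "unknown predictor '%s'", focal)
  model <- fit@fit
  rhsVars <- setdiff(all.vars(stats::formula(model)),
                     c(".y", "naturalized", ".w"))
  others <- setdiff(rhsVars, focal)
  fixed <- list()
  for (v in others) {
    if (!is.null(fixValues[[v]])) fixed[[v]] <- fixValues[[v]]
    else if (!is.null(fixQuantiles[[v]]))
      fixed[[v]] <- unname(stats::quantile(data[[v]], fixQuantiles[[v]]))
    else if (is.numeric(data[[v]])) fixed[[v]] <- mean(data[[v]])
    else fixed[[v]] <- levels(as.factor(data[[v]]))[1]
  }
  badFix <- setdiff(union(names(fixQuantiles), names(fixValues)), rhsVars)
  assertThat(length(badFix) == 0, "unknown predictor '%s'", badFix[1])
  focalGrid <- seq(min(data[[focal]]), max(data[[focal]]),
                   length.out = grid)
  newdata <- expand.grid(c(stats::setNames(list(focalGrid), focal), fixed),
                         KEEP.OUT.ATTRS = FALSE)
  newdata$.w <- 1
  pred <- if (inherits(model, "merMod"))
    stats::predict(model, newdata = newdata, re.form = NA,
                   type = "response")
  else stats::predict(model, newdata = newdata, type = "response")
  out <- newdata[, c(focal, names(fixed)), drop = FALSE]
  out$predicted <- as.numeric(pred)
  out
}

#' Inventory-completeness sensitivity refits
#'
#' Two standard checks that incomplete regional checklists do not drive a
#' fitted relationship: (a) refit on the subset of regions whose completeness
#' exceeds \code{minCompleteness}; (b) refit on all regions using
#' completeness as the weighting variable.
#'
#' @param response Numeric response.
#' @param predictors Named list or data.frame of predictors.
#' @param completeness Completeness fractions in [0, 1].
#' @param minCompleteness Subset threshold (default 0.5).
#' @return List with elements \code{subset} and \code{weighted}, both
#'   \linkS4class{ModelFit}s.
#' @export
completenessWeightedRefit <- function(response, predictors, completeness,
                                      minCompleteness = 0.5) {
  assertThat(all(completeness >= 0 & completeness <= 1),
             "completeness must lie in [0, 1]")
  data <- as.data.frame(predictors)
  keep <- completeness > minCompleteness
  assertThat(any(keep), "no regions exceed completeness %.2f",
             minCompleteness)
  subsetFit <- fitWeightedLinear(response[keep],
                                 data[keep, , drop = FALSE])
  weightedFit <- fitWeightedLinear(response, data, weights = completeness)
  list(subset = subsetFit, weighted = weightedFit)
}
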