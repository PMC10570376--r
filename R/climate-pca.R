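#' The 19 bioclim variable names
#'
#' @return Character vector \code{bio1..bio19}.
#' @export
bioclimVariables <- function() paste0("bio", 1:19)

#' The six bioclim variables used by the suitability models
#'
#' Mean diurnal range (bio2), temperature seasonality (bio4), maximum
#' temperature of the warmest month (bio5), precipitation seasonality
#' (bio15), precipitation of the wettest quarter (bio16) and of the driest
#' quarter (bio17).
#'
#' @return Character vector of length six.
#' @export
sdmVariables <- function() c("bio2", "bio4", "bio5", "bio15", "bio16", "bio17")

#' Fit a normalizing transform to one climate variable
#'
#' Supported transforms: \code{identity}; \code{log1p_shift} and
#' \code{sqrt_shift}, which shift the variable to be non-negative before
#' log1p/sqrt; and \code{power}, a Yeo-Johnson power-normalizing transform
#' whose exponent is fitted to the data (via \code{car::powerTransform}).
#' The fitted parameters are stored in the returned spec so the same
#' transform can be replayed on new data.
#'
#' @param values Numeric vector.
#' @param name Transform name.
#' @return A spec list: \code{name} plus fitted parameters (\code{shift} or
#'   \code{lambda}).
#' @export
fitTransform <- function(values,
                         name = c("power", "identity", "log1p_shift",
                                  "sqrt_shift")) {
  name <- match.arg(name)
  spec <- switch(name,
    identity = list(name = "identity"),
    log1p_shift = list(name = "log1p_shift", shift = max(0, -min(values))),
    sqrt_shift = list(name = "sqrt_shift", shift = max(0, -min(values))),
    power = {
      lambda <- tryCatch(
        as.numeric(car::powerTransform(values ~ 1,
                                       family = "yjPower")$lambda),
        error = function(e) 1)
      if (!is.finite(lambda)) lambda <- 1
      list(name = "power", lambda = lambda)
    })
  spec
}

#' Apply a (fitted) transform to a vector
#'
#' @param values Numeric vector.
#' @param spec A spec from \code{\link{fitTransform}}, or a transform name
#'   (fitted on the fly).
#' @param variable Variable name used in error messages.
#' @return Transformed numeric vector (monotone in the input).
#' @examples
#' transformVariable(c(0, exp(1) - 1), list(name = "log1p_shift", shift = 0))
#' @export
transformVariable <- function(values, spec, variable = "variable") {
  if (is.character(spec)) spec <- fitTransform(values, spec)
  out <- switch(spec$name,
    identity = values,
    log1p_shift = log1p(values + spec$shift),
    sqrt_shift = sqrt(values + spec$shift),
    power = car::yjPower(values, spec$lambda),
    stop("unknown transform '", spec$name, "'"))
  assertThat(all(is.finite(out)),
             "transform '%s' produced non-finite values for %s",
             spec$name, variable)
  out
}

#' Fit the climate PCA (PC_Temp, PC_Prec)
#'
#' Applies the per-variable normalizing transforms, centers and scales each
#' variable to unit variance, and runs a PCA. By default the PCA is fitted on
#' grid cells (\code{mode = "cell"}); \code{mode = "region"} fits on region
#' means as a sensitivity option. Axis signs are fixed so that mean annual
#' temperature (bio1) loads positively on axis 1 (high PC_Temp = warm) and
#' annual precipitation (bio12) positively on axis 2 (high PC_Prec = wet).
#'
#' @param grid data.frame with columns region_id, cell_id and the bioclim
#'   variables.
#' @param transforms Named list of transform specs or names per variable;
#'   unnamed scalar \code{"power"} (the default) applies the fitted
#'   Yeo-Johnson transform to every variable.
#' @param vars Climate variables to use (default all 19).
#' @param mode \code{"cell"} or \code{"region"}.
#' @return A \linkS4class{ClimatePCA}.
#' @export
fitClimatePCA <- function(grid, transforms = "power",
                          vars = bioclimVariables(),
                          mode = c("cell", "region")) {
  mode <- match.arg(mode)
  assertThat(all(vars %in% names(grid)),
             "grid is missing climate variables: %s",
             paste(setdiff(vars, names(grid)), collapse = ", "))
  X <- grid[, vars, drop = FALSE]
  if (mode == "region") {
    X <- stats::aggregate(X, list(region_id = grid$region_id), mean)
    X <- X[, vars, drop = FALSE]
  }
  assertThat(nrow(X) >= 20, "need at least 20 rows to fit the PCA (got %d)",
             nrow(X))
  if (is.character(transforms) && length(transforms) == 1)
    transforms <- stats::setNames(rep(list(transforms), length(vars)), vars)
  specs <- list()
  for (v in vars) {
    sp <- transforms[[v]]
    if (is.null(sp)) sp <- "identity"
    if (is.character(sp)) sp <- fitTransform(X[[v]], sp)
    X[[v]] <- transformVariable(X[[v]], sp, v)
    specs[[v]] <- sp
  }
  sds <- vapply(X, stats::sd, numeric(1))
  assertThat(all(sds > 0), "zero-variance variable(s) after transform: %s",
             paste(vars[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  # arbitrary PCA signs: orient axes by the temperature/precipitation anchors
  if ("bio1" %in% vars && rot["bio1", 1] < 0) rot[, 1] <- -rot[, 1]
  if ("bio12" %in% vars && ncol(rot) >= 2 && rot["bio12", 2] < 0)
    rot[, 2] <- -rot[, 2]
  new("ClimatePCA", transforms = specs, center = pc$center, scale = pc$scale,
      rotation = rot, sdev = pc$sdev,
      varExplained = pc$sdev^2 / sum(pc$sdev^2), mode = mode)
}

#' Cell-level PCA scores
#'
#' Replays the stored transforms and standardization on (possibly new) cells
#' and projects them on the fitted axes.
#'
#' @param pca A \linkS4class{ClimatePCA}.
#' @param cells data.frame containing the PCA's climate variables.
#' @param comps Components to return (default 1:2).
#' @return Matrix of scores (cells x components).
#' @export
pcaScores <- function(pca, cells, comps = 1:2) {
  vars <- rownames(pca@rotation)
  assertThat(all(vars %in% names(cells)),
             "cells are missing climate variables: %s",
             paste(setdiff(vars, names(cells)), collapse = ", "))
  X <- cells[, vars, drop = FALSE]
  for (v in vars) X[[v]] <- transformVariable(X[[v]], pca@transforms[[v]], v)
  Xs <- scale(as.matrix(X), center = pca@center, scale = pca@scale)
  Xs %*% pca@rotation[, comps, drop = FALSE]
}

#' Region-level principal component scores
#'
#' PC_Temp and PC_Prec of each region: the unweighted mean of its cell-level
#' scores on axes 1 and 2. Averaging scores does not generally commute with
#' averaging raw variables when transforms are non-linear; cell-level
#' averaging (matching the cell-level fit) is the reference behaviour.
#'
#' @param pca A \linkS4class{ClimatePCA}.
#' @param grid Climate grid with region_id, cell_id and the variables.
#' @param region Optional single region id; when given, a named length-2
#'   vector \code{c(pc_temp, pc_prec)} is returned.
#' @return data.frame (region_id, pc_temp, pc_prec), or a length-2 vector.
#' @export
regionPCScores <- function(pca, grid, region = NULL) {
  if (!is.null(region)) {
    assertThat(region %in% grid$region_id, "unknown region '%s'", region)
    grid <- grid[grid$region_id == region, , drop = FALSE]
  }
  sc <- pcaScores(pca, grid, comps = 1:2)
  agg <- stats::aggregate(sc, list(region_id = grid$region_id), mean)
  out <- data.frame(region_id = as.character(agg$region_id),
                    pc_temp = agg[[2]], pc_prec = agg[[3]])
  if (!is.null(region))
    return(c(pc_temp = out$pc_temp[1], pc_prec = out$pc_prec[1]))
  out
}
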