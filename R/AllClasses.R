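#' @import methods
NULL

#' TaxonomyMap: species-to-genus-to-family lookup
#'
#' Parallel character vectors mapping each species to exactly one genus and
#' each genus to exactly one family. Used to decide where missing species are
#' grafted onto the phylogeny and how trees are collapsed to genus or family
#' resolution.
#'
#' @slot species character, unique species names.
#' @slot genus character, genus of each species.
#' @slot family character, family of each species.
#' @export
setClass("TaxonomyMap",
  representation(species = "character", genus = "character",
                 family = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@species)
    if (length(object@genus) != n || length(object@family) != n)
      msg <- c(msg, "species, genus and family must have equal length")
    if (anyDuplicated(object@species))
      msg <- c(msg, "duplicated species names")
    if (any(is.na(object@species)) || any(is.na(object@genus)) ||
        any(is.na(object@family)))
      msg <- c(msg, "NA entries are not allowed")
    gf <- unique(data.frame(g = object@genus, f = object@family))
    if (anyDuplicated(gf$g))
      msg <- c(msg, "a genus maps to more than one family")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TaxonomyMap
#'
#' @param species,genus,family Parallel character vectors, or a data.frame
#'   with columns \code{species}, \code{genus}, \code{family} passed as the
#'   first argument.
#' @return A \linkS4class{TaxonomyMap}.
#' @examples
#' taxonomyMap(c("Poa_annua", "Poa_trivialis"), c("Poa", "Poa"),
#'             c("Poaceae", "Poaceae"))
#' @export
taxonomyMap <- function(species, genus = NULL, family = NULL) {
  if (is.data.frame(species)) {
    df <- species
    assertThat(all(c("species", "genus", "family") %in% names(df)),
               "taxonomy data.frame needs columns species, genus, family")
    return(new("TaxonomyMap", species = as.character(df$species),
               genus = as.character(df$genus),
               family = as.character(df$family)))
  }
  new("TaxonomyMap", species = as.character(species),
      genus = as.character(genus), family = as.character(family))
}

#' SpeciesRegistry: taxonomy, economic use, and regional status sets
#'
#' Per-species taxonomy plus the sets of regions where each species is native
#' and where it is naturalized. Conflicting records are resolved before
#' construction (see \code{\link{resolveStatusConflicts}}); the validity
#' method guarantees that no species is simultaneously native and naturalized
#' in the same region.
#'
#' @slot taxonomy a \linkS4class{TaxonomyMap}.
#' @slot econUse named logical, economic-use flag per species.
#' @slot nativeRegions named list of character region-id vectors.
#' @slot naturalizedRegions named list of character region-id vectors.
#' @export
setClass("SpeciesRegistry",
  representation(taxonomy = "TaxonomyMap", econUse = "logical",
                 nativeRegions = "list", naturalizedRegions = "list"),
  validity = function(object) {
    msg <- NULL
    sp <- object@taxonomy@species
    for (slotnm in c("econUse", "nativeRegions", "naturalizedRegions")) {
      x <- slot(object, slotnm)
      if (!identical(names(x), sp))
        msg <- c(msg, sprintf("%s names must equal taxonomy species", slotnm))
    }
    if (is.null(msg)) {
      both <- mapply(function(a, b) length(intersect(a, b)) > 0,
                     object@nativeRegions, object@naturalizedRegions)
      if (any(both))
        msg <- c(msg, sprintf(
          "species simultaneously native and naturalized in a region: %s",
          paste(head(sp[both], 5), collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
  })

#' RegionSet: regional attributes and assemblages
#'
#' Holds the per-region attribute table (area, centroid latitude, continent,
#' human-modification index, inventory completeness) together with the native
#' and naturalized-alien assemblages of each region.
#'
#' @slot info data.frame with columns \code{region_id}, \code{area_km2},
#'   \code{latitude}, \code{continent}, \code{hm}, \code{completeness}.
#' @slot natives named list (by region id) of native species vectors.
#' @slot aliens named list (by region id) of naturalized alien species.
#' @export
setClass("RegionSet",
  representation(info = "data.frame", natives = "list", aliens = "list"),
  validity = function(object) {
    msg <- NULL
    need <- c("region_id", "area_km2", "latitude", "continent", "hm",
              "completeness")
    if (!all(need %in% names(object@info)))
      msg <- c(msg, paste("info must have columns",
                          paste(need, collapse = ", ")))
    else {
      ids <- as.character(object@info$region_id)
      if (anyDuplicated(ids)) msg <- c(msg, "duplicated region ids")
      if (!identical(names(object@natives), ids) ||
          !identical(names(object@aliens), ids))
        msg <- c(msg, "natives/aliens lists must be named by region_id")
      if (any(object@info$area_km2 <= 0)) msg <- c(msg, "area_km2 must be > 0")
      if (any(object@info$hm < 0 | object@info$hm > 1))
        msg <- c(msg, "hm must lie in [0, 1]")
      if (is.null(msg)) {
        ovl <- mapply(function(a, b) length(intersect(a, b)) > 0,
                      object@natives, object@aliens)
        if (any(ovl))
          msg <- c(msg, sprintf("natives and aliens overlap in region(s): %s",
                                paste(head(ids[ovl], 5), collapse = ", ")))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RegionSet
#'
#' @param info Region attribute data.frame (see \linkS4class{RegionSet}).
#' @param natives,aliens Named lists of species-name vectors, one entry per
#'   region id.
#' @return A \linkS4class{RegionSet}.
#' @export
regionSet <- function(info, natives, aliens) {
  ids <- as.character(info$region_id)
  info$region_id <- ids
  new("RegionSet", info = info, natives = natives[ids], aliens = aliens[ids])
}

#' ClimatePCA: fitted principal components of the bioclim space
#'
#' Stores per-variable normalizing transforms, centering/scaling constants and
#' loadings so cell-level scores can be reproduced on new data. Axis 1 is
#' sign-fixed so warm regions score high (PC_Temp); axis 2 so wet regions
#' score high (PC_Prec).
#'
#' @slot transforms named list of transform specs (see
#'   \code{\link{fitTransform}}).
#' @slot center,scale named numeric, standardization constants.
#' @slot rotation matrix of loadings (variables x components).
#' @slot sdev numeric, component standard deviations.
#' @slot varExplained numeric, fraction of variance per component.
#' @slot mode character, \code{"cell"} or \code{"region"} fitting mode.
#' @export
setClass("ClimatePCA",
  representation(transforms = "list", center = "numeric", scale = "numeric",
                 rotation = "matrix", sdev = "numeric",
                 varExplained = "numeric", mode = "character"),
  validity = function(object) {
    msg <- NULL
    ve <- object@varExplained
    if (any(diff(ve) > 1e-8)) msg <- c(msg, "varExplained must be non-increasing")
    if (sum(ve) > 1 + 1e-8) msg <- c(msg, "varExplained must sum to <= 1")
    cp <- crossprod(object@rotation)
    if (max(abs(cp - diag(ncol(cp)))) > 1e-6)
      msg <- c(msg, "loadings must be orthonormal")
    if (is.null(msg)) TRUE else msg
  })

#' EnvelopeModel: climatic-envelope suitability model for one species
#'
#' A Gaussian envelope over the six distribution-model bioclim variables:
#' suitability of a cell is \code{exp(-0.5 * Mahalanobis^2)} to the training
#' presence mean/covariance, in (0, 1]. A model is retained when its test AUC
#' against background exceeds 0.7; the presence/background threshold is the
#' maximum training sensitivity-plus-specificity score.
#'
#' @slot species character species name.
#' @slot vars character, the climate variables used.
#' @slot mu numeric, training presence mean.
#' @slot sigma matrix, training presence covariance (possibly ridged).
#' @slot ridge numeric, ridge added to the covariance diagonal (0 if none).
#' @slot auc numeric, test AUC.
#' @slot threshold numeric, max sensitivity+specificity suitability cutoff.
#' @slot retained logical, whether the model passed the AUC filter.
#' @export
setClass("EnvelopeModel",
  representation(species = "character", vars = "character", mu = "numeric",
                 sigma = "matrix", ridge = "numeric", auc = "numeric",
                 threshold = "numeric", retained = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!identical(object@retained, object@auc > 0.7))
      msg <- c(msg, "retained flag must equal (auc > 0.7)")
    if (object@threshold > 1 + 1e-12 || object@threshold < 0)
      msg <- c(msg, "threshold must lie in the score range (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' ModelFit: a fitted statistical model with its coefficient table
#'
#' Light container around the package's regression fits. Holds the coefficient
#' table (estimate, SE, statistic, p-value), random-effect variance components
#' when applicable, standardized coefficients where computed, the adjusted
#' R-squared for linear fits, a convergence flag, and the underlying fitted
#' object for prediction.
#'
#' @slot formula character description of the model.
#' @slot coef data.frame: term, estimate, se, statistic, p_value.
#' @slot ranef data.frame of random-effect variance components (may be empty).
#' @slot stdCoef data.frame of standardized coefficients (may be empty).
#' @slot r2adj numeric adjusted R-squared (NA for non-linear fits).
#' @slot converged logical.
#' @slot fit the underlying model object.
#' @slot data the model data (for partial predictions).
#' @export
setClass("ModelFit",
  representation(formula = "character", coef = "data.frame",
                 ranef = "data.frame", stdCoef = "data.frame",
                 r2adj = "numeric", converged = "logical", fit = "ANY",
                 data = "data.frame"),
  validity = function(object) {
    msg <- NULL
    need <- c("term", "estimate", "se", "statistic", "p_value")
    if (!all(need %in% names(object@coef)))
      msg <- c(msg, "coef table must have term/estimate/se/statistic/p_value")
    if (!is.na(object@r2adj) && object@r2adj > 1)
      msg <- c(msg, "adjusted R^2 cannot exceed 1")
    if (isTRUE(object@converged) &&
        !all(is.finite(object@coef$estimate)))
      msg <- c(msg, "converged fit must have finite estimates")
    if (is.null(msg)) TRUE else msg
  })

#' SyntheticWorld: a generated study system with known ground truth
#'
#' Bundles the simulated phylogeny, taxonomy, species registry, regions,
#' climate grid, the species-by-region naturalization table, and the
#' generative parameters (including realized random effects) used to create
#' them, so that parameter-recovery experiments can compare estimates against
#' truth.
#'
#' @slot tree an \code{ape} \code{phylo} object (ultrametric).
#' @slot taxonomy a \linkS4class{TaxonomyMap}.
#' @slot registry a \linkS4class{SpeciesRegistry}.
#' @slot regions a \linkS4class{RegionSet}.
#' @slot climate data.frame climate grid (region_id, cell_id, bio1..bio19).
#' @slot natTable data.frame: species, region_id, mpd_to_natives,
#'   abs_latitude, naturalized.
#' @slot truth list of generative parameters and realized random effects.
#' @slot params the \code{\link{worldParams}} list used.
#' @export
setClass("SyntheticWorld",
  representation(tree = "ANY", taxonomy = "TaxonomyMap",
                 registry = "SpeciesRegistry", regions = "RegionSet",
                 climate = "data.frame", natTable = "data.frame",
                 truth = "list", params = "list"),
  validity = function(object) {
    msg <- NULL
    if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
    else {
      sp <- object@taxonomy@species
      if (!all(sp %in% object@tree$tip.label))
        msg <- c(msg, "all registry species must be tips of the tree")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "TaxonomyMap", function(object) {
  cat(sprintf("TaxonomyMap: %d species, %d genera, %d families\n",
              length(object@species), length(unique(object@genus)),
              length(unique(object@family))))
})

setMethod("show", "SpeciesRegistry", function(object) {
  nat <- sum(lengths(object@naturalizedRegions) > 0)
  cat(sprintf(paste0("SpeciesRegistry: %d species (%d with economic use, ",
                     "%d naturalized somewhere)\n"),
              length(object@taxonomy@species), sum(object@econUse), nat))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf(paste0("RegionSet: %d regions, latitude %.1f..%.1f, ",
                     "median natives %d, median aliens %d\n"),
              nrow(object@info), min(object@info$latitude),
              max(object@info$latitude),
              as.integer(stats::median(lengths(object@natives))),
              as.integer(stats::median(lengths(object@aliens)))))
})

setMethod("show", "ClimatePCA", function(object) {
  cat(sprintf("ClimatePCA (%s-level fit): axis1 %.1f%%, axis2 %.1f%% of variance\n",
              object@mode, 100 * object@varExplained[1],
              100 * object@varExplained[2]))
})

setMethod("show", "EnvelopeModel", function(object) {
  cat(sprintf("EnvelopeModel [%s]: AUC %.3f (%s), threshold %.3g\n",
              object@species, object@auc,
              if (object@retained) "retained" else "rejected",
              object@threshold))
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit:", object@formula, "\n")
  if (!isTRUE(object@converged)) cat("  (did not converge)\n")
  tab <- object@coef
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$statistic <- signif(tab$statistic, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  if (!is.na(object@r2adj)) cat(sprintf("  adjusted R^2 = %.3f\n", object@r2adj))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld: %d species on tree, %d regions, %d climate cells\n",
              length(object@tree$tip.label), nrow(object@regions@info),
              nrow(object@climate)))
})

# ---- accessors ------------------------------------------------------------

#' Accessors for package containers
#'
#' Small generic accessors used throughout: species names of a registry or
#' taxonomy, region ids and attribute table of a RegionSet, the native or
#' alien assemblage of a region, and the coefficient table of a ModelFit.
#'
#' @param x The object.
#' @param region A region id (for \code{nativesOf}/\code{aliensOf}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setMethod("speciesNames", "TaxonomyMap", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesNames", "SpeciesRegistry", function(x) x@taxonomy@species)

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setMethod("regionIds", "RegionSet", function(x) as.character(x@info$region_id))

#' @rdname accessors
#' @export
setGeneric("regionInfo", function(x) standardGeneric("regionInfo"))
#' @rdname accessors
#' @export
setMethod("regionInfo", "RegionSet", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("nativesOf", function(x, region) standardGeneric("nativesOf"))
#' @rdname accessors
#' @export
setMethod("nativesOf", "RegionSet", function(x, region) {
  assertThat(region %in% names(x@natives), "unknown region '%s'", region)
  x@natives[[region]]
})

#' @rdname accessors
#' @export
setGeneric("aliensOf", function(x, region) standardGeneric("aliensOf"))
#' @rdname accessors
#' @export
setMethod("aliensOf", "RegionSet", function(x, region) {
  assertThat(region %in% names(x@aliens), "unknown region '%s'", region)
  x@aliens[[region]]
})

#' @rdname accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
#' @rdname accessors
#' @export
setMethod("coefTable", "ModelFit", function(x) x@coef)

#' @rdname accessors
#' @export
setGeneric("worldTree", function(x) standardGeneric("worldTree"))
#' @rdname accessors
#' @export
setMethod("worldTree", "SyntheticWorld", function(x) x@tree)

#' @rdname accessors
#' @export
setGeneric("worldRegions", function(x) standardGeneric("worldRegions"))
#' @rdname accessors
#' @export
setMethod("worldRegions", "SyntheticWorld", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("worldRegistry", function(x) standardGeneric("worldRegistry"))
#' @rdname accessors
#' @export
setMethod("worldRegistry", "SyntheticWorld", function(x) x@registry)

#' @rdname accessors
#' @export
setGeneric("worldClimate", function(x) standardGeneric("worldClimate"))
#' @rdname accessors
#' @export
setMethod("worldClimate", "SyntheticWorld", function(x) x@climate)

#' @rdname accessors
#' @export
setGeneric("naturalizationTable", function(x) standardGeneric("naturalizationTable"))
#' @rdname accessors
#' @export
setMethod("naturalizationTable", "SyntheticWorld", function(x) x@natTable)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticWorld", function(x) x@truth)

# internal fast lookups used by other modules
genusOf <- function(tax, sp) tax@genus[match(sp, tax@species)]
familyOf <- function(tax, sp) tax@family[match(sp, tax@species)]
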