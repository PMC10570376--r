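#' The six alien source-pool types
#'
#' Returns the names of the six candidate source pools a region's naturalized
#' aliens may be drawn from in the null model, from most to least inclusive:
#' \describe{
#'   \item{GLOBAL_NONNATIVE}{all species not native to the focal region.}
#'   \item{ECON_USE_FLORA}{species with economic uses plus the global
#'     naturalized flora, minus the region's natives.}
#'   \item{GLOBAL_NAT}{species naturalized in at least one region worldwide.}
#'   \item{CONTINENT_NAT}{species naturalized somewhere on the focal
#'     region's continent.}
#'   \item{CLIMATE_NAT}{globally naturalized species climatically suitable
#'     for the focal region.}
#'   \item{CLIMATE_CONTINENT_NAT}{intersection of the previous two.}
#' }
#'
#' @return Character vector of length six.
#' @export
poolTypes <- function() {
  c("GLOBAL_NONNATIVE", "ECON_USE_FLORA", "GLOBAL_NAT", "CONTINENT_NAT",
    "CLIMATE_NAT", "CLIMATE_CONTINENT_NAT")
}

#' Build a species registry from long-format status records
#'
#' Records are rows (region_id, species, status) with status \code{"native"}
#' or \code{"naturalized"}. A (region, species) pair reported with both
#' statuses is a conflict, resolved by the chosen rule: \code{"native_wins"}
#' (the default) assigns conflicted records as native; \code{"alien_wins"} is
#' the sensitivity variant assigning them as naturalized.
#'
#' @param records data.frame with columns region_id, species, status.
#' @param taxonomy A \linkS4class{TaxonomyMap} covering all species.
#' @param econUse Named logical economic-use flag per species (defaults to
#'   all-FALSE).
#' @param rule Conflict-resolution rule.
#' @return A \linkS4class{SpeciesRegistry} with attribute
#'   \code{"n_conflicts"}, the number of conflicting (region, species) pairs.
#' @export
resolveStatusConflicts <- function(records, taxonomy,
                                   econUse = NULL,
                                   rule = c("native_wins", "alien_wins")) {
  rule <- match.arg(rule)
  assertThat(all(c("region_id", "species", "status") %in% names(records)),
             "records need columns region_id, species, status")
  bad <- setdiff(unique(records$status), c("native", "naturalized"))
  assertThat(length(bad) == 0, "unknown status token(s): %s",
             paste(bad, collapse = ", "))
  assertThat(all(records$species %in% taxonomy@species),
             "records contain species absent from taxonomy: %s",
             paste(head(setdiff(records$species, taxonomy@species), 5),
                   collapse = ", "))
  sp <- taxonomy@species
  if (is.null(econUse)) econUse <- stats::setNames(rep(FALSE, length(sp)), sp)
  econUse <- as.logical(econUse[sp]); names(econUse) <- sp
  econUse[is.na(econUse)] <- FALSE

  key <- paste(records$region_id, records$species, sep = "\r")
  isNat <- records$status == "native"
  natKeys <- unique(key[isNat])
  alnKeys <- unique(key[!isNat])
  conflicts <- intersect(natKeys, alnKeys)
  if (rule == "native_wins") alnKeys <- setdiff(alnKeys, conflicts)
  else natKeys <- setdiff(natKeys, conflicts)

  splitKeys <- function(keys) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(region = vapply(parts, `[`, "", 1),
               species = vapply(parts, `[`, "", 2))
  }
  emptyList <- stats::setNames(rep(list(character(0)), length(sp)), sp)
  natDf <- splitKeys(natKeys); alnDf <- splitKeys(alnKeys)
  nativeRegions <- emptyList
  if (nrow(natDf)) {
    byNat <- split(natDf$region, factor(natDf$species, levels = sp))
    nativeRegions[names(byNat)] <- lapply(byNat, sort)
  }
  naturalizedRegions <- emptyList
  if (nrow(alnDf)) {
    byAln <- split(alnDf$region, factor(alnDf$species, levels = sp))
    naturalizedRegions[names(byAln)] <- lapply(byAln, sort)
  }
  reg <- new("SpeciesRegistry", taxonomy = taxonomy, econUse = econUse,
             nativeRegions = nativeRegions,
             naturalizedRegions = naturalizedRegions)
  attr(reg, "n_conflicts") <- length(conflicts)
  reg
}

#' Filter regions by area
#'
#' Retains regions whose area strictly exceeds \code{minArea} (the main
#' analysis uses 5000 km2; 0, 1000 and 10000 km2 are sensitivity settings).
#' Order is preserved.
#'
#' @param regions A \linkS4class{RegionSet}.
#' @param minArea Threshold in km2.
#' @return A \linkS4class{RegionSet} restricted to the retained regions.
#' @export
filterRegions <- function(regions, minArea = 5000) {
  assertThat(minArea >= 0, "minArea must be non-negative")
  keep <- regions@info$area_km2 > minArea
  regionSet(regions@info[keep, , drop = FALSE],
            regions@natives[keep], regions@aliens[keep])
}

# species naturalized in >= 1 region anywhere
naturalizedAnywhere <- function(registry) {
  speciesNames(registry)[lengths(registry@naturalizedRegions) > 0]
}

#' Construct one alien source pool for a focal region
#'
#' Implements the set algebra of the six pools (see \code{\link{poolTypes}}).
#' Every pool excludes the focal region's natives; the region's observed
#' aliens remain members so the null model can redraw them.
#'
#' @param pool One of \code{poolTypes()}.
#' @param region A region id present in \code{regions}.
#' @param regions A \linkS4class{RegionSet}.
#' @param registry A \linkS4class{SpeciesRegistry}.
#' @param suitability Named list, species -> character vector of region ids
#'   where the species is climatically suitable. Required for the two
#'   CLIMATE pools.
#' @return Character vector of candidate species.
#' @export
buildPool <- function(pool, region, regions, registry, suitability = NULL) {
  pool <- match.arg(pool, poolTypes())
  info <- regions@info
  assertThat(region %in% info$region_id, "unknown region '%s'", region)
  sp <- speciesNames(registry)
  regionNatives <- sp[vapply(registry@nativeRegions,
                             function(r) region %in% r, logical(1))]
  globalNat <- naturalizedAnywhere(registry)

  continentNat <- function() {
    cont <- info$continent[info$region_id == region]
    contRegions <- info$region_id[info$continent == cont]
    sp[vapply(registry@naturalizedRegions,
              function(r) any(r %in% contRegions), logical(1))]
  }
  climateNat <- function() {
    assertThat(!is.null(suitability),
               "pool '%s' requires a suitability table", pool)
    suitable <- names(suitability)[vapply(suitability,
                                          function(r) region %in% r,
                                          logical(1))]
    intersect(globalNat, suitable)
  }
  members <- switch(pool,
    GLOBAL_NONNATIVE = setdiff(sp, regionNatives),
    ECON_USE_FLORA = union(sp[registry@econUse], globalNat),
    GLOBAL_NAT = globalNat,
    CONTINENT_NAT = continentNat(),
    CLIMATE_NAT = climateNat(),
    CLIMATE_CONTINENT_NAT = intersect(continentNat(), climateNat()))
  members <- setdiff(members, regionNatives)
  nAlien <- length(aliensOf(regions, region))
  assertThat(length(members) >= nAlien,
             "pool %s of region %s (%d species) smaller than the region's %d aliens",
             pool, region, length(members), nAlien)
  sort(members)
}
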