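#' Parameters of the synthetic world generator
#'
#' Returns the full parameter list with defaults that define the generator's
#' study conditions: a 400-species ultrametric pure-birth phylogeny carrying
#' 40 genera in 12 families, 60 regions spanning latitudes -60..60 with
#' 10 climate cells each, Brownian thermal optima, environmental filtering of
#' native assemblages whose width shrinks exponentially with absolute
#' latitude, and a complementary log-log naturalization process with a
#' negative MPD-by-latitude interaction (preadaptation strengthening
#' poleward).
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @examples
#' p <- worldParams(n_species = 100, n_regions = 20, seed = 7)
#' @export
worldParams <- function(...) {
  p <- list(
    n_species = 400,
    birth_rate = 1,
    n_genera = 40,
    n_families = 12,
    trait_sigma2 = 1,
    n_regions = 60,
    latitude_range = 60,
    n_continents = 6,
    cells_per_region = 10,
    climate_noise_sd = 2,
    cell_lat_jitter = 1,
    filtering_base_sd = 2,
    filtering_latitude_coefficient = 0.02,
    target_richness = 80,
    beta0 = -2.2,
    beta_mpd = -0.4,
    beta_lat = 0.3,
    beta_int = -0.5,
    sd_species = 0.5,
    sd_region = 0.3,
    hm_shape1 = 2,
    hm_shape2 = 5,
    econ_rate = 0.3,
    area_meanlog = log(5e4),
    area_sdlog = 1,
    completeness_min = 0.3,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  assertThat(length(bad) == 0, "unknown world parameter(s): %s",
             paste(bad, collapse = ", "))
  p[names(over)] <- over
  assertThat(p$n_species >= 4, "n_species must be at least 4")
  assertThat(p$n_genera <= p$n_species, "n_genera cannot exceed n_species")
  assertThat(p$n_families <= p$n_genera, "n_families cannot exceed n_genera")
  assertThat(p$birth_rate > 0 && p$trait_sigma2 >= 0 &&
               p$filtering_base_sd > 0 && p$sd_species >= 0 &&
               p$sd_region >= 0, "rates and SDs must be non-negative")
  p
}

#' Simulate a pure-birth (Yule) tree with clade-cut taxonomy
#'
#' Forward simulation of a constant-rate pure-birth process started from two
#' lineages, stopped at \code{nSpecies} tips, with a final exponential wait
#' appended so tips do not end exactly at the last split. The tree is
#' ultrametric by construction. Genera and families are assigned by cutting
#' the tree at the two depths where the lineage count equals
#' \code{nGenera} and \code{nFamilies}, so both ranks are monophyletic and
#' genera nest within families.
#'
#' @param nSpecies Number of tips (>= 4).
#' @param birthRate Speciation rate per lineage per unit time.
#' @param seed Integer seed.
#' @param nGenera,nFamilies Taxon counts for the clade cuts.
#' @return List with elements \code{tree} (a \code{phylo}) and
#'   \code{taxonomy} (a \linkS4class{TaxonomyMap}).
#' @export
simulateTree <- function(nSpecies, birthRate = 1, seed = 1L,
                         nGenera = min(10, nSpecies),
                         nFamilies = min(4, nGenera)) {
  assertThat(nSpecies >= 4, "nSpecies must be at least 4")
  withLocalSeed(seed, {
    nEvents <- nSpecies - 2        # splits after the root split
    parent <- integer(0); child <- integer(0); elen <- numeric(0)
    rootNode <- nSpecies + 1
    # active lineages: originating node and birth time
    actNode <- c(rootNode, rootNode); actBirth <- c(0, 0)
    t <- 0
    splitTimes <- numeric(nEvents)
    for (j in seq_len(nEvents)) {
      k <- length(actNode)
      t <- t + stats::rexp(1, birthRate * k)
      splitTimes[j] <- t
      i <- sample.int(k, 1)
      newNode <- rootNode + j
      parent <- c(parent, actNode[i]); child <- c(child, newNode)
      elen <- c(elen, t - actBirth[i])
      actNode <- c(actNode[-i], newNode, newNode)
      actBirth <- c(actBirth[-i], t, t)
    }
    T_ <- t + stats::rexp(1, birthRate * nSpecies)
    tipLabels <- sprintf("s%04d", seq_len(nSpecies))
    parent <- c(parent, actNode)
    child <- c(child, seq_len(nSpecies))
    elen <- c(elen, T_ - actBirth)
    tree <- list(edge = cbind(parent, child), edge.length = elen,
                 tip.label = tipLabels, Nnode = nSpecies - 1)
    class(tree) <- "phylo"
    attr(tree, "order") <- NULL
    tree <- stats::reorder(tree, "cladewise")

    depths <- nodeDepths(tree)
    cutGroups <- function(count, prefix) {
      if (count >= nSpecies) {
        g <- stats::setNames(paste0(prefix, sprintf("%03d",
                                                    seq_len(nSpecies))),
                             tipLabels)
        return(g)
      }
      tcut <- if (count <= 2) 0 else
        mean(sort(splitTimes)[c(count - 2, count - 1)])
      nodeTime <- depths
      cross <- which(nodeTime[tree$edge[, 1]] <= tcut &
                       nodeTime[tree$edge[, 2]] > tcut)
      g <- stats::setNames(rep(NA_character_, nSpecies), tipLabels)
      for (ii in seq_along(cross)) {
        top <- tree$edge[cross[ii], 2]
        tips <- if (top <= nSpecies) tipLabels[top]
                else ape::extract.clade(tree, top)$tip.label
        g[tips] <- paste0(prefix, sprintf("%03d", ii))
      }
      g
    }
    gen <- cutGroups(nGenera, "g")
    fam <- cutGroups(nFamilies, "f")
    # family of a genus: the family of its tips (consistent by nesting)
    famOfGen <- tapply(fam, gen, function(x) x[1])
    tax <- taxonomyMap(tipLabels, unname(gen[tipLabels]),
                       unname(famOfGen[gen[tipLabels]]))
    list(tree = tree, taxonomy = tax)
  })
}

#' Simulate phylogenetically conserved thermal optima
#'
#' Brownian motion along the tree from a root value of 0, the standard model
#' of niche conservatism: closely related species receive similar optima, so
#' environmental filtering induces phylogenetic clustering.
#'
#' @param tree Ultrametric \code{phylo}.
#' @param traitSigma2 Brownian rate (trait units squared per unit time).
#' @param seed Integer seed.
#' @return Named numeric vector of tip optima.
#' @export
simulateNicheTraits <- function(tree, traitSigma2 = 1, seed = 1L) {
  if (traitSigma2 == 0)
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  withLocalSeed(seed, {
    x <- phytools::fastBM(tree, sig2 = traitSigma2, a = 0)
    x[tree$tip.label]
  })
}

#' Generate regions and their climate grid
#'
#' Region centroids are uniform over the latitude band; continents are
#' longitudinal blocks; areas are log-normal; the human-modification index is
#' Beta-distributed independently of latitude; completeness is uniform.
#' Cell-level climate follows the planetary template: temperature variables
#' decrease with absolute latitude, temperature seasonality increases, and
#' precipitation variables follow a latitude-independent humidity gradient,
#' all with configurable noise, so a PCA recovers a temperature axis and a
#' precipitation axis.
#'
#' @param params A \code{\link{worldParams}} list.
#' @param seed Integer seed.
#' @return List: \code{regions} (a \linkS4class{RegionSet} with empty
#'   assemblages) and \code{climate} (the cell grid).
#' @export
buildRegions <- function(params, seed = 1L) {
  assertThat(params$n_regions >= 8, "need at least 8 regions")
  withLocalSeed(seed, {
    n <- params$n_regions
    ids <- sprintf("R%03d", seq_len(n))
    lat <- stats::runif(n, -params$latitude_range, params$latitude_range)
    lon <- stats::runif(n, 0, 360)
    continent <- paste0("C", cut(lon, breaks = seq(0, 360,
                                                   length.out =
                                                     params$n_continents + 1),
                                 labels = FALSE, include.lowest = TRUE))
    info <- data.frame(
      region_id = ids,
      area_km2 = stats::rlnorm(n, params$area_meanlog, params$area_sdlog),
      latitude = lat,
      continent = continent,
      hm = stats::rbeta(n, params$hm_shape1, params$hm_shape2),
      completeness = stats::runif(n, params$completeness_min, 1))

    m <- params$cells_per_region
    nc <- n * m
    regionCell <- rep(ids, each = m)
    latCell <- rep(lat, each = m) +
      stats::rnorm(nc, 0, params$cell_lat_jitter)
    noise <- function(s = 1) stats::rnorm(nc, 0, s)
    tem <- 28 - 0.55 * abs(latCell) + noise(params$climate_noise_sd)
    hum <- rep(stats::rnorm(n), each = m) + noise(0.5)
    climate <- data.frame(
      region_id = regionCell,
      cell_id = paste0(regionCell, "_c", rep(seq_len(m), n)),
      bio1 = tem,
      bio2 = 10 + 0.10 * tem + noise(0.5),
      bio3 = 40 + 0.60 * tem + noise(1),
      bio4 = 800 - 12 * tem + noise(30),
      bio5 = tem + 9 + noise(1),
      bio6 = tem - 9 + noise(1),
      bio7 = 25 - 0.30 * tem + noise(1),
      bio8 = tem + 3 + noise(1),
      bio9 = tem - 3 + noise(1),
      bio10 = tem + 6 + noise(1),
      bio11 = tem - 6 + noise(1),
      bio12 = exp(6.5 + 0.80 * hum + noise(0.30)),
      bio15 = 60 - 12 * hum + noise(5))
    climate$bio13 <- 0.18 * climate$bio12 * exp(noise(0.1))
    climate$bio14 <- 0.03 * climate$bio12 * exp(noise(0.3))
    climate$bio16 <- 0.45 * climate$bio12 * exp(noise(0.1))
    climate$bio17 <- 0.08 * climate$bio12 * exp(noise(0.2))
    climate$bio18 <- 0.30 * climate$bio12 * exp(noise(0.2))
    climate$bio19 <- 0.20 * climate$bio12 * exp(noise(0.2))
    climate <- climate[, c("region_id", "cell_id", bioclimVariables())]
    empty <- stats::setNames(rep(list(character(0)), n), ids)
    list(regions = regionSet(info, empty, empty), climate = climate)
  })
}

#' Assemble native floras by latitude-dependent environmental filtering
#'
#' Species s is native to region r with probability proportional to a
#' Gaussian niche kernel
#' \code{exp(-(optimum_s - climate_r)^2 / (2 sigma_r^2))} where the filter
#' width \code{sigma_r = filtering_base_sd *
#' exp(-filtering_latitude_coefficient * |lat_r|)} shrinks toward the poles:
#' high-latitude assemblages are drawn from a narrow slice of niche space and
#' are therefore phylogenetically clustered. Occupancy probabilities are
#' normalized per region so the expected richness equals
#' \code{target_richness}. Thermal optima and the regional climate (mean
#' bio1) are compared on a common standardized scale.
#'
#' @param regions A \linkS4class{RegionSet} (assemblages ignored).
#' @param climate The climate grid of \code{regions}.
#' @param optima Named vector from \code{\link{simulateNicheTraits}}.
#' @param params A \code{\link{worldParams}} list.
#' @param seed Integer seed.
#' @return Named list of native species per region.
#' @export
assembleNatives <- function(regions, climate, optima, params, seed = 1L) {
  info <- regionInfo(regions)
  regClim <- tapply(climate$bio1, climate$region_id, mean)[info$region_id]
  climz <- as.numeric(scale(regClim))
  optz <- if (stats::sd(optima) > 0) as.numeric(scale(optima))
          else rep(0, length(optima))
  names(optz) <- names(optima)
  sigma <- params$filtering_base_sd *
    exp(-params$filtering_latitude_coefficient * abs(info$latitude))
  withLocalSeed(seed, {
    draw <- function() {
      out <- vector("list", nrow(info))
      names(out) <- info$region_id
      for (i in seq_len(nrow(info))) {
        kern <- exp(-(optz - climz[i])^2 / (2 * sigma[i]^2))
        p <- pmin(1, kern * params$target_richness / sum(kern))
        out[[i]] <- names(optima)[stats::runif(length(p)) < p]
      }
      out
    }
    natives <- draw()
    if (any(lengths(natives) == 0)) natives <- draw()
    assertThat(all(lengths(natives) > 0),
               "region(s) with zero natives even after resampling: %s",
               paste(names(natives)[lengths(natives) == 0], collapse = ", "))
    natives
  })
}

#' Simulate naturalization outcomes under a cloglog process
#'
#' For every (species, region) pair with the species not native to the
#' region, a naturalization indicator is drawn with probability
#' \code{cloglog^-1(beta0 + beta_mpd * MPDz + beta_lat * |lat|z +
#' beta_int * MPDz * |lat|z + u_species + v_region)}, where MPD is the
#' species' mean patristic distance to the region's natives, z denotes
#' standardization over all pairs, and u, v are Gaussian random effects. The
#' realized random effects and the standardization constants are recorded as
#' ground truth.
#'
#' @param tree The phylogeny.
#' @param regions A \linkS4class{RegionSet} whose natives are populated.
#' @param natives Named list of native species per region.
#' @param params A \code{\link{worldParams}} list.
#' @param seed Integer seed.
#' @return List: \code{aliens} (named list per region), \code{table} (the
#'   species-by-region naturalization table) and \code{truth}.
#' @export
simulateNaturalizations <- function(tree, regions, natives, params,
                                    seed = 1L) {
  info <- regionInfo(regions)
  allSp <- tree$tip.label
  rows <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    r <- info$region_id[i]
    nat <- natives[[r]]
    cand <- setdiff(allSp, nat)
    mpd <- distancesToSet(tree, nat)[cand] / length(nat)
    rows[[i]] <- data.frame(species = cand, region_id = r,
                            mpd_to_natives = as.numeric(mpd),
                            abs_latitude = abs(info$latitude[i]))
  }
  tab <- do.call(rbind, rows)
  mpdz <- as.numeric(scale(tab$mpd_to_natives))
  latz <- as.numeric(scale(tab$abs_latitude))
  withLocalSeed(seed, {
    u <- stats::setNames(stats::rnorm(length(allSp), 0, params$sd_species),
                         allSp)
    v <- stats::setNames(stats::rnorm(nrow(info), 0, params$sd_region),
                         info$region_id)
    eta <- params$beta0 + params$beta_mpd * mpdz + params$beta_lat * latz +
      params$beta_int * mpdz * latz + u[tab$species] + v[tab$region_id]
    p <- 1 - exp(-exp(eta))
    tab$naturalized <- as.integer(stats::runif(nrow(tab)) < p)
    prev <- mean(tab$naturalized)
    assertThat(prev > 0 && prev < 1,
               paste("degenerate naturalization outcome (prevalence %.3f);",
                     "adjust the beta parameters"), prev)
    aliens <- stats::setNames(
      lapply(info$region_id,
             function(r) tab$species[tab$region_id == r &
                                       tab$naturalized == 1]),
      info$region_id)
    truth <- list(params = params, u_species = u, v_region = v,
                  mpd_center = mean(tab$mpd_to_natives),
                  mpd_scale = stats::sd(tab$mpd_to_natives),
                  lat_center = mean(tab$abs_latitude),
                  lat_scale = stats::sd(tab$abs_latitude))
    list(aliens = aliens, table = tab, truth = truth)
  })
}

#' Generate a complete synthetic world
#'
#' Chains tree simulation, trait evolution, region/climate generation, native
#' assembly and the naturalization process, each on its own substream of the
#' master seed, and assembles the results into a \linkS4class{SyntheticWorld}
#' whose registry, regions and climate grid satisfy the preconditions of
#' every downstream pipeline stage.
#'
#' @param params A \code{\link{worldParams}} list (its \code{seed} element is
#'   the master seed).
#' @return A \linkS4class{SyntheticWorld}.
#' @examples
#' w <- generateWorld(worldParams(n_species = 60, n_regions = 12,
#'                                target_richness = 20, seed = 1))
#' @export
generateWorld <- function(params = worldParams()) {
  seed <- params$seed
  sim <- simulateTree(params$n_species, params$birth_rate,
                      seed = substreamSeed(seed, "tree"),
                      nGenera = params$n_genera,
                      nFamilies = params$n_families)
  tree <- sim$tree; tax <- sim$taxonomy
  optima <- simulateNicheTraits(tree, params$trait_sigma2,
                                seed = substreamSeed(seed, "traits"))
  rg <- buildRegions(params, seed = substreamSeed(seed, "regions"))
  natives <- assembleNatives(rg$regions, rg$climate, optima, params,
                             seed = substreamSeed(seed, "natives"))
  withNat <- regionSet(regionInfo(rg$regions), natives,
                       stats::setNames(rep(list(character(0)),
                                           length(natives)),
                                       names(natives)))
  natz <- simulateNaturalizations(tree, withNat, natives, params,
                                  seed = substreamSeed(seed, "naturalization"))
  regions <- regionSet(regionInfo(rg$regions), natives, natz$aliens)

  sp <- tree$tip.label
  econ <- withLocalSeed(substreamSeed(seed, "econ"), {
    stats::setNames(stats::runif(length(sp)) < params$econ_rate, sp)
  })
  invert <- function(listByRegion) {
    out <- stats::setNames(rep(list(character(0)), length(sp)), sp)
    for (r in names(listByRegion))
      for (s in listByRegion[[r]]) out[[s]] <- c(out[[s]], r)
    out
  }
  registry <- new("SpeciesRegistry", taxonomy = tax, econUse = econ,
                  nativeRegions = invert(natives),
                  naturalizedRegions = invert(natz$aliens))
  truth <- natz$truth
  truth$optima <- optima
  new("SyntheticWorld", tree = tree, taxonomy = tax, registry = registry,
      regions = regions, climate = rg$climate, natTable = natz$table,
      truth = truth, params = params)
}

#' Write a synthetic world to disk in the pipeline's exchange formats
#'
#' Emits \code{tree.nwk}, \code{species.csv} (species, genus, family,
#' econ_use), \code{status.csv} (region_id, species, status),
#' \code{regions.csv}, \code{climate.csv} and \code{occurrences.csv}
#' (species, cell_id: every cell of every region where the species occurs),
#' the inputs consumed by \code{\link{runPipeline}}.
#'
#' @param world A \linkS4class{SyntheticWorld}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeNewick(world@tree, file.path(dir, "tree.nwk"))
  tax <- world@taxonomy
  utils::write.csv(data.frame(species = tax@species, genus = tax@genus,
                              family = tax@family,
                              econ_use = as.integer(world@registry@econUse)),
                   file.path(dir, "species.csv"), row.names = FALSE)
  reg <- world@regions
  status <- rbind(
    do.call(rbind, lapply(regionIds(reg), function(r) {
      nat <- nativesOf(reg, r)
      if (!length(nat)) return(NULL)
      data.frame(region_id = r, species = nat, status = "native")
    })),
    do.call(rbind, lapply(regionIds(reg), function(r) {
      al <- aliensOf(reg, r)
      if (!length(al)) return(NULL)
      data.frame(region_id = r, species = al, status = "naturalized")
    })))
  utils::write.csv(status, file.path(dir, "status.csv"), row.names = FALSE)
  utils::write.csv(regionInfo(reg), file.path(dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(world@climate, file.path(dir, "climate.csv"),
                   row.names = FALSE)
  cellsByRegion <- split(world@climate$cell_id, world@climate$region_id)
  occ <- do.call(rbind, lapply(regionIds(reg), function(r) {
    spHere <- c(nativesOf(reg, r), aliensOf(reg, r))
    if (!length(spHere)) return(NULL)
    expand.grid(species = spHere, cell_id = cellsByRegion[[r]],
                stringsAsFactors = FALSE)
  }))
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a world directory back into pipeline inputs
#'
#' @param dir Directory written by \code{\link{writeWorld}} (or assembled by
#'   hand in the same formats).
#' @param conflictRule Passed to \code{\link{resolveStatusConflicts}}.
#' @return List: tree, taxonomy, registry, regions
#'   (\linkS4class{RegionSet}), climate, occurrences.
#' @export
readWorld <- function(dir, conflictRule = "native_wins") {
  tree <- parseNewick(file = file.path(dir, "tree.nwk"))
  spdf <- utils::read.csv(file.path(dir, "species.csv"))
  tax <- taxonomyMap(spdf)
  econ <- stats::setNames(spdf$econ_use > 0, spdf$species)
  status <- utils::read.csv(file.path(dir, "status.csv"))
  registry <- resolveStatusConflicts(status, tax, econ, rule = conflictRule)
  info <- utils::read.csv(file.path(dir, "regions.csv"))
  ids <- as.character(info$region_id)
  emptyAll <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  natives <- emptyAll; aliens <- emptyAll
  for (s in spdf$species) {
    for (r in intersect(registry@nativeRegions[[s]], ids))
      natives[[r]] <- c(natives[[r]], s)
    for (r in intersect(registry@naturalizedRegions[[s]], ids))
      aliens[[r]] <- c(aliens[[r]], s)
  }
  regions <- regionSet(info, natives, aliens)
  climate <- utils::read.csv(file.path(dir, "climate.csv"))
  occ <- utils::read.csv(file.path(dir, "occurrences.csv"))
  list(tree = tree, taxonomy = tax, registry = registry, regions = regions,
       climate = climate, occurrences = occ)
}
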