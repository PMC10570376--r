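#' Pipeline configuration
#'
#' Assembles the configuration of \code{\link{runPipeline}} with defaults
#' mirroring the main-text analysis settings: all six pools, 1000 null
#' replicates, regions larger than 5000 km2, conflicts resolved as native,
#' the full-resolution tree, absolute latitude, cell-level PCA, and the
#' envelope suitability stage.
#'
#' @param in_dir Input world directory (see \code{\link{writeWorld}});
#'   ignored when a \linkS4class{SyntheticWorld} is passed to
#'   \code{runPipeline} directly.
#' @param out_dir Output directory.
#' @param pools Pool types to run (subset of \code{\link{poolTypes}()}).
#' @param n_reps Null-model replicates per (region, pool).
#' @param seed Master seed for every random stage.
#' @param min_area Region area threshold in km2 (strict).
#' @param conflict_rule \code{"native_wins"} or \code{"alien_wins"}.
#' @param tree_resolution \code{"full"} or \code{"genus"} (collapsed tree).
#' @param latitude_mode \code{"absolute"} or \code{"signed"} for the
#'   region-level regressions.
#' @param pca_mode \code{"cell"} or \code{"region"}.
#' @param suitability \code{"envelope"} to fit the envelope stage, or the
#'   path of a precomputed CSV (species, region_id) of suitable regions.
#' @param glmm_structure Random-effect structure of the species-level model.
#' @return Named list of class \code{"natphyloConfig"}.
#' @export
pipelineConfig <- function(in_dir = NULL, out_dir = "natphylo_out",
                           pools = poolTypes(), n_reps = 1000, seed = 1L,
                           min_area = 5000,
                           conflict_rule = c("native_wins", "alien_wins"),
                           tree_resolution = c("full", "genus"),
                           latitude_mode = c("absolute", "signed"),
                           pca_mode = c("cell", "region"),
                           suitability = "envelope",
                           glmm_structure = c("full", "intercepts_only",
                                              "none")) {
  pools <- vapply(pools, function(p) match.arg(p, poolTypes()), character(1))
  assertThat(n_reps >= 1, "n_reps must be at least 1")
  cfg <- list(in_dir = in_dir, out_dir = out_dir, pools = unname(pools),
              n_reps = n_reps, seed = as.integer(seed), min_area = min_area,
              conflict_rule = match.arg(conflict_rule),
              tree_resolution = match.arg(tree_resolution),
              latitude_mode = match.arg(latitude_mode),
              pca_mode = match.arg(pca_mode), suitability = suitability,
              glmm_structure = match.arg(glmm_structure))
  class(cfg) <- "natphyloConfig"
  cfg
}

# occurrences (species, cell_id) implied by the assemblages of a RegionSet
occurrencesFromRegions <- function(regions, climate) {
  cellsByRegion <- split(climate$cell_id, climate$region_id)
  do.call(rbind, lapply(regionIds(regions), function(r) {
    spHere <- c(nativesOf(regions, r), aliensOf(regions, r))
    if (!length(spHere)) return(NULL)
    expand.grid(species = spHere, cell_id = cellsByRegion[[r]],
                stringsAsFactors = FALSE)
  }))
}

#' Build the species-level naturalization table
#'
#' One row per (species, region) pair with the species not native to the
#' region: the species' mean patristic distance to the region's natives, the
#' region's absolute latitude, and whether the species is naturalized there.
#'
#' @param tree The phylogeny.
#' @param regions A \linkS4class{RegionSet}.
#' @param species Candidate species (default: all tree tips).
#' @return data.frame: species, region_id, mpd_to_natives, abs_latitude,
#'   naturalized.
#' @export
buildNaturalizationTable <- function(tree, regions,
                                     species = tree$tip.label) {
  info <- regionInfo(regions)
  rows <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    r <- info$region_id[i]
    nat <- intersect(nativesOf(regions, r), tree$tip.label)
    if (!length(nat)) next
    cand <- setdiff(intersect(species, tree$tip.label), nat)
    if (!length(cand)) next
    mpd <- distancesToSet(tree, nat)[cand] / length(nat)
    rows[[i]] <- data.frame(
      species = cand, region_id = r, mpd_to_natives = as.numeric(mpd),
      abs_latitude = abs(info$latitude[i]),
      naturalized = as.integer(cand %in% aliensOf(regions, r)))
  }
  do.call(rbind, rows)
}

flattenFit <- function(model, fit) {
  co <- fit@coef
  co$model <- model
  if (nrow(fit@stdCoef)) {
    co$std_estimate <- fit@stdCoef$std_estimate[
      match(co$term, fit@stdCoef$term)]
  } else co$std_estimate <- NA_real_
  co$converged <- fit@converged
  co$r2adj <- fit@r2adj
  co[, c("model", "term", "estimate", "se", "statistic", "p_value",
         "std_estimate", "converged", "r2adj")]
}

#' Run the full analysis pipeline
#'
#' Executes ingest, grafting, optional genus-level collapse, pool
#' construction and the null model, the climate PCA, the suitability stage
#' (when a climate pool is requested), the region-level regressions
#' (latitude, latitude-by-HM interaction, climate mixed model), the
#' species-level cloglog naturalization model, and partial predictions, then
#' writes \code{region_results.csv}, \code{naturalization_table.csv},
#' \code{model_fits.csv}, \code{partial_predictions.csv},
#' \code{pca_scores.csv}, \code{suitability.csv} (when fitted) and a
#' \code{manifest.txt} with seeds, stage timings and per-region skip reasons.
#' Any stage error aborts with a stage-named message and the manifest marks
#' the run incomplete.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param world Optional \linkS4class{SyntheticWorld} used instead of
#'   \code{config$in_dir}.
#' @param stages Stages to run: subset of \code{c("null", "pca",
#'   "suitability", "stats")}; defaults to all.
#' @return Invisibly, a list with the main result tables and fitted models.
#' @export
runPipeline <- function(config, world = NULL,
                        stages = c("null", "pca", "suitability", "stats")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(sprintf("package_version: %s",
                        as.character(utils::packageVersion("natphylo"))),
                sprintf("r_version: %s", R.version.string),
                sprintf("seed: %d", config$seed),
                sprintf("n_reps: %d", config$n_reps),
                sprintf("min_area_km2: %s", format(config$min_area)),
                sprintf("pools: %s", paste(config$pools, collapse = ",")),
                sprintf("status: incomplete"))
  writeManifest <- function() writeLines(manifest,
                                         file.path(config$out_dir,
                                                   "manifest.txt"))
  writeManifest()
  stageNo <- 0
  runStage <- function(name, expr) {
    stageNo <<- stageNo + 1
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest <<- c(manifest, sprintf("stage_%02d_%s_seconds: %.2f", stageNo,
                                     name, proc.time()[["elapsed"]] - t0))
    out
  }
  outCsv <- function(df, name) utils::write.csv(
    df, file.path(config$out_dir, name), row.names = FALSE)

  ing <- runStage("ingest", {
    if (!is.null(world)) {
      list(tree = world@tree, taxonomy = world@taxonomy,
           registry = world@registry, regions = world@regions,
           climate = world@climate,
           occurrences = NULL)
    } else {
      assertThat(!is.null(config$in_dir) && dir.exists(config$in_dir),
                 "input directory not found: %s",
                 if (is.null(config$in_dir)) "(unset)" else config$in_dir)
      readWorld(config$in_dir, conflictRule = config$conflict_rule)
    }
  })
  regions <- runStage("filter_regions",
                      filterRegions(ing$regions, config$min_area))
  manifest <- c(manifest, sprintf("n_regions_retained: %d",
                                  nrow(regionInfo(regions))))
  tree <- runStage("grafting", {
    missing <- setdiff(speciesNames(ing$registry), ing$tree$tip.label)
    if (length(missing)) {
      tr <- graftMissingSpecies(ing$tree, ing$taxonomy, missing)
      rep <- graftReport(tr)
      manifest <- c(manifest,
                    sprintf("grafted_at_genus: %d", rep$added_at_genus),
                    sprintf("grafted_at_family: %d", rep$added_at_family))
      tr
    } else ing$tree
  })
  if (config$tree_resolution == "genus")
    tree <- runStage("collapse_genus",
                     collapseToRank(tree, ing$taxonomy, "genus"))

  results <- list()

  suit <- NULL
  needsSuit <- any(grepl("^CLIMATE", config$pools))
  if ("suitability" %in% stages && needsSuit) {
    suit <- runStage("suitability", {
      if (identical(config$suitability, "envelope")) {
        occ <- ing$occurrences
        if (is.null(occ)) occ <- occurrencesFromRegions(ing$regions,
                                                        ing$climate)
        buildSuitabilityTable(occ, ing$climate,
                              seed = substreamSeed(config$seed,
                                                   "suitability"))
      } else {
        df <- utils::read.csv(config$suitability)
        split(as.character(df$region_id), df$species)
      }
    })
    suitDf <- do.call(rbind, lapply(names(suit), function(s)
      if (length(suit[[s]])) data.frame(species = s, region_id = suit[[s]])
      else NULL))
    if (is.null(suitDf))
      suitDf <- data.frame(species = character(0), region_id = character(0))
    outCsv(suitDf, "suitability.csv")
    results$suitability <- suit
  }

  if ("null" %in% stages) {
    poolsNow <- if (needsSuit && is.null(suit))
      setdiff(config$pools, c("CLIMATE_NAT", "CLIMATE_CONTINENT_NAT"))
    else config$pools
    rr <- runStage("null_model",
                   runNullModel(tree, regions, ing$registry,
                                pools = poolsNow, suitability = suit,
                                nReps = config$n_reps, seed = config$seed))
    skipped <- attr(rr, "skipped")
    for (i in seq_len(nrow(skipped)))
      manifest <- c(manifest, sprintf("skipped_region: %s (%s)",
                                      skipped$region_id[i],
                                      skipped$reason[i]))
    outCsv(rr, "region_results.csv")
    results$region_results <- rr
  }

  if ("pca" %in% stages) {
    pcs <- runStage("climate_pca", {
      pca <- fitClimatePCA(ing$climate, mode = config$pca_mode)
      scores <- regionPCScores(pca, ing$climate)
      manifest <- c(manifest,
                    sprintf("pca_axis1_var_frac: %.4f", pca@varExplained[1]),
                    sprintf("pca_axis2_var_frac: %.4f", pca@varExplained[2]))
      list(pca = pca, scores = scores)
    })
    outCsv(pcs$scores, "pca_scores.csv")
    results$pca <- pcs$pca
    results$pc_scores <- pcs$scores
  }

  if ("stats" %in% stages) {
    fits <- runStage("statistics", {
      rr <- results$region_results
      assertThat(!is.null(rr), "statistics stage requires the null stage")
      info <- regionInfo(regions)
      lat <- if (config$latitude_mode == "absolute") abs(info$latitude)
             else info$latitude
      names(lat) <- info$region_id
      hm <- stats::setNames(info$hm, info$region_id)
      cont <- stats::setNames(info$continent, info$region_id)
      fits <- list()
      obs <- rr[rr$pool == rr$pool[1], ]
      fits[["lm_mpd_latitude"]] <- fitWeightedLinear(
        obs$observed_mpd, list(latitude = unname(lat[obs$region_id])))
      fits[["int_mpd_latitude_hm"]] <- fitInteractionModel(
        obs$observed_mpd, unname(lat[obs$region_id]),
        unname(hm[obs$region_id]))
      minRegions <- 8   # too few regions cannot support the design
      for (p in unique(rr$pool)) {
        sub <- rr[rr$pool == p & !is.na(rr$weight), ]
        if (nrow(sub) < minRegions) next
        fits[[paste0("lm_dmpd_latitude_", p)]] <- fitWeightedLinear(
          sub$delta_mpd, list(latitude = unname(lat[sub$region_id])),
          weights = sub$weight)
        fits[[paste0("int_dmpd_latitude_hm_", p)]] <- fitInteractionModel(
          sub$delta_mpd, unname(lat[sub$region_id]),
          unname(hm[sub$region_id]), weights = sub$weight)
      }
      if (!is.null(results$pc_scores)) {
        sc <- results$pc_scores
        pcT <- stats::setNames(sc$pc_temp, sc$region_id)
        pcP <- stats::setNames(sc$pc_prec, sc$region_id)
        fits[["lmm_mpd_climate"]] <- fitLMMClimate(
          obs$observed_mpd, unname(pcT[obs$region_id]),
          unname(pcP[obs$region_id]), unname(hm[obs$region_id]),
          unname(cont[obs$region_id]))
        for (p in unique(rr$pool)) {
          sub <- rr[rr$pool == p & !is.na(rr$weight), ]
          if (nrow(sub) < minRegions) next
          fits[[paste0("lmm_dmpd_climate_", p)]] <- fitLMMClimate(
            sub$delta_mpd, unname(pcT[sub$region_id]),
            unname(pcP[sub$region_id]), unname(hm[sub$region_id]),
            unname(cont[sub$region_id]), weights = sub$weight)
        }
      }
      natTab <- buildNaturalizationTable(tree, regions)
      outCsv(natTab, "naturalization_table.csv")
      fits[["glmm_naturalization"]] <- fitGLMMNaturalization(
        natTab, randomStructure = config$glmm_structure)
      fits
    })
    results$fits <- fits
    results$naturalization_table <- utils::read.csv(
      file.path(config$out_dir, "naturalization_table.csv"))
    fitRows <- do.call(rbind, lapply(names(fits),
                                     function(m) flattenFit(m, fits[[m]])))
    outCsv(fitRows, "model_fits.csv")
    results$model_fits <- fitRows

    pp <- runStage("partial_predictions", {
      rows <- list()
      ppInt <- partialPredictions(fits[["int_mpd_latitude_hm"]], "latitude",
                                  fixQuantiles = list(hm = c(0.1, 0.5, 0.9)),
                                  grid = 25)
      rows[["int_mpd"]] <- data.frame(model = "int_mpd_latitude_hm",
                                      focal = "latitude",
                                      focal_value = ppInt$latitude,
                                      fixed_at = sprintf("hm=%.4f", ppInt$hm),
                                      predicted = ppInt$predicted)
      g <- fits[["glmm_naturalization"]]
      latFix <- unname(stats::quantile(g@data$lat, c(0.1, 0.5, 0.9)))
      ppG <- partialPredictions(g, "mpd", fixValues = list(lat = latFix),
                                grid = 25)
      rows[["glmm"]] <- data.frame(model = "glmm_naturalization",
                                   focal = "mpd",
                                   focal_value = ppG$mpd,
                                   fixed_at = sprintf("lat=%.4f", ppG$lat),
                                   predicted = ppG$predicted)
      do.call(rbind, rows)
    })
    outCsv(pp, "partial_predictions.csv")
    results$partial_predictions <- pp
  }

  manifest[manifest == "status: incomplete"] <- "status: complete"
  writeManifest()
  invisible(results)
}
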