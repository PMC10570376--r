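#' Null distribution of cross-group MPD for a region
#'
#' Keeps the native assemblage and the number of naturalized aliens fixed and
#' redraws the alien identities uniformly, without replacement, from the
#' candidate pool (minus the region's natives). Each replicate's MPD is
#' computed from the linear-time distance-to-set engine
#' (\code{\link{distancesToSet}}), so a replicate costs O(n_aliens) after one
#' O(edges) preprocessing pass.
#'
#' @param tree A \code{phylo}.
#' @param natives Native tip set (fixed).
#' @param nAliens Number of aliens per draw (>= 1).
#' @param pool Candidate species (tips); the region's natives are removed
#'   internally if present.
#' @param nReps Number of replicates (default 1000).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of \code{nReps} null MPD values.
#' @export
nullDistribution <- function(tree, natives, nAliens, pool, nReps = 1000,
                             seed = 1L) {
  checkTipSet(tree, natives, "native")
  assertThat(nAliens >= 1, "nAliens must be at least 1")
  assertThat(nReps >= 1, "nReps must be at least 1")
  candidates <- setdiff(pool, natives)
  checkTipSet(tree, candidates, "pool")
  assertThat(length(candidates) >= nAliens,
             "pool too small: %d candidates for %d aliens",
             length(candidates), nAliens)
  perSpecies <- distancesToSet(tree, natives)[candidates] / length(natives)
  nc <- length(candidates)
  withLocalSeed(seed, {
    vapply(seq_len(nReps),
           function(i) mean(perSpecies[sample.int(nc, nAliens)]),
           numeric(1))
  })
}

#' Summarize an observed MPD against its null distribution
#'
#' Computes DeltaMPD (observed minus null mean), SES.MPD (DeltaMPD divided by
#' the null standard deviation, sample SD with n-1 denominator) and the
#' inverse-null-variance weight used in the downstream weighted regressions.
#' With a degenerate (zero-SD) null, SES and weight are reported as NA.
#'
#' @param observed Observed MPD.
#' @param nulls Numeric vector of null MPD values.
#' @return A one-row data.frame: observed_mpd, null_mean, null_sd, delta_mpd,
#'   ses_mpd, weight, n_reps.
#' @examples
#' summarizeNull(12, c(8, 10, 12))
#' @export
summarizeNull <- function(observed, nulls) {
  assertThat(length(nulls) > 0, "null vector is empty")
  m <- mean(nulls)
  s <- stats::sd(nulls)
  if (length(nulls) == 1) s <- 0
  data.frame(observed_mpd = observed, null_mean = m, null_sd = s,
             delta_mpd = observed - m,
             ses_mpd = if (s > 0) (observed - m) / s else NA_real_,
             weight = if (s > 0) 1 / s^2 else NA_real_,
             n_reps = length(nulls))
}

#' Run the null model for one region across source pools
#'
#' Restricts the region's natives and aliens to species resolvable on the
#' tree, computes the observed cross-group MPD once, then builds each
#' requested pool and its null distribution. Each (region, pool) pair gets a
#' deterministic substream seed derived from the master seed, so results are
#' independent of processing order.
#'
#' @param tree A \code{phylo}.
#' @param region Region id.
#' @param regions A \linkS4class{RegionSet}.
#' @param registry A \linkS4class{SpeciesRegistry}.
#' @param pools Character vector of pool types (default all six).
#' @param suitability Suitability table for the CLIMATE pools (see
#'   \code{\link{buildPool}}).
#' @param nReps Replicates per pool.
#' @param seed Master seed.
#' @return data.frame with one row per pool: region_id, pool, n_native,
#'   n_alien, observed_mpd, null_mean, null_sd, delta_mpd, ses_mpd, weight,
#'   n_reps. Zero rows (with attribute \code{"skip_reason"}) when the region
#'   fails a precondition.
#' @export
runRegionPools <- function(tree, region, regions, registry,
                           pools = poolTypes(), suitability = NULL,
                           nReps = 1000, seed = 1L) {
  natives <- intersect(nativesOf(regions, region), tree$tip.label)
  aliens <- intersect(aliensOf(regions, region), tree$tip.label)
  skip <- function(reason) {
    out <- emptyNullResults()
    attr(out, "skip_reason") <- reason
    out
  }
  if (length(natives) == 0) return(skip("no tree-resolvable natives"))
  if (length(aliens) == 0) return(skip("no tree-resolvable aliens"))
  observed <- crossgroupMPD(tree, aliens, natives)
  poolSkips <- character(0)
  rows <- lapply(pools, function(p) {
    res <- tryCatch({
      pool <- intersect(buildPool(p, region, regions, registry, suitability),
                        tree$tip.label)
      nulls <- nullDistribution(tree, natives, length(aliens), pool,
                                nReps = nReps,
                                seed = substreamSeed(seed, region, p))
      cbind(data.frame(region_id = region, pool = p,
                       n_native = length(natives),
                       n_alien = length(aliens)),
            summarizeNull(observed, nulls))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      poolSkips <<- c(poolSkips, sprintf("%s: %s", p, res))
      NULL
    } else res
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- emptyNullResults()
    attr(out, "skip_reason") <- paste(poolSkips, collapse = "; ")
  } else if (length(poolSkips)) {
    attr(out, "pool_skips") <- poolSkips
  }
  out
}

emptyNullResults <- function() {
  data.frame(region_id = character(0), pool = character(0),
             n_native = integer(0), n_alien = integer(0),
             observed_mpd = numeric(0), null_mean = numeric(0),
             null_sd = numeric(0), delta_mpd = numeric(0),
             ses_mpd = numeric(0), weight = numeric(0), n_reps = integer(0))
}

#' Run the null model for every region of a RegionSet
#'
#' Loops \code{\link{runRegionPools}} over regions, collecting results and a
#' log of skipped regions with their reasons.
#'
#' @inheritParams runRegionPools
#' @return data.frame of per-(region, pool) results with attribute
#'   \code{"skipped"}: a data.frame (region_id, reason).
#' @export
runNullModel <- function(tree, regions, registry, pools = poolTypes(),
                         suitability = NULL, nReps = 1000, seed = 1L) {
  out <- list(); skipped <- list()
  for (r in regionIds(regions)) {
    res <- runRegionPools(tree, r, regions, registry, pools, suitability,
                          nReps, seed)
    if (nrow(res) == 0)
      skipped[[r]] <- data.frame(region_id = r,
                                 reason = attr(res, "skip_reason"))
    else {
      ps <- attr(res, "pool_skips")
      if (length(ps))
        skipped[[r]] <- data.frame(region_id = r,
                                   reason = paste(ps, collapse = "; "))
      out[[r]] <- res
    }
  }
  results <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
             else emptyNullResults()
  attr(results, "skipped") <- if (length(skipped))
    do.call(rbind, c(skipped, make.row.names = FALSE))
  else data.frame(region_id = character(0), reason = character(0))
  results
}
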