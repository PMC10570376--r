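# Shared fixtures: random trees via ape (independent of the package's own
# Yule simulator), tiny worlds, and a hand-built registry.

randTree <- function(n, seed) {
  set.seed(seed)
  ape::rphylo(n, birth = 1, death = 0)
}

randDisjointSets <- function(tree, seed) {
  set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)
  a <- sample(tips, sample.int(max(1, floor(n / 2)), 1))
  b <- sample(setdiff(tips, a), sample.int(max(1, floor(n / 2)), 1))
  list(aliens = a, natives = b)
}

bruteMPD <- function(tree, a, b) {
  D <- stats::cophenetic(tree)
  mean(D[a, b, drop = FALSE])
}

tinyParams <- function(seed = 1, ...) {
  worldParams(n_species = 120, n_regions = 20, target_richness = 30,
              cells_per_region = 6, seed = seed, ...)
}

# registry of 5 species over 3 regions on 2 continents, built from records
toyRegistryParts <- function() {
  tax <- taxonomyMap(sprintf("S%d", 1:5), c("G1", "G1", "G2", "G2", "G3"),
                     c("F1", "F1", "F1", "F1", "F2"))
  records <- rbind(
    data.frame(region_id = "R1", species = c("S1", "S2"), status = "native"),
    data.frame(region_id = "R1", species = c("S3"), status = "naturalized"),
    data.frame(region_id = "R2", species = c("S3", "S4"), status = "native"),
    data.frame(region_id = "R2", species = c("S1", "S5"),
               status = "naturalized"),
    data.frame(region_id = "R3", species = c("S5"), status = "native"),
    data.frame(region_id = "R3", species = c("S4"), status = "naturalized"))
  econ <- stats::setNames(c(TRUE, FALSE, FALSE, TRUE, FALSE),
                          sprintf("S%d", 1:5))
  registry <- resolveStatusConflicts(records, tax, econ)
  info <- data.frame(region_id = c("R1", "R2", "R3"),
                     area_km2 = c(8000, 6000, 9000),
                     latitude = c(10, -35, 52),
                     continent = c("C1", "C1", "C2"),
                     hm = c(0.2, 0.5, 0.7),
                     completeness = c(0.9, 0.8, 0.6))
  natives <- list(R1 = c("S1", "S2"), R2 = c("S3", "S4"), R3 = "S5")
  aliens <- list(R1 = "S3", R2 = c("S1", "S5"), R3 = "S4")
  list(taxonomy = tax, registry = registry,
       regions = regionSet(info, natives, aliens))
}

# climate grid with planted structure for PCA tests
toyGrid <- function(nCells = 40, seed = 5) {
  set.seed(seed)
  lat <- runif(nCells, -60, 60)
  tem <- 25 - 0.5 * abs(lat) + rnorm(nCells, 0, 1)
  g <- data.frame(region_id = paste0("R", rep(1:(nCells / 4), each = 4)),
                  cell_id = paste0("c", seq_len(nCells)))
  for (v in bioclimVariables()) g[[v]] <- rnorm(nCells)
  g$bio1 <- tem
  g$bio12 <- exp(rnorm(nCells, 6, 0.5))
  g
}
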