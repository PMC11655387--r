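## Synthetic island archipelagos: climate grids with a specified future
## displacement, island-structured genotypes with planted climate-adaptive
## loci and optional introgression, and plain-text fixtures for the rest of
## the pipeline.

#' Default climate gradient specification
#'
#' One row per predictor giving an intercept (`base`), linear trends per km
#' of easting/northing (`slope_x`, `slope_y`) and a cell-level Gaussian
#' noise SD. The defaults emulate a Mediterranean-climate archipelago with a
#' cooler, wetter north and an east--west gradient in precipitation
#' seasonality.
#'
#' @return data frame with columns `predictor`, `base`, `slope_x`,
#'   `slope_y`, `noise_sd`.
#' @export
default_climate_gradients <- function() {
  data.frame(
    predictor = c("BIO5", "BIO6", "BIO15", "BIO18", "BIO19", "elev"),
    base      = c(24,  8,   80,  10,  300, 300),
    slope_x   = c(0,   0, -0.05,  0,    0,   0),
    slope_y   = c(-0.02, -0.01, 0, 0.05, 0.5, 0),
    noise_sd  = c(0.3, 0.3, 2,   1,   10,  150),
    stringsAsFactors = FALSE
  )
}

#' Default future climate displacement
#'
#' Warming of roughly two degrees with drier winters, the qualitative
#' pattern of mid-century projections for the southern California coast.
#'
#' @return named numeric vector of future minus historic shifts, one per
#'   predictor (elevation does not change).
#' @export
default_future_shift <- function() {
  c(BIO5 = 2.2, BIO6 = 2.0, BIO15 = 5, BIO18 = -3, BIO19 = -40, elev = 0)
}

#' Simulate an archipelago climate grid
#'
#' Lays out `n_islands` clusters of grid cells on a plane (km coordinates),
#' draws six climate predictors for a historic slice from linear spatial
#' gradients plus noise, and builds a future slice as historic plus a
#' per-predictor displacement (optionally with cell-level variation).
#'
#' @param n_islands number of islands (>= 1).
#' @param cells_per_island grid cells per island (>= 1).
#' @param climate_gradients gradient specification as returned by
#'   [default_climate_gradients()].
#' @param future_shift named vector of per-predictor displacements
#'   (future minus historic); see [default_future_shift()].
#' @param shift_sd optional named vector of cell-level SDs around each
#'   displacement (default 0: the shift is exact and uniform).
#' @param island_spacing_km distance between island centres.
#' @param island_radius_km spread of cells around an island centre.
#' @param seed integer RNG seed.
#' @return an object of class `archipelago` with elements `grid` (cell_id,
#'   island, x, y), `historic` and `future` (cells x predictors matrices),
#'   `displacement` (`future - historic`), `predictors`, and `seed`.
#' @export
make_archipelago <- function(n_islands,
                             cells_per_island,
                             climate_gradients = default_climate_gradients(),
                             future_shift = default_future_shift(),
                             shift_sd = NULL,
                             island_spacing_km = 40,
                             island_radius_km = 8,
                             seed = 1L) {
  if (!is.numeric(n_islands) || n_islands < 1)
    stop("n_islands must be a positive integer")
  if (!is.numeric(cells_per_island) || cells_per_island < 1)
    stop("cells_per_island must be a positive integer")
  preds <- climate_gradients$predictor
  if (!all(names(future_shift) %in% preds))
    stop("future_shift names must match gradient predictors")
  set.seed(seed)

  ## island centres on a gentle arc so latitude and longitude both vary
  centre_x <- (seq_len(n_islands) - 1) * island_spacing_km
  centre_y <- (seq_len(n_islands) - 1) * island_spacing_km * 0.6 +
    sin(seq_len(n_islands)) * island_spacing_km * 0.15

  n_cells <- n_islands * cells_per_island
  island <- rep(sprintf("island%02d", seq_len(n_islands)),
                each = cells_per_island)
  x <- rep(centre_x, each = cells_per_island) +
    runif(n_cells, -island_radius_km, island_radius_km)
  y <- rep(centre_y, each = cells_per_island) +
    runif(n_cells, -island_radius_km, island_radius_km)
  grid <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(n_cells)),
    island = island, x = x, y = y, stringsAsFactors = FALSE
  )

  historic <- matrix(NA_real_, n_cells, length(preds),
                     dimnames = list(grid$cell_id, preds))
  for (i in seq_along(preds)) {
    g <- climate_gradients[i, ]
    historic[, i] <- g$base + g$slope_x * x + g$slope_y * y +
      rnorm(n_cells, 0, g$noise_sd)
  }

  displacement <- matrix(0, n_cells, length(preds),
                         dimnames = dimnames(historic))
  for (p in names(future_shift)) {
    displacement[, p] <- future_shift[[p]]
    if (!is.null(shift_sd) && !is.null(shift_sd[[p]]) && shift_sd[[p]] > 0)
      displacement[, p] <- displacement[, p] +
        rnorm(n_cells, 0, shift_sd[[p]])
  }
  future <- historic + displacement

  structure(
    list(grid = grid, historic = historic, future = future,
         displacement = displacement, predictors = preds, seed = seed),
    class = "archipelago"
  )
}

#' @export
print.archipelago <- function(x, ...) {
  cat(sprintf("archipelago: %d islands, %d cells, predictors: %s\n",
              length(unique(x$grid$island)), nrow(x$grid),
              paste(x$predictors, collapse = ", ")))
  invisible(x)
}

#' Simulate island-structured genotypes over an archipelago
#'
#' Neutral loci follow the Balding--Nichols model: an ancestral frequency
#' `p0 ~ Uniform(0.05, 0.95)` and island frequencies drawn from
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` so that islands are differentiated at
#' the target F_ST `F`. Adaptive loci follow a logistic cline in one driving
#' climate predictor: the allele frequency at a cell is
#' `plogis(qlogis(p0) + b * z)` with `z` the standardised driver value.
#' Genotypes are binomial draws of two alleles; missingness is applied per
#' genotype, either uniformly or through a Poisson read-depth mask.
#'
#' @param arch an [make_archipelago()] object.
#' @param n_per_island diploid individuals sampled per island.
#' @param n_neutral,n_adaptive locus counts.
#' @param fst Balding--Nichols differentiation parameter in (0, 1).
#' @param effect_b cline steepness for adaptive loci (logit scale per SD of
#'   the driver); its sign sets the direction of the cline.
#' @param adaptive_driver predictor name(s) driving the adaptive loci,
#'   recycled across loci.
#' @param admixture optional list describing a two-pool introgression
#'   gradient: `rates` (per-island mean ancestry of pool A, recycled) and
#'   `concentration` (Beta concentration of individual ancestries,
#'   default 10). `NULL` disables admixture (all individuals pure pool A).
#' @param missing_rate per-genotype missingness probability (uniform mode).
#' @param depth optional list(`lambda`, `min_dp`) switching to depth-driven
#'   missingness: DP ~ Poisson(lambda), genotypes with DP < min_dp masked.
#' @param seed integer RNG seed.
#' @return list with elements `gm` (a [genotype_matrix()], with a `depth`
#'   attribute holding the per-genotype DP matrix) and `truth` (data frame
#'   locus_id/type/driver/b, with attributes `fst` and `admixture`).
#' @export
simulate_genotypes <- function(arch,
                               n_per_island = 20,
                               n_neutral = 1800,
                               n_adaptive = 200,
                               fst = 0.05,
                               effect_b = 2,
                               adaptive_driver = "BIO5",
                               admixture = NULL,
                               missing_rate = 0,
                               depth = NULL,
                               seed = 1L) {
  if (!inherits(arch, "archipelago")) stop("arch must be an archipelago")
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (n_adaptive > 0 && effect_b == 0)
    warning("effect_b = 0: adaptive loci are indistinguishable from neutral")
  set.seed(seed)

  islands <- unique(arch$grid$island)
  n_isl <- length(islands)
  n_ind <- n_per_island * n_isl
  n_loci <- n_neutral + n_adaptive

  ## place individuals on random cells of their island
  cell_idx <- unlist(lapply(islands, function(isl) {
    sample(which(arch$grid$island == isl), n_per_island, replace = TRUE)
  }))
  sample_meta <- data.frame(
    id = sprintf("ind%03d", seq_len(n_ind)),
    island = rep(islands, each = n_per_island),
    lat = arch$grid$y[cell_idx],
    lon = arch$grid$x[cell_idx],
    cell_id = arch$grid$cell_id[cell_idx],
    stringsAsFactors = FALSE
  )

  ## individual admixture proportions (share of ancestral pool A)
  if (is.null(admixture)) {
    q <- rep(1, n_ind)
  } else {
    rates <- rep(admixture$rates, length.out = n_isl)
    conc <- if (is.null(admixture$concentration)) 10 else admixture$concentration
    q <- rbeta(n_ind,
               rep(rates, each = n_per_island) * conc,
               (1 - rep(rates, each = n_per_island)) * conc)
  }
  sample_meta$species_field_id <-
    ifelse(q >= 0.9, "species_A", ifelse(q <= 0.1, "species_B", "hybrid"))

  isl_of_ind <- match(sample_meta$island, islands)
  dosage <- matrix(NA_integer_, n_ind, n_loci)

  bn_island_freqs <- function(p0) {
    ## Balding-Nichols island frequencies around ancestral p0
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    matrix(rbeta(n_isl * length(p0), rep(a, each = n_isl),
                 rep(b, each = n_isl)), nrow = n_isl)
  }

  ## neutral loci: two ancestral pools if admixing, one otherwise
  p0a <- runif(n_neutral, 0.05, 0.95)
  pa <- bn_island_freqs(p0a)             # islands x loci, pool A
  if (is.null(admixture)) {
    pb <- pa
  } else {
    p0b <- runif(n_neutral, 0.05, 0.95)
    pb <- bn_island_freqs(p0b)
  }
  for (j in seq_len(n_neutral)) {
    p_ind <- q * pa[isl_of_ind, j] + (1 - q) * pb[isl_of_ind, j]
    dosage[, j] <- rbinom(n_ind, 2, p_ind)
  }

  ## adaptive loci: logistic cline in the standardised driving predictor
  drivers <- character(0)
  if (n_adaptive > 0) {
    drivers <- rep(adaptive_driver, length.out = n_adaptive)
    if (!all(drivers %in% arch$predictors))
      stop("adaptive_driver must name archipelago predictors")
    p0_ad <- runif(n_adaptive, 0.2, 0.8)
    for (k in seq_len(n_adaptive)) {
      z <- scale(arch$historic[, drivers[k]])[, 1]
      p_cell <- plogis(qlogis(p0_ad[k]) + effect_b * z)
      dosage[, n_neutral + k] <- rbinom(n_ind, 2, p_cell[cell_idx])
    }
  }

  ## per-genotype depth and missingness
  if (!is.null(depth)) {
    min_dp <- if (is.null(depth$min_dp)) 5L else as.integer(depth$min_dp)
    dp <- matrix(rpois(n_ind * n_loci, depth$lambda), n_ind, n_loci)
    dosage[dp < min_dp] <- NA_integer_
  } else {
    dp <- matrix(20L, n_ind, n_loci)
    if (missing_rate > 0) {
      miss <- matrix(runif(n_ind * n_loci) < missing_rate, n_ind, n_loci)
      dosage[miss] <- NA_integer_
      dp[miss] <- 3L   # below the default depth mask, so a re-read masks too
    }
  }

  locus_id <- sprintf("snp%05d", seq_len(n_loci))
  snp_meta <- data.frame(
    chrom = "1", pos = seq_len(n_loci) * 1000L,
    ref = "A", alt = "T",
    id = locus_id,
    mean_depth = colMeans(dp),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(dosage, snp_meta, sample_meta)
  attr(gm, "depth") <- dp

  truth <- data.frame(
    locus_id = locus_id,
    type = rep(c("neutral", "adaptive"), c(n_neutral, n_adaptive)),
    driver = c(rep(NA_character_, n_neutral), drivers),
    b = c(rep(NA_real_, n_neutral), rep(effect_b, n_adaptive)),
    stringsAsFactors = FALSE
  )
  attr(truth, "fst") <- fst
  attr(truth, "admixture") <- q
  attr(truth, "seed") <- seed

  list(gm = gm, truth = truth)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits a VCF (GT and per-genotype DP), sample metadata CSV, per-sample and
#' gridded climate CSVs (historic and future slices), the truth table, and a
#' JSON manifest recording the seed and the file list.
#'
#' @param gm genotype matrix from [simulate_genotypes()].
#' @param arch the archipelago the genotypes were simulated on.
#' @param truth truth table from [simulate_genotypes()].
#' @param dir output directory; created if absent.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the manifest as a list.
#' @export
write_fixture <- function(gm, arch, truth, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory ", dir, " is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  vcf_path <- file.path(dir, "genotypes.vcf")
  write_vcf(gm, vcf_path, depth = attr(gm, "depth"))

  samples_path <- file.path(dir, "samples.csv")
  write.csv(gm$sample_meta, samples_path, row.names = FALSE)

  ## per-sample climate (historic and future at the individual's cell)
  ci <- match(gm$sample_meta$cell_id, arch$grid$cell_id)
  clim_sample <- rbind(
    data.frame(sample_id = gm$sample_meta$id, slice = "historic",
               arch$historic[ci, , drop = FALSE], check.names = FALSE),
    data.frame(sample_id = gm$sample_meta$id, slice = "future",
               arch$future[ci, , drop = FALSE], check.names = FALSE)
  )
  clim_sample_path <- file.path(dir, "climate_samples.csv")
  write.csv(clim_sample, clim_sample_path, row.names = FALSE)

  ## gridded climate, long over slices
  clim_grid <- rbind(
    data.frame(arch$grid, slice = "historic", arch$historic,
               check.names = FALSE),
    data.frame(arch$grid, slice = "future", arch$future,
               check.names = FALSE)
  )
  grid_path <- file.path(dir, "climate_grid.csv")
  write.csv(clim_grid, grid_path, row.names = FALSE)

  truth_path <- file.path(dir, "truth.csv")
  write.csv(truth, truth_path, row.names = FALSE)

  manifest <- list(
    seed = attr(truth, "seed"),
    n_individuals = nrow(gm$dosage),
    n_loci = ncol(gm$dosage),
    files = basename(c(vcf_path, samples_path, clim_sample_path,
                       grid_path, truth_path))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## Write a genotype_matrix as a minimal VCF 4.2 with GT and DP.
write_vcf <- function(gm, path, depth = NULL) {
  n_ind <- nrow(gm$dosage)
  n_loci <- ncol(gm$dosage)
  if (is.null(depth)) depth <- matrix(20L, n_ind, n_loci)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_meta$id), collapse = "\t")
  )
  body <- vapply(seq_len(n_loci), function(j) {
    d <- gm$dosage[, j]
    g <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(gm$snp_meta$chrom[j], gm$snp_meta$pos[j],
            if (!is.null(gm$snp_meta$id)) gm$snp_meta$id[j] else ".",
            gm$snp_meta$ref[j], gm$snp_meta$alt[j], ".", "PASS", ".",
            "GT:DP", paste0(g, ":", depth[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
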