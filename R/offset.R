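## Genomic offsets between seed sources and planting sites, the three
## conservation scenarios (status quo, ecosystem preservation, species
## preservation), the climate suitability index, and best-pair ranking.

## Climate-only predictor set: spatial (PCNM) axes are excluded from
## offsets by default because unsampled grid cells carry no PCNM values.
offset_predictors <- function(model, use_predictors = NULL,
                              include_spatial = FALSE) {
  if (!is.null(use_predictors)) return(use_predictors)
  if (include_spatial) return(model$predictors)
  grep("^PCNM", model$predictors, invert = TRUE, value = TRUE)
}

#' Genomic offset between two climates
#'
#' Euclidean distance between the genomic-scaled (turnover-transformed)
#' representations of a seed source's historic climate and a planting
#' site's (typically future) climate.
#'
#' @param model a [fit_gf()] turnover model.
#' @param source_row,site_row single climate rows (data frame or named
#'   vector) containing every predictor used.
#' @param use_predictors predictor subset; default: the model's non-PCNM
#'   predictors.
#' @param include_spatial include PCNM axes (only meaningful when both
#'   rows are sampled sites with PCNM values).
#' @return a non-negative scalar; zero iff the transformed climates are
#'   identical.
#' @export
genomic_offset <- function(model, source_row, site_row,
                           use_predictors = NULL,
                           include_spatial = FALSE) {
  up <- offset_predictors(model, use_predictors, include_spatial)
  a <- gf_transform(model, as.data.frame(as.list(source_row)), up)
  b <- gf_transform(model, as.data.frame(as.list(site_row)), up)
  sqrt(sum((a - b)^2))
}

#' Offset table between seed sources and planting sites
#'
#' @param model a [fit_gf()] model.
#' @param source_climates climate rows of the seed sources (historic
#'   slice), one row per source; rownames label the sources.
#' @param site_climates climate rows of the candidate planting sites
#'   (future slice); rownames label the sites.
#' @inheritParams genomic_offset
#' @return sources x sites matrix of offsets with attribute `model_id`.
#' @export
offset_table <- function(model, source_climates, site_climates,
                         use_predictors = NULL, include_spatial = FALSE) {
  up <- offset_predictors(model, use_predictors, include_spatial)
  A <- gf_transform(model, source_climates, up)
  B <- gf_transform(model, site_climates, up)
  O <- matrix(0, nrow(A), nrow(B),
              dimnames = list(rownames(source_climates),
                              rownames(site_climates)))
  for (i in seq_len(nrow(A)))
    O[i, ] <- sqrt(colSums((t(B) - A[i, ])^2))
  attr(O, "model_id") <- model$model_id
  O
}

#' Status-quo scenario: offsets of populations kept in place
#'
#' @param model a [fit_gf()] model.
#' @param hist_rows,fut_rows historic and future climate rows for the same
#'   population cells, in the same order.
#' @inheritParams genomic_offset
#' @return named vector of per-population offsets.
#' @export
scenario_status_quo <- function(model, hist_rows, fut_rows,
                                use_predictors = NULL,
                                include_spatial = FALSE) {
  if (is.null(fut_rows)) stop("future climate slice is missing")
  hist_rows <- as.data.frame(hist_rows)
  fut_rows <- as.data.frame(fut_rows)
  if (nrow(hist_rows) != nrow(fut_rows))
    stop("historic and future slices must cover the same cells")
  up <- offset_predictors(model, use_predictors, include_spatial)
  A <- gf_transform(model, hist_rows, up)
  B <- gf_transform(model, fut_rows, up)
  out <- sqrt(rowSums((A - B)^2))
  names(out) <- rownames(hist_rows)
  out
}

#' Ecosystem-preservation scenario: best seed source per site
#'
#' For each planting site (column of the offset table), the minimum offset
#' over all seed sources and the source attaining it. Exact ties are all
#' reported; the first source in table order is designated.
#'
#' @param offsets sources x sites matrix from [offset_table()], with
#'   future climates at the sites.
#' @return data frame: `site`, `min_offset`, `best_source`, `n_ties`.
#' @export
scenario_ecosystem <- function(offsets) {
  if (nrow(offsets) == 0) stop("empty source set")
  sites <- colnames(offsets)
  if (is.null(sites)) sites <- as.character(seq_len(ncol(offsets)))
  srcs <- rownames(offsets)
  if (is.null(srcs)) srcs <- as.character(seq_len(nrow(offsets)))
  mins <- apply(offsets, 2, min)
  best <- apply(offsets, 2, which.min)
  nt <- vapply(seq_len(ncol(offsets)),
               function(j) sum(offsets[, j] == mins[j]), integer(1))
  data.frame(site = sites, min_offset = mins, best_source = srcs[best],
             n_ties = nt, row.names = NULL, stringsAsFactors = FALSE)
}

#' Species-preservation scenario: best planting site per population
#'
#' For each population (row of the offset table), the minimum offset over
#' the candidate planting sites under future climate.
#'
#' @param offsets populations x candidate-sites matrix from
#'   [offset_table()] (site columns hold future climates; the pool may be
#'   the sampled sites only or every grid cell).
#' @return data frame: `population`, `min_offset`, `best_site`, `n_ties`.
#' @export
scenario_species <- function(offsets) {
  if (ncol(offsets) == 0) stop("empty candidate site pool")
  pops <- rownames(offsets)
  if (is.null(pops)) pops <- as.character(seq_len(nrow(offsets)))
  sites <- colnames(offsets)
  if (is.null(sites)) sites <- as.character(seq_len(ncol(offsets)))
  mins <- apply(offsets, 1, min)
  best <- apply(offsets, 1, which.min)
  nt <- vapply(seq_len(nrow(offsets)),
               function(i) sum(offsets[i, ] == mins[i]), integer(1))
  data.frame(population = pops, min_offset = mins, best_site = sites[best],
             n_ties = nt, row.names = NULL, stringsAsFactors = FALSE)
}

#' Climate suitability index
#'
#' `S = 1 - O / max(O)` over all pairs in the table: 1 means a climate
#' identical to the climate of origin, 0 the least suitable pairing.
#'
#' @param offsets offset matrix (or vector); the maximum is taken over all
#'   entries of this table, so sub-tables scaled against a wider run should
#'   pass `max_offset` explicitly.
#' @param max_offset optional global maximum offset to scale by.
#' @return suitability values in `[0, 1]`, same shape as `offsets`.
#' @export
suitability <- function(offsets, max_offset = NULL) {
  m <- if (is.null(max_offset)) max(offsets) else max_offset
  if (m <= 0) {
    warning("all offsets are zero; suitability is 1 everywhere")
    return(offsets * 0 + 1)
  }
  1 - offsets / m
}

#' Ranked seed-source/planting-site pairs
#'
#' Per planting site, sources ranked by decreasing suitability (and per
#' population, sites likewise); the site ordering reproduces a
#' heat-map-style layout with rows sorted by average suitability, optimal
#' sites first.
#'
#' @param suit sources x sites suitability matrix from [suitability()].
#' @param top_k pairs retained per site/population.
#' @return list with `per_site` and `per_population` rank tables and
#'   `site_order` (site names by decreasing mean suitability).
#' @export
best_pairs <- function(suit, top_k = 1L) {
  if (top_k < 1) stop("top_k must be >= 1")
  srcs <- rownames(suit); if (is.null(srcs)) srcs <- as.character(seq_len(nrow(suit)))
  sites <- colnames(suit); if (is.null(sites)) sites <- as.character(seq_len(ncol(suit)))
  per_site <- do.call(rbind, lapply(seq_len(ncol(suit)), function(j) {
    ord <- order(-suit[, j])[seq_len(min(top_k, nrow(suit)))]
    data.frame(site = sites[j], rank = seq_along(ord), source = srcs[ord],
               suitability = suit[ord, j], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  per_population <- do.call(rbind, lapply(seq_len(nrow(suit)), function(i) {
    ord <- order(-suit[i, ])[seq_len(min(top_k, ncol(suit)))]
    data.frame(population = srcs[i], rank = seq_along(ord),
               site = sites[ord], suitability = suit[i, ord],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  site_order <- sites[order(-colMeans(suit))]
  list(per_site = per_site, per_population = per_population,
       site_order = site_order)
}

#' Full scenario report for a set of populations
#'
#' Computes status-quo offsets, the ecosystem-preservation minima per site,
#' species-preservation minima per population (over the sampled sites and,
#' when a grid is given, over all grid cells), and the suitability matrix
#' scaled by the single maximum offset of the widest table so values are
#' comparable across scenarios.
#'
#' @param model a [fit_gf()] model.
#' @param pop_hist,pop_fut historic/future climate rows at the sampled
#'   population cells (same rownames, same order).
#' @param grid_fut optional future climate rows for every grid cell
#'   (all-cells planting pool).
#' @inheritParams genomic_offset
#' @return list of class `scenario_report` with elements `status_quo`,
#'   `ecosystem`, `species_sampled`, `species_all` (or `NULL`),
#'   `offsets_sampled`, `offsets_all`, `suitability`, `max_offset`.
#' @export
scenario_report <- function(model, pop_hist, pop_fut, grid_fut = NULL,
                            use_predictors = NULL, include_spatial = FALSE) {
  up <- offset_predictors(model, use_predictors, include_spatial)
  sq <- scenario_status_quo(model, pop_hist, pop_fut, up)
  O_sampled <- offset_table(model, pop_hist, pop_fut, up)
  O_all <- if (!is.null(grid_fut)) offset_table(model, pop_hist, grid_fut, up)
           else NULL
  max_off <- max(O_sampled, if (!is.null(O_all)) max(O_all) else -Inf)
  structure(
    list(
      status_quo = sq,
      ecosystem = scenario_ecosystem(O_sampled),
      species_sampled = scenario_species(O_sampled),
      species_all = if (!is.null(O_all)) scenario_species(O_all) else NULL,
      offsets_sampled = O_sampled,
      offsets_all = O_all,
      suitability = suitability(O_sampled, max_offset = max_off),
      max_offset = max_off,
      model_id = model$model_id
    ),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf(
    "scenario_report: %d populations, %d sampled sites%s\n",
    length(x$status_quo), ncol(x$offsets_sampled),
    if (!is.null(x$offsets_all))
      sprintf(", %d grid cells", ncol(x$offsets_all)) else ""))
  cat(sprintf("  mean status-quo offset: %.4f\n", mean(x$status_quo)))
  cat(sprintf("  mean ecosystem-preservation offset: %.4f\n",
              mean(x$ecosystem$min_offset)))
  cat(sprintf("  mean species-preservation offset (sampled): %.4f\n",
              mean(x$species_sampled$min_offset)))
  if (!is.null(x$species_all))
    cat(sprintf("  mean species-preservation offset (all cells): %.4f\n",
                mean(x$species_all$min_offset)))
  invisible(x)
}
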