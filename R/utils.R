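## Internal helpers shared across modules.

#' Construct a genotype matrix object
#'
#' Container for a diploid dosage matrix (individuals x SNPs, values 0/1/2
#' with `NA` for missing) together with per-SNP and per-sample metadata.
#'
#' @param dosage integer matrix, individuals in rows, SNPs in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param snp_meta data frame with one row per SNP; expected columns
#'   `chrom`, `pos` (1-based), `ref`, `alt` and optionally `mean_depth`.
#' @param sample_meta data frame with one row per individual; expected
#'   columns `id`, `island`, `lat`, `lon`, `species_field_id` (extra
#'   columns are carried along).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snp_meta = NULL, sample_meta = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      chrom = "1", pos = seq_len(ncol(dosage)),
      ref = "A", alt = "T", stringsAsFactors = FALSE
    )
  }
  if (is.null(sample_meta)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(dosage)))
    sample_meta <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  if (nrow(snp_meta) != ncol(dosage))
    stop("snp_meta must have one row per dosage column")
  if (nrow(sample_meta) != nrow(dosage))
    stop("sample_meta must have one row per dosage row")
  ## positions strictly increasing within each chromosome
  if (all(c("chrom", "pos") %in% names(snp_meta)) && nrow(snp_meta) > 1) {
    for (ch in unique(snp_meta$chrom)) {
      p <- snp_meta$pos[snp_meta$chrom == ch]
      if (any(diff(p) <= 0))
        stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(dosage) <- sample_meta$id
  if (!is.null(snp_meta$id)) colnames(dosage) <- snp_meta$id
  structure(
    list(dosage = dosage, snp_meta = snp_meta, sample_meta = sample_meta),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * n_miss / length(x$dosage)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param i individual (row) indices; `NULL` keeps all.
#' @param j SNP (column) indices; `NULL` keeps all.
#' @return the subsetted [genotype_matrix()].
#' @export
gm_subset <- function(gm, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(gm$dosage))
  if (is.null(j)) j <- seq_len(ncol(gm$dosage))
  genotype_matrix(
    gm$dosage[i, j, drop = FALSE],
    gm$snp_meta[j, , drop = FALSE],
    gm$sample_meta[i, , drop = FALSE]
  )
}

#' Pairwise site distances in kilometres
#'
#' Great-circle (haversine) distances for lon/lat coordinates, plane
#' Euclidean distances otherwise.
#'
#' @param coords two-column matrix: `(x, y)` in km, or `(lon, lat)` in
#'   degrees with `lonlat = TRUE`.
#' @param lonlat treat columns as lon/lat.
#' @return symmetric sites x sites distance matrix in km.
#' @export
coord_dist_km <- function(coords, lonlat = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have exactly two columns")
  if (lonlat) {
    d <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  } else {
    d <- as.matrix(dist(coords))
  }
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}

## Minor allele frequency per SNP from dosages, ignoring missing entries.
maf_from_dosage <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Deterministic child seed for a numbered sub-stream
#'
#' Derives a reproducible per-stream seed from a user seed and a stream
#' index, staying within the 32-bit integer range.
#'
#' @param seed integer user seed.
#' @param k stream index.
#' @return integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647)
}
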