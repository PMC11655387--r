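## Genotype and climate I/O plus the site/genotype filter ladder:
## biallelic selection, depth masking, MAF and missingness filters,
## window-based LD pruning, and modal imputation.

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x, keeps biallelic SNP records only, converts GT to
#' dosages (count of the alternate allele) and masks genotypes whose
#' FORMAT/DP is below `min_gt_depth`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param min_gt_depth genotypes with read depth below this are set to
#'   missing (0 disables the mask and DP need not be present).
#' @param sample_meta optional per-sample metadata data frame with an `id`
#'   column, joined by sample name.
#' @return a [genotype_matrix()]; per-SNP `mean_depth` is the mean DP over
#'   samples; the attribute `n_non_biallelic` counts excluded records.
#' @export
read_vcf <- function(path, min_gt_depth = 5L, sample_meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0) stop("no records in ", path)
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("GT field absent from FORMAT in ", path)

  biallelic <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  n_non_biallelic <- sum(!biallelic)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ## dosage = number of alternate alleles; separators / or |
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L

  if (min_gt_depth > 0) {
    has_dp <- grepl("(^|:)DP(:|$)", fmt)
    if (!all(has_dp)) {
      bad <- which(!has_dp)[1]
      stop("FORMAT/DP absent (record ", fix[bad, "CHROM"], ":",
           fix[bad, "POS"], ") but min_gt_depth > 0")
    }
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    dos[is.na(dp) | dp < min_gt_depth] <- NA_integer_
  } else {
    dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  }

  keep <- which(biallelic)
  dos <- t(dos[keep, , drop = FALSE])          # individuals x SNPs
  dp <- dp[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[is.na(ids) | ids == "."]
  snp_meta <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
    id = ids,
    mean_depth = rowMeans(dp, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(id = rownames(dos), stringsAsFactors = FALSE)
  } else {
    sample_meta <- sample_meta[match(rownames(dos), sample_meta$id), ,
                               drop = FALSE]
  }
  gm <- genotype_matrix(dos, snp_meta, sample_meta)
  attr(gm, "n_non_biallelic") <- n_non_biallelic
  gm
}

#' Apply site-level filters
#'
#' Removes SNPs failing, in order: mean depth across samples below
#' `min_mean_depth`; minor allele frequency (computed on non-missing,
#' depth-masked dosages) below `min_maf`; missingness above `max_missing`.
#'
#' @param gm a [genotype_matrix()].
#' @param min_mean_depth minimum mean read depth per SNP.
#' @param min_maf minimum minor allele frequency.
#' @param max_missing maximum tolerated fraction of missing genotypes.
#' @return list with `gm` (filtered) and `report`, a filter ledger whose
#'   removals sum to `input - output`.
#' @export
filter_sites <- function(gm, min_mean_depth = 5, min_maf = 0.01,
                         max_missing = 0.10) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1)
    stop("max_missing must be in [0, 1]")
  n_in <- ncol(gm$dosage)
  keep <- rep(TRUE, n_in)

  md <- gm$snp_meta$mean_depth
  rm_depth <- if (!is.null(md)) !is.na(md) & md < min_mean_depth
              else rep(FALSE, n_in)
  keep <- keep & !rm_depth

  maf <- maf_from_dosage(gm$dosage)
  rm_maf <- keep & (is.na(maf) | maf < min_maf)
  keep <- keep & !rm_maf

  miss <- colMeans(is.na(gm$dosage))
  rm_miss <- keep & miss > max_missing
  keep <- keep & !rm_miss

  if (!any(keep)) stop("all SNPs removed: empty matrix")
  report <- list(
    input = n_in,
    output = sum(keep),
    removed = list(
      low_mean_depth = sum(rm_depth),
      low_maf = sum(rm_maf),
      high_missing = sum(rm_miss)
    )
  )
  stopifnot(report$input - sum(unlist(report$removed)) == report$output)
  list(gm = gm_subset(gm, j = which(keep)), report = report)
}

#' Prune SNPs in linkage disequilibrium
#'
#' Sliding-window pruning in the style of PLINK's `--indep-pairwise`:
#' within each window of `window` SNPs (advancing by `step`), pairs with
#' squared Pearson correlation of dosages above `r2` are broken by removing
#' one member until no offending pair remains. Correlations use pairwise
#' complete observations; zero-variance SNPs have undefined correlation and
#' are never removed on that account.
#'
#' Within an offending pair the SNP with the lower minor allele frequency
#' is dropped (tie: the later-position SNP); `dialect = "keep-first"` always
#' drops the later SNP instead.
#'
#' @param gm a [genotype_matrix()].
#' @param window window size in SNPs.
#' @param step window shift in SNPs.
#' @param r2 squared-correlation threshold.
#' @param dialect `"maf"` (default) or `"keep-first"` removal preference.
#' @return list with `gm` (pruned, input order preserved) and `kept`,
#'   indices into the input SNP columns.
#' @export
ld_prune <- function(gm, window = 50L, step = 10L, r2 = 0.1,
                     dialect = c("maf", "keep-first")) {
  dialect <- match.arg(dialect)
  if (!(window > step && step >= 1)) stop("need window > step >= 1")
  dos <- gm$dosage
  m <- ncol(dos)
  maf <- maf_from_dosage(dos)
  pos <- gm$snp_meta$pos
  kept <- seq_len(m)
  s <- 1L
  while (s <= length(kept)) {
    idx <- kept[s:min(s + window - 1L, length(kept))]
    if (length(idx) >= 2) {
      drop <- prune_window(dos[, idx, drop = FALSE], maf[idx], pos[idx],
                           r2, dialect)
      if (length(drop)) kept <- setdiff(kept, idx[drop])
    }
    s <- s + step
  }
  list(gm = gm_subset(gm, j = kept), kept = kept)
}

## Remove columns within one window until no pair exceeds r2; returns the
## local indices removed. Deterministic: the worst pair is treated first.
prune_window <- function(dos, maf, pos, r2, dialect) {
  suppressWarnings(C <- cor(dos, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  r2m <- C^2
  diag(r2m) <- 0
  active <- seq_len(ncol(dos))
  removed <- integer(0)
  repeat {
    sub <- r2m[active, active, drop = FALSE]
    w <- which(sub == max(sub), arr.ind = TRUE)
    if (max(sub) <= r2) break
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    i <- active[w[1]]; j <- active[w[2]]
    if (dialect == "keep-first") {
      out <- if (pos[i] > pos[j]) i else j
    } else if (maf[i] < maf[j]) {
      out <- i
    } else if (maf[j] < maf[i]) {
      out <- j
    } else {
      out <- if (pos[i] > pos[j]) i else j
    }
    removed <- c(removed, out)
    active <- setdiff(active, out)
    if (length(active) < 2) break
  }
  sort(removed)
}

#' Impute missing genotypes with the per-SNP mode
#'
#' Each missing entry is replaced by the most common dosage at that SNP;
#' ties are broken toward the lower dosage (reference-biased, but
#' deterministic). Non-missing entries are never altered.
#'
#' @param gm a [genotype_matrix()].
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_mode <- function(gm) {
  dos <- gm$dosage
  if (!anyNA(dos)) return(gm)
  counts <- vapply(0:2, function(k) colSums(dos == k, na.rm = TRUE),
                   numeric(ncol(dos)))
  if (ncol(dos) == 1) counts <- matrix(counts, nrow = 1)
  all_missing <- rowSums(counts) == 0
  if (any(all_missing)) {
    nm <- gm$snp_meta$id
    if (is.null(nm)) nm <- as.character(which(all_missing))
    stop("SNP(s) entirely missing: ",
         paste(nm[all_missing], collapse = ", "))
  }
  mode_val <- max.col(counts, ties.method = "first") - 1L  # ties -> lower
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mode_val[idx[, 2]]
  out <- gm
  out$dosage <- dos
  out
}

#' Reduce predictors to a pairwise-uncorrelated subset
#'
#' Greedy elimination: while any pair of retained predictors has
#' `|Pearson r| > threshold`, take the currently worst-offending pair and
#' drop the member with the larger mean `|r|` to all other retained
#' predictors. Constant predictors (undefined correlations) are removed
#' first with a warning.
#'
#' @param climate data frame or matrix of numeric predictors.
#' @param threshold maximum tolerated absolute pairwise correlation.
#' @return character vector of retained predictor names.
#' @export
select_uncorrelated_predictors <- function(climate, threshold = 0.7) {
  X <- as.matrix(climate)
  if (ncol(X) < 2) stop("need at least two predictors")
  const <- apply(X, 2, function(v) var(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("removing constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    C <- abs(cor(X[, keep, drop = FALSE], use = "pairwise.complete.obs"))
    diag(C) <- 0
    worst <- max(C)
    if (worst <= threshold) break
    w <- which(C == worst, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    pair <- keep[c(w[1], w[2])]
    mean_r <- vapply(pair, function(p) {
      others <- setdiff(keep, p)
      mean(C[p, others])
    }, numeric(1))
    drop <- if (mean_r[2] >= mean_r[1]) pair[2] else pair[1]
    keep <- setdiff(keep, drop)
  }
  keep
}
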