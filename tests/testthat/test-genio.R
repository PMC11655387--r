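## A three-record toy VCF written inline: a biallelic SNP with one
## low-depth genotype, a triallelic record, and a clean biallelic SNP.
write_toy_vcf <- function(path, format = "GT:DP",
                          geno = c("0/0:20", "0/1:4", "1/1:30"),
                          alt2 = "T,G") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "T", ".", "PASS", ".", format, geno),
          collapse = "\t"),
    paste(c("1", "200", "rs2", "A", alt2, ".", "PASS", ".", format,
            "0/0:9", "0/1:9", "0/0:9"), collapse = "\t"),
    paste(c("1", "300", "rs3", "C", "G", ".", "PASS", ".", format,
            "1/1:15", "0/0:15", "0/1:15"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

test_that("read_vcf masks low-depth genotypes and drops multiallelics", {
  p <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(p, min_gt_depth = 5)
  ## triallelic record excluded, so 2 SNPs survive from 3 records
  expect_equal(ncol(gm$dosage), 2L)
  expect_equal(attr(gm, "n_non_biallelic"), 1L)
  ## the DP=4 genotype is masked, its neighbours kept
  expect_true(is.na(gm$dosage["s2", 1]))
  expect_equal(gm$dosage["s1", 1], 0L)
  expect_equal(gm$dosage["s3", 1], 2L)

  ## disabling the mask returns the raw GT field
  gm0 <- read_vcf(p, min_gt_depth = 0)
  expect_equal(gm0$dosage["s2", 1], 1L)
  expect_false(anyNA(gm0$dosage))
})

test_that("read_vcf errors on absent GT or DP", {
  p1 <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                      format = "DP", geno = c("20", "4", "30"))
  expect_error(read_vcf(p1), "GT")
  p2 <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                      format = "GT", geno = c("0/0", "0/1", "1/1"))
  expect_error(read_vcf(p2, min_gt_depth = 5), "DP")
  expect_silent(gm <- read_vcf(p2, min_gt_depth = 0))
})

test_that("filter_sites applies the rules in order and keeps its ledger", {
  ## 10 SNPs: 2 low-MAF (cols 1-2), 1 high-missing (col 3),
  ## 1 low mean depth (col 4), 6 clean
  set.seed(1)
  n <- 20
  dos <- matrix(rbinom(10 * n, 2, 0.4), n, 10)
  dos[, 1] <- 0L                      # monomorphic: MAF 0
  dos[, 2] <- c(1L, rep(0L, n - 1))   # MAF 1/40 = 0.025
  dos[1:3, 3] <- NA                   # 15% missing > 10%
  gm <- genotype_matrix(dos)
  gm$snp_meta$mean_depth <- c(rep(20, 3), 4, rep(20, 6))
  ## with 20 samples a MAF below 1% is unrepresentable, so the MAF rule is
  ## exercised at 5%; the depth/missingness thresholds are the defaults
  res <- filter_sites(gm, min_mean_depth = 5, min_maf = 0.05,
                      max_missing = 0.10)
  expect_equal(res$report$removed$low_mean_depth, 1L)
  expect_equal(res$report$removed$low_maf, 2L)
  expect_equal(res$report$removed$high_missing, 1L)
  expect_equal(ncol(res$gm$dosage), 6L)
  ## conservation: input = output + sum(removals)
  expect_equal(res$report$input,
               res$report$output + sum(unlist(res$report$removed)))
})

test_that("filter_sites rejects an emptied matrix with a clear error", {
  gm <- genotype_matrix(matrix(0L, 5, 3))   # all monomorphic
  expect_error(filter_sites(gm), "empty matrix")
})

## Independent brute-force pruning oracle: same window/step/removal rule,
## recomputing correlations from scratch with explicit loops.
oracle_prune <- function(dos, pos, window, step, r2) {
  maf <- apply(dos, 2, function(d) {
    p <- mean(d, na.rm = TRUE) / 2; min(p, 1 - p)
  })
  kept <- seq_len(ncol(dos))
  s <- 1
  while (s <= length(kept)) {
    idx <- kept[s:min(s + window - 1, length(kept))]
    repeat {
      if (length(idx) < 2) break
      worst <- 0; wi <- NA; wj <- NA
      for (ii in seq_along(idx)) {
        for (jj in seq_along(idx)) {
          if (jj <= ii) next
          x <- dos[, idx[ii]]; y <- dos[, idx[jj]]
          ok <- !is.na(x) & !is.na(y)
          r <- suppressWarnings(cor(x[ok], y[ok]))
          if (!is.finite(r)) r <- 0
          if (r^2 > worst) { worst <- r^2; wi <- idx[ii]; wj <- idx[jj] }
        }
      }
      if (worst <= r2) break
      out <- if (maf[wi] < maf[wj]) wi
             else if (maf[wj] < maf[wi]) wj
             else if (pos[wi] > pos[wj]) wi else wj
      kept <- setdiff(kept, out)
      idx <- setdiff(idx, out)
    }
    s <- s + step
  }
  kept
}

test_that("ld_prune matches the exhaustive window oracle and is idempotent", {
  set.seed(7)
  n <- 80
  m <- 100
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                n, m)
  ## plant correlated blocks: near-copies of a parent column
  for (start in c(10, 40, 75)) {
    for (k in 1:3) {
      col <- dos[, start]
      flip <- sample(n, 4)
      col[flip] <- rbinom(4, 2, 0.5)
      dos[, start + k] <- col
    }
  }
  gm <- genotype_matrix(dos)
  res <- ld_prune(gm, window = 20, step = 5, r2 = 0.1)
  expect_equal(res$kept, oracle_prune(dos, gm$snp_meta$pos, 20, 5, 0.1))

  ## planted duplicates must not survive together
  expect_lt(length(res$kept), m)

  ## idempotence: pruning the pruned set removes nothing
  res2 <- ld_prune(res$gm, window = 20, step = 5, r2 = 0.1)
  expect_equal(ncol(res2$gm$dosage), ncol(res$gm$dosage))

  ## order preserved
  expect_true(all(diff(res$kept) > 0))
})

test_that("ld_prune trivial cases behave", {
  ## two identical columns -> exactly one retained
  dos <- cbind(c(0L, 1L, 2L, 1L, 0L, 2L), c(0L, 1L, 2L, 1L, 0L, 2L))
  gm <- genotype_matrix(dos)
  res <- ld_prune(gm, window = 2, step = 1, r2 = 0.1)
  expect_equal(length(res$kept), 1L)

  ## mutually orthogonal constructed columns -> all retained
  d2 <- cbind(c(0L, 0L, 1L, 1L, 2L, 2L, 1L, 1L),
              c(1L, 1L, 0L, 2L, 0L, 2L, 1L, 1L),
              c(0L, 2L, 1L, 1L, 1L, 1L, 0L, 2L))
  stopifnot(max(abs(cor(d2)[upper.tri(diag(3))])) < 1e-8)
  res2 <- ld_prune(genotype_matrix(d2), window = 3, step = 1, r2 = 0.1)
  expect_equal(res2$kept, 1:3)
})

test_that("impute_mode fills with the modal dosage, lower on ties", {
  dos <- cbind(c(0L, 0L, 1L, 2L, NA),   # mode 0
               c(1L, 1L, 0L, 2L, 1L),   # complete column
               c(0L, 0L, 2L, 2L, NA))   # tie {0:2, 2:2}
  gm <- genotype_matrix(dos)
  out <- impute_mode(gm)
  expect_false(anyNA(out$dosage))
  expect_equal(unname(out$dosage[5, 1]), 0L)   # mode 0 among (0,0,1,2)
  expect_equal(unname(out$dosage[5, 3]), 0L)   # tie -> lower dosage
  ## non-missing entries preserved exactly
  keep <- !is.na(gm$dosage)
  expect_identical(out$dosage[keep], gm$dosage[keep])

  ## identity on complete data
  gm2 <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 2, 2))
  expect_identical(impute_mode(gm2), gm2)

  ## all-missing SNP errors with its name
  gm3 <- genotype_matrix(cbind(c(0L, 1L), c(NA, NA)))
  gm3$snp_meta$id <- c("okA", "badB")
  expect_error(impute_mode(gm3), "badB")
})

## Independent greedy oracle for predictor reduction.
oracle_select <- function(X, threshold) {
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    C <- abs(cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= threshold) break
    w <- which(C == max(C), arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    pair <- keep[c(w[1], w[2])]
    mr <- sapply(pair, function(p) mean(C[p, setdiff(keep, p)]))
    keep <- setdiff(keep, if (mr[2] >= mr[1]) pair[2] else pair[1])
  }
  keep
}

test_that("select_uncorrelated_predictors matches the greedy oracle", {
  set.seed(11)
  n <- 200
  base <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(
    v1 = base[, 1],
    v2 = base[, 1] + rnorm(n, 0, 0.1),    # ~0.99 with v1
    v3 = base[, 2],
    v4 = base[, 2] + base[, 1] + rnorm(n, 0, 0.5),
    v5 = base[, 3],
    v6 = base[, 3] + rnorm(n, 0, 0.4),
    v7 = base[, 4],
    v8 = -base[, 4] + rnorm(n, 0, 0.3)
  )
  got <- select_uncorrelated_predictors(as.data.frame(X), 0.7)
  expect_equal(got, oracle_select(X, 0.7))
  C <- abs(cor(X[, got])); diag(C) <- 0
  expect_lte(max(C), 0.7)

  ## r = 0.99 pair -> one retained
  got2 <- select_uncorrelated_predictors(as.data.frame(X[, 1:2]), 0.7)
  expect_equal(length(got2), 1L)

  ## already-uncorrelated set is untouched
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(select_uncorrelated_predictors(as.data.frame(Y), 0.7),
               c("a", "b", "c"))

  ## constant predictor removed first, with a warning
  Z <- data.frame(k = rep(1, n), a = rnorm(n), b = rnorm(n))
  expect_warning(gotz <- select_uncorrelated_predictors(Z, 0.7), "constant")
  expect_false("k" %in% gotz)
})
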