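## Brute-force RDA oracle: explicit hat-matrix projection of the centred
## responses onto the standardised predictors, then SVD.
oracle_rda <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  Yhat <- H %*% Yc
  sv <- svd(Yhat)
  d <- sv$d[sv$d > max(sv$d) * 1e-10]
  n <- nrow(Y); p <- ncol(X)
  r2 <- sum(Yhat^2) / sum(Yc^2)
  list(eig = d^2 / (n - 1), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

test_that("fit_rda matches the hat-matrix oracle and vegan on a toy", {
  set.seed(21)
  n <- 20; m <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  B <- matrix(rnorm(3 * m, 0, 0.5), 3, m)
  Y <- X %*% B + matrix(rnorm(n * m), n, m)
  fit <- fit_rda(Y, X)
  ora <- oracle_rda(Y, X)
  expect_equal(fit$eig, ora$eig, tolerance = 1e-8)
  expect_equal(fit$r2, ora$r2, tolerance = 1e-10)
  expect_equal(fit$adj_r2, ora$adj_r2, tolerance = 1e-10)
  expect_true(all(diff(fit$eig) <= 1e-12))

  ## vegan cross-check: eigenvalues, R2, adjusted R2
  v <- vegan::rda(Y ~ x1 + x2 + x3, data = as.data.frame(X), scale = FALSE)
  expect_equal(unname(fit$eig), unname(v$CCA$eig), tolerance = 1e-8)
  ra <- vegan::RsquareAdj(v)
  expect_equal(fit$r2, ra$r.squared, tolerance = 1e-8)
  expect_equal(fit$adj_r2, ra$adj.r.squared, tolerance = 1e-8)

  ## loadings agree with vegan up to per-axis sign
  vl <- vegan::scores(v, display = "species",
                      choices = seq_along(fit$eig), scaling = 0)
  for (k in seq_along(fit$eig)) {
    a <- fit$loadings[, k] / sqrt(sum(fit$loadings[, k]^2))
    b <- vl[, k] / sqrt(sum(vl[, k]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }
})

test_that("partial RDA matches vegan's Condition()", {
  set.seed(4)
  n <- 30; m <- 40
  Z <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("z1", "z2")))
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- Z %*% matrix(rnorm(2 * m), 2, m) + X %*% matrix(rnorm(2 * m), 2, m) +
    matrix(rnorm(n * m), n, m)
  fit <- fit_rda(Y, X, condition = Z)
  dat <- data.frame(X, Z)
  v <- vegan::rda(Y ~ x1 + x2 + Condition(z1 + z2), data = dat)
  expect_equal(unname(fit$eig), unname(v$CCA$eig), tolerance = 1e-8)
})

test_that("fit_rda limiting cases: exact fit, null data, collinearity", {
  set.seed(31)
  n <- 25
  X <- matrix(rnorm(n * 2), n, 2)
  ## responses exactly in the predictor span -> R2 = 1, two axes
  Yex <- scale(X) %*% matrix(c(1, 2, -1, 0.5, 3, 1), 2, 3)
  fex <- fit_rda(Yex, X)
  expect_equal(fex$r2, 1, tolerance = 1e-10)
  expect_equal(length(fex$eig), 2L)

  ## independent noise -> adjusted R2 near zero (can be slightly negative)
  set.seed(32)
  Y0 <- matrix(rnorm(100 * 60), 100, 60)
  X0 <- matrix(rnorm(100 * 3), 100, 3)
  f0 <- fit_rda(Y0, X0)
  expect_lt(abs(f0$adj_r2), 0.02)

  ## duplicated predictor -> informative collinearity error
  Xc <- cbind(a = X[, 1], b = X[, 1])
  expect_error(fit_rda(Yex, Xc), "select_uncorrelated_predictors")

  ## missing responses refused
  Yna <- Yex; Yna[1, 1] <- NA
  expect_error(fit_rda(Yna, X), "impute")
})

test_that("permutation test resolves signal and respects its floor", {
  set.seed(41)
  n <- 30; m <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  Ysig <- scale(X) %*% matrix(rnorm(2 * m, 0, 2), 2, m) +
    matrix(rnorm(n * m, 0, 0.3), n, m)
  ps <- permutation_test(fit_rda(Ysig, X), n_perm = 99, seed = 1)
  ## strong signal: best attainable p at 99 permutations
  expect_equal(ps$p, 0.01)
  expect_equal(length(ps$f_perm), 99L)
  expect_true(all(ps$f_perm < ps$f_obs))

  ## determinism
  ps2 <- permutation_test(fit_rda(Ysig, X), n_perm = 99, seed = 1)
  expect_identical(ps$p, ps2$p)
})

test_that("permutation test holds its nominal type-I error under the null", {
  ## 400 null replicates at small n; rejection rate at alpha = 0.05 should
  ## be 0.05 within binomial noise (3 sd ~ 0.033)
  set.seed(55)
  n <- 12; m <- 5
  rej <- 0L
  n_rep <- 400L
  for (b in seq_len(n_rep)) {
    Y <- matrix(rnorm(n * m), n, m)
    X <- matrix(rnorm(n * 2), n, 2)
    p <- permutation_test(fit_rda(Y, X), n_perm = 99, seed = b)$p
    if (p <= 0.05) rej <- rej + 1L
  }
  rate <- rej / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("variance partitioning satisfies its additivity identity", {
  set.seed(61)
  n <- 60; m <- 80
  clim <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  geo <- data.frame(g1 = rnorm(n), g2 = rnorm(n))
  Y <- as.matrix(clim) %*% matrix(rnorm(2 * m), 2, m) +
    0.5 * as.matrix(geo) %*% matrix(rnorm(2 * m), 2, m) +
    matrix(rnorm(n * m), n, m)
  vp <- variance_partition(Y, clim, geo, n_perm = 49, seed = 1)
  ## identity holds to numerical precision by construction
  expect_equal(vp$full,
               vp$climate_alone + vp$geography_alone + vp$joint,
               tolerance = 1e-10)
  ## both drivers detectable
  expect_lte(vp$p[["full"]], 0.05)
  expect_gt(vp$climate_alone, 0)
  expect_gt(vp$geography_alone, 0)

  ## climate-only world: geography explains (essentially) nothing alone
  Yc <- as.matrix(clim) %*% matrix(rnorm(2 * m), 2, m) +
    matrix(rnorm(n * m), n, m)
  vpc <- variance_partition(Yc, clim, geo, n_perm = 49, seed = 2)
  expect_lt(abs(vpc$geography_alone), 0.01)
  expect_gt(vpc$climate_alone, 0.1)
  expect_gt(vpc$p[["geography_alone"]], 0.05)

  ## confounded world: shared driver flows into the joint fraction
  shared <- rnorm(n)
  clim2 <- data.frame(c1 = shared + rnorm(n, 0, 0.2))
  geo2 <- data.frame(g1 = shared + rnorm(n, 0, 0.2))
  Yj <- shared %*% t(rnorm(m, 0, 2)) + matrix(rnorm(n * m), n, m)
  vpj <- variance_partition(Yj, clim2, geo2, n_perm = 0)
  expect_gt(vpj$joint, vpj$climate_alone)
  expect_gt(vpj$joint, vpj$geography_alone)

  ## shared column names rejected
  expect_error(variance_partition(Y, clim, data.frame(c1 = rnorm(n))),
               "disjoint")
})

test_that("outlier detection matches its Gaussian null expectation", {
  ## 10000 x 3 standard-normal loadings: expected flags
  ## 10000 * 3 * 2 * pnorm(-4) ~ 1.9, so a handful at most
  set.seed(71)
  L <- matrix(rnorm(30000), 10000, 3)
  out <- detect_outliers(L, n_axes = 3, sd_mult = 4)
  expect_lte(nrow(out), 10)
  expect_equal(dim(attr(out, "flagged")), c(10000L, 3L))
  ## the flagged attribute is consistent with an independent z computation
  zz <- scale(L)
  expect_equal(unname(which(rowSums(abs(zz) > 4) > 0)), out$snp)

  ## planted outlier is flagged on the right axis with the right z
  L2 <- matrix(rnorm(3000), 1000, 3)
  L2[500, 2] <- 10
  out2 <- detect_outliers(L2, n_axes = 3, sd_mult = 4)
  expect_true(500 %in% out2$snp)
  row <- out2[out2$snp == 500, ]
  expect_equal(row$axis, 2L)
  expect_equal(row$z, (L2[500, 2] - mean(L2[, 2])) / sd(L2[, 2]))

  ## axis-sign invariance: flipping loadings flips z but not the set
  out2f <- detect_outliers(-L2, n_axes = 3, sd_mult = 4)
  expect_equal(out2f$snp, out2$snp)
  expect_equal(out2f$z, -out2$z)

  ## infinite threshold -> no candidates
  expect_equal(nrow(detect_outliers(L2, sd_mult = Inf)), 0L)
})

test_that("candidate SNPs are assigned their most-correlated predictor", {
  set.seed(81)
  n <- 100
  P <- data.frame(BIO5 = rnorm(n), BIO15 = rnorm(n), BIO19 = rnorm(n))
  ## SNP 1 is a rescaling of BIO5 -> |r| = 1, no tie
  ## SNP 2 tracks BIO15 negatively; SNP 3 is pure noise
  Y <- cbind(2 * P$BIO5 + 7,
             -P$BIO15 + rnorm(n, 0, 0.2),
             rnorm(n))
  got <- assign_predictor(1:3, Y, P)
  expect_equal(got$predictor[1], "BIO5")
  expect_equal(got$abs_r[1], 1, tolerance = 1e-12)
  expect_false(got$tie[1])
  expect_equal(got$predictor[2], "BIO15")
  expect_lt(got$r[2], 0)
  expect_true(got$low_confidence[3] || got$abs_r[3] < 0.3)

  ## exact tie between duplicated predictors: first wins, flagged
  P2 <- data.frame(a = P$BIO5, b = P$BIO5)
  gt <- assign_predictor(1, Y, P2)
  expect_equal(gt$predictor, "a")
  expect_true(gt$tie)

  ## constant SNP warns and stays unassigned
  Yk <- cbind(rep(1, n))
  expect_warning(gk <- assign_predictor(1, Yk, P), "constant")
  expect_true(is.na(gk$predictor))
  expect_true(gk$low_confidence)
})

test_that("the RDA pipeline recovers planted adaptive SNPs", {
  fx <- tiny_sim(n_islands = 5, cells = 6, n_per_island = 18,
                 n_neutral = 300, n_adaptive = 30, effect_b = 3, seed = 97)
  clim <- sample_climate(fx$arch, fx$gm)
  keep <- select_uncorrelated_predictors(clim, 0.7)
  fit <- fit_rda(fx$gm, clim[, keep, drop = FALSE])
  out <- detect_outliers(fit, n_axes = 3, sd_mult = 3)
  ad <- which(fx$truth$type == "adaptive")
  ## enrichment: candidates hit adaptive loci far above their base rate
  expect_gt(nrow(out), 0)
  prec <- mean(out$snp %in% ad)
  expect_gt(prec, length(ad) / ncol(fx$gm$dosage) * 3)

  ## true-positive candidates point at the planted driver or one of its
  ## tight climatic proxies (island gradients are strongly collinear, so
  ## exact attribution is not identifiable; assignment runs on the full
  ## candidate climate table)
  tp <- out$snp[out$snp %in% ad]
  expect_gt(length(tp), 0)
  asg <- assign_predictor(tp, fx$gm, clim)
  proxy_r <- abs(cor(clim$BIO5, clim[, asg$predictor]))
  expect_true(all(proxy_r > 0.6))
})
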