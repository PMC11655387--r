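## Redundancy analysis: full and partial constrained ordination of dosage
## matrices on climate/geography predictors, permutation tests, variance
## partitioning, outlier candidate SNPs and most-correlated-variable
## assignment.

#' Fit a (partial) redundancy analysis
#'
#' Ordinary RDA: the SNP matrix is column-centred, predictors are
#' standardised, the multivariate least-squares fitted values are
#' decomposed by SVD, and the constrained axes are the right/left singular
#' vectors. With a `condition` set, both responses and predictors are first
#' replaced by their residuals from least squares on the conditioning
#' variables (partial RDA).
#'
#' @param gm a [genotype_matrix()] without missing entries, or a plain
#'   numeric matrix of responses.
#' @param predictors data frame or matrix of constraining variables.
#' @param condition optional data frame or matrix of conditioning
#'   variables.
#' @return an `rda_model`: list with `loadings` (SNPs x axes), `scores`
#'   (sites x axes), `eig` (non-increasing), `r2`, `adj_r2` (Ezekiel),
#'   plus the matrices needed by [permutation_test()].
#' @export
fit_rda <- function(gm, predictors, condition = NULL) {
  Y <- if (inherits(gm, "genotype_matrix")) gm$dosage else as.matrix(gm)
  if (anyNA(Y)) stop("response contains missing values; impute first")
  storage.mode(Y) <- "double"
  X <- scale(as.matrix(predictors))
  n <- nrow(Y)
  p <- ncol(X)
  q <- 0L

  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Qz <- NULL
  if (!is.null(condition)) {
    Z <- scale(as.matrix(condition))
    q <- ncol(Z)
    qrz <- qr(cbind(1, Z))
    Qz <- qr.Q(qrz)[, seq_len(qrz$rank), drop = FALSE]
    Yc <- Yc - Qz %*% crossprod(Qz, Yc)
    X <- X - Qz %*% crossprod(Qz, X)
  }
  if (n <= p + q + 1)
    stop("need more individuals than predictors plus conditions")
  kx <- kappa(crossprod(X), exact = TRUE)
  if (!is.finite(kx) || kx > 1e10)
    stop("predictors are (near-)collinear; reduce them first, e.g. with ",
         "select_uncorrelated_predictors()")

  qrx <- qr(X)
  Qx <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  Yhat <- Qx %*% crossprod(Qx, Yc)
  sv <- svd(Yhat)
  tol <- max(sv$d) * 1e-10
  keep <- which(sv$d > tol)
  d <- sv$d[keep]
  axes <- paste0("RDA", seq_along(keep))
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  colnames(loadings) <- colnames(scores) <- axes
  if (inherits(gm, "genotype_matrix") && !is.null(gm$snp_meta$id))
    rownames(loadings) <- gm$snp_meta$id

  ss_fit <- sum(Yhat^2)
  ss_tot <- sum(Yc^2)
  r2 <- ss_fit / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)

  structure(
    list(loadings = loadings, scores = scores,
         eig = d^2 / (n - 1), r2 = r2, adj_r2 = adj_r2,
         n = n, p = p, q = q,
         Y = Yc, Qx = Qx, Qz = Qz,
         predictors = colnames(as.data.frame(predictors))),
    class = "rda_model"
  )
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf(
    "rda_model: %d sites, %d response columns, %d predictors%s\n",
    x$n, nrow(x$loadings), x$p,
    if (x$q > 0) sprintf(" (conditioned on %d)", x$q) else ""
  ))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' Permutation test for an RDA model
#'
#' Pseudo-F test: `F = (SS_fit / p) / (SS_res / (n - p - q - 1))`. Rows of
#' the (conditioned) response are permuted; for partial models this is the
#' Freedman--Lane scheme, permuting the residuals of the reduced
#' (conditioning-only) model and re-residualising. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so 99 permutations bound it
#' below by 0.01.
#'
#' @param model an [fit_rda()] result.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `p`, `f_obs`, and the permuted `f_perm` values.
#' @export
permutation_test <- function(model, n_perm = 99L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  f_stat <- function(E) {
    if (!is.null(model$Qz))
      E <- E - model$Qz %*% crossprod(model$Qz, E)
    else
      E <- scale(E, center = TRUE, scale = FALSE)
    ss_fit <- sum(crossprod(model$Qx, E)^2)
    ss_tot <- sum(E^2)
    df_res <- model$n - model$p - model$q - 1
    (ss_fit / model$p) / ((ss_tot - ss_fit) / df_res)
  }
  f_obs <- f_stat(model$Y)
  f_perm <- vapply(seq_len(n_perm), function(b) {
    f_stat(model$Y[sample(model$n), , drop = FALSE])
  }, numeric(1))
  list(p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       f_obs = f_obs, f_perm = f_perm)
}

#' Partition genetic variance between climate and geography
#'
#' Adjusted-R-squared partitioning in the classic varpart style:
#' `full = adjR2(climate + geography)`,
#' `climate_alone = full - adjR2(geography)`,
#' `geography_alone = full - adjR2(climate)`,
#' `joint = full - climate_alone - geography_alone`. The joint fraction is
#' confounded and not testable by permutation; the other fractions are
#' tested with [permutation_test()] (partial models for the "alone"
#' fractions).
#'
#' @param gm response genotype matrix (imputed) or numeric matrix.
#' @param climate_preds,geo_preds disjoint predictor tables.
#' @param n_perm permutations per testable fraction (0 skips the tests).
#' @param seed RNG seed.
#' @return list with the four adjusted R-squared fractions, `proportions`
#'   of explainable variance (dividing by `full`; `NA` when `full <= 0`),
#'   and `p` per testable fraction.
#' @export
variance_partition <- function(gm, climate_preds, geo_preds,
                               n_perm = 99L, seed = 1L) {
  cn <- colnames(as.data.frame(climate_preds))
  gn <- colnames(as.data.frame(geo_preds))
  if (length(intersect(cn, gn)) > 0)
    stop("climate and geography predictor sets must be disjoint")
  both <- cbind(as.data.frame(climate_preds), as.data.frame(geo_preds))
  m_full <- fit_rda(gm, both)
  m_clim <- fit_rda(gm, climate_preds)
  m_geo <- fit_rda(gm, geo_preds)

  full <- m_full$adj_r2
  climate_alone <- full - m_geo$adj_r2
  geography_alone <- full - m_clim$adj_r2
  joint <- full - climate_alone - geography_alone

  proportions <- if (full > 0) {
    c(climate_alone = climate_alone / full,
      geography_alone = geography_alone / full,
      joint = joint / full)
  } else {
    c(climate_alone = NA_real_, geography_alone = NA_real_,
      joint = NA_real_)
  }

  p <- c(full = NA_real_, climate_alone = NA_real_,
         geography_alone = NA_real_)
  if (n_perm > 0) {
    p["full"] <- permutation_test(m_full, n_perm, child_seed(seed, 1))$p
    p["climate_alone"] <- permutation_test(
      fit_rda(gm, climate_preds, condition = geo_preds),
      n_perm, child_seed(seed, 2))$p
    p["geography_alone"] <- permutation_test(
      fit_rda(gm, geo_preds, condition = climate_preds),
      n_perm, child_seed(seed, 3))$p
  }

  list(full = full, climate_alone = climate_alone,
       geography_alone = geography_alone, joint = joint,
       proportions = proportions, p = p,
       models = list(full = m_full, climate = m_clim, geography = m_geo))
}

#' Detect outlier (candidate) SNPs on the leading RDA axes
#'
#' A SNP is a candidate when its loading on any of the first `n_axes`
#' constrained axes lies more than `sd_mult` standard deviations from that
#' axis's mean loading.
#'
#' @param model an [fit_rda()] result, or a plain SNPs x axes loading
#'   matrix.
#' @param n_axes number of leading axes scanned.
#' @param sd_mult the SD multiple defining an outlier.
#' @return data frame with one row per candidate: `snp` (index), `id`,
#'   `axis` (the axis with the largest |z|), `z`, and a logical matrix
#'   attribute `"flagged"` of per-axis flags.
#' @export
detect_outliers <- function(model, n_axes = 3L, sd_mult = 4) {
  L <- if (inherits(model, "rda_model")) model$loadings else as.matrix(model)
  n_axes <- min(n_axes, ncol(L))
  if (n_axes < 1) stop("model has no axes")
  Z <- matrix(NA_real_, nrow(L), n_axes)
  for (k in seq_len(n_axes)) {
    mu <- mean(L[, k]); s <- sd(L[, k])
    if (!is.finite(s) || s == 0) {
      warning("axis ", k, " has zero loading SD; skipped")
      Z[, k] <- 0
      next
    }
    Z[, k] <- (L[, k] - mu) / s
  }
  flagged <- abs(Z) > sd_mult
  hit <- which(rowSums(flagged, na.rm = TRUE) > 0)
  best <- apply(abs(Z[hit, , drop = FALSE]), 1, which.max)
  ids <- rownames(L)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(L)))
  out <- data.frame(
    snp = hit,
    id = ids[hit],
    axis = as.integer(best),
    z = Z[cbind(hit, best)],
    stringsAsFactors = FALSE
  )
  attr(out, "flagged") <- flagged
  attr(out, "sd_mult") <- sd_mult
  out
}

#' Assign each candidate SNP its most-correlated predictor
#'
#' @param candidates data frame from [detect_outliers()] (needs a `snp`
#'   column of indices), or an integer vector of SNP indices.
#' @param gm imputed [genotype_matrix()] (or numeric matrix) the
#'   candidates index into.
#' @param predictors data frame of predictors in declared priority order
#'   (ties are assigned to the earlier predictor and flagged).
#' @return data frame: `snp`, `predictor`, `r`, `abs_r`, `tie`,
#'   `low_confidence` (|r| < 0.1).
#' @export
assign_predictor <- function(candidates, gm, predictors) {
  idx <- if (is.data.frame(candidates)) candidates$snp else as.integer(candidates)
  Y <- if (inherits(gm, "genotype_matrix")) gm$dosage else as.matrix(gm)
  P <- as.matrix(predictors)
  pn <- colnames(P)
  out <- lapply(idx, function(j) {
    d <- Y[, j]
    if (var(d) == 0) {
      warning("SNP ", j, " has constant dosage; unassigned")
      return(data.frame(snp = j, predictor = NA_character_, r = NA_real_,
                        abs_r = NA_real_, tie = FALSE,
                        low_confidence = TRUE))
    }
    r <- suppressWarnings(as.vector(cor(d, P)))
    r[!is.finite(r)] <- 0
    a <- abs(r)
    best <- which.max(a)                      # first wins on exact ties
    tie <- sum(a == a[best]) > 1
    data.frame(snp = j, predictor = pn[best], r = r[best],
               abs_r = a[best], tie = tie,
               low_confidence = a[best] < 0.1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
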