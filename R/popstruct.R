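## Genome-wide structure summaries: Weir-Cockerham F_ST with SD bands,
## genotype PCA, identity-by-state distances, isolation-by-distance fits,
## and ancestry-group designation from an ADMIXTURE-style Q matrix.

#' Pairwise Weir--Cockerham F_ST
#'
#' Variance-components estimator of differentiation for every pair of
#' groups. The multi-locus estimate is the ratio of averages
#' `sum(a) / sum(a + b + c)` over usable loci; the spread across loci is
#' reported as the sample SD of per-locus theta, giving the one-SD band
#' (which may dip below zero -- negative values carry no biological meaning
#' beyond "indistinguishable from zero").
#'
#' @param gm a [genotype_matrix()].
#' @param groups vector of group labels, one per individual.
#' @return list with `pairs`, a data frame (group1, group2, theta, sd,
#'   lower, upper, n_loci_used, n_excluded), `overall`, the analogous
#'   one-row multi-group estimate over all groups at once, and
#'   `per_locus`, a list of per-pair data frames of a/b/c components and
#'   per-locus theta.
#' @export
wc_fst <- function(gm, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(gm$dosage))
    stop("groups must have one label per individual")
  labs <- unique(groups)
  if (length(labs) < 2) stop("need at least two groups")
  split_dos <- lapply(labs, function(g)
    gm$dosage[groups == g, , drop = FALSE])
  names(split_dos) <- labs

  summarise <- function(comp) {
    usable <- comp$usable
    theta_multi <- sum(comp$a[usable]) /
      sum((comp$a + comp$b + comp$c)[usable])
    s <- sd(comp$theta[usable])
    data.frame(theta = theta_multi, sd = s,
               lower = theta_multi - s, upper = theta_multi + s,
               n_loci_used = sum(usable), n_excluded = sum(!usable))
  }

  combs <- utils::combn(labs, 2)
  pairs <- vector("list", ncol(combs))
  per_locus <- vector("list", ncol(combs))
  for (k in seq_len(ncol(combs))) {
    g1 <- combs[1, k]; g2 <- combs[2, k]
    comp <- wc_components(split_dos[[g1]], split_dos[[g2]])
    pairs[[k]] <- cbind(data.frame(group1 = g1, group2 = g2,
                                   stringsAsFactors = FALSE),
                        summarise(comp))
    per_locus[[k]] <- data.frame(
      a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
      usable = comp$usable
    )
    names(per_locus)[k] <- paste(g1, g2, sep = "~")
  }
  overall <- summarise(do.call(wc_components, unname(split_dos)))
  list(pairs = do.call(rbind, pairs), overall = overall,
       per_locus = per_locus)
}

## Weir & Cockerham (1984) a, b, c variance components per locus for r
## samples of dosage rows (one matrix per group). Loci with < 2 non-missing
## genotypes in any group, or monomorphic across all groups, are unusable.
wc_components <- function(...) {
  mats <- list(...)
  r <- length(mats)
  n <- sapply(mats, function(m) colSums(!is.na(m)))       # loci x r
  p <- sapply(mats, function(m) colMeans(m, na.rm = TRUE) / 2)
  h <- sapply(mats, function(m) colMeans(m == 1, na.rm = TRUE))
  if (is.null(dim(n))) { n <- rbind(n); p <- rbind(p); h <- rbind(h) }
  nsum <- rowSums(n)
  nbar <- nsum / r
  nc <- (nsum - rowSums(n^2) / nsum) / (r - 1)
  pbar <- rowSums(n * p) / nsum
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  denom <- a + b + c_
  usable <- apply(n >= 2, 1, all) & pbar > 0 & pbar < 1 &
    is.finite(denom) & denom > 0
  theta <- ifelse(usable, a / denom, NA_real_)
  list(a = a, b = b, c = c_, theta = theta, usable = usable)
}

#' PCA of an imputed genotype matrix
#'
#' @param gm a [genotype_matrix()] with no missing entries (see
#'   [impute_mode()]).
#' @param n_axes number of axes to return.
#' @return list with `scores` (individuals x axes), `explained`
#'   (per-axis fraction of total variance), `sdev`.
#' @export
pca_genotypes <- function(gm, n_axes = 10L) {
  dos <- gm$dosage
  if (anyNA(dos)) stop("genotypes contain missing values; impute first")
  pc <- prcomp(dos, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_axes > rank) {
    warning("requested ", n_axes, " axes but rank is ", rank,
            "; truncating")
    n_axes <- rank
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = pc$x[, seq_len(n_axes), drop = FALSE],
    explained = explained[seq_len(n_axes)],
    sdev = pc$sdev[seq_len(n_axes)]
  )
}

#' Identity-by-state genetic distance
#'
#' Proportion of allele mismatches between two individuals over their
#' shared non-missing SNPs: `d = mismatching alleles / (2 x shared SNPs)`,
#' so identical genotypes give 0 and opposite homozygotes give 1.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric individuals x individuals matrix with zero diagonal;
#'   pairs sharing no non-missing SNP are `NA` (with a warning).
#' @export
ibs_distance <- function(gm) {
  dos <- gm$dosage
  if (nrow(dos) < 2) stop("need at least two individuals")
  M <- !is.na(dos)
  A <- lapply(0:2, function(k) {
    z <- dos == k; z[is.na(z)] <- FALSE; storage.mode(z) <- "double"; z
  })
  mism <- A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[1]]) +
    A[[2]] %*% t(A[[3]]) + A[[3]] %*% t(A[[2]]) +
    2 * (A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]]))
  shared <- (M + 0) %*% t(M + 0)
  d <- mism / (2 * shared)
  if (any(shared == 0 & row(shared) != col(shared))) {
    warning("some pairs share no non-missing SNPs; distance set to NA")
  }
  d[shared == 0] <- NA
  diag(d) <- 0
  rownames(d) <- colnames(d) <- gm$sample_meta$id
  d
}

#' Isolation-by-distance fit
#'
#' Fits a four-parameter sigmoid
#' `d_gen = c + L / (1 + exp(-k (d_geo - x0)))` to all pairwise distances
#' by least squares and reports adjusted R-squared together with a
#' Mantel-style permutation p-value (pairs of individuals are not
#' independent, so ordinary regression p-values would be anti-conservative).
#'
#' @param genetic_d square genetic distance matrix (e.g. [ibs_distance()]).
#' @param geographic_km square geographic distance matrix in km.
#' @param n_perm permutations for the Mantel-style test.
#' @param seed RNG seed for the permutations.
#' @return list with `params` (L, k, x0, c), `adj_r2`, `p`, `fitted`
#'   function of distance, and `fallback` (TRUE when the sigmoid failed to
#'   converge and a monotone regression was used instead).
#' @export
fit_ibd <- function(genetic_d, geographic_km, n_perm = 99L, seed = 1L) {
  genetic_d <- as.matrix(genetic_d)
  geographic_km <- as.matrix(geographic_km)
  stopifnot(all(dim(genetic_d) == dim(geographic_km)))
  lt <- lower.tri(genetic_d)
  y <- genetic_d[lt]
  x <- geographic_km[lt]
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)

  fallback <- FALSE
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ cc + L / (1 + exp(-k * (x - x0))),
      start = list(L = max(y) - min(y), k = 4 / max(sd(x), 1e-9),
                   x0 = median(x), cc = min(y)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fallback <- TRUE
    iso <- stats::isoreg(x, y)
    yhat <- iso$yf[order(order(x))]
    params <- NULL
    fitted_fun <- stats::approxfun(sort(x), iso$yf, rule = 2)
    p_fit <- 3   # effective parameters for the adjusted R2, nominal
  } else {
    params <- coef(fit)
    yhat <- fitted(fit)
    fitted_fun <- function(d) {
      params[["cc"]] + params[["L"]] /
        (1 + exp(-params[["k"]] * (d - params[["x0"]])))
    }
    p_fit <- 4
  }
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p_fit - 1)

  ## Mantel-style permutation: shuffle individuals jointly in the genetic
  ## matrix, score by |correlation| between distance vectors
  set.seed(seed)
  obs <- suppressWarnings(cor(y, x))
  if (!is.finite(obs)) obs <- 0
  n_ind <- nrow(genetic_d)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(n_ind)
    yp <- genetic_d[perm, perm][lt][ok]
    rp <- suppressWarnings(cor(yp, x))
    if (!is.finite(rp)) rp <- 0
    if (abs(rp) >= abs(obs)) ge <- ge + 1L
  }
  p <- (1 + ge) / (1 + n_perm)

  list(params = params, adj_r2 = adj_r2, p = p, fitted = fitted_fun,
       fallback = fallback, n_pairs = n)
}

#' Read an ADMIXTURE-style Q matrix
#'
#' @param path whitespace-delimited file, one row per individual, one
#'   column per ancestry group.
#' @return numeric matrix of ancestry fractions.
#' @export
read_qmatrix <- function(path) {
  q <- as.matrix(read.table(path, header = FALSE))
  colnames(q) <- paste0("K", seq_len(ncol(q)))
  q
}

#' Designate ancestry groups from a Q matrix
#'
#' An individual is assigned to the group holding at least `threshold` of
#' its ancestry (inclusive), otherwise labelled `"hybrid"`.
#'
#' @param q matrix of ancestry fractions, rows summing to one.
#' @param threshold assignment threshold.
#' @param labels group labels, one per Q column.
#' @return character vector of labels.
#' @export
assign_groups <- function(q, threshold = 0.9, labels = colnames(q)) {
  q <- as.matrix(q)
  if (is.null(labels)) labels <- paste0("K", seq_len(ncol(q)))
  if (length(labels) != ncol(q))
    stop("labels must match the number of Q columns")
  bad <- abs(rowSums(q) - 1) > 1e-3
  if (any(bad))
    stop("Q rows not summing to 1: ",
         paste(which(bad), collapse = ", "))
  top <- max.col(q, ties.method = "first")
  ifelse(q[cbind(seq_len(nrow(q)), top)] >= threshold,
         labels[top], "hybrid")
}
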