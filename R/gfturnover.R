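## Gradient-forest core: per-SNP regression forests, R2-weighted cumulative
## split-importance turnover functions, and transformation of climate
## tables into "genomic-scaled" space.

#' Gradient-forest parameters
#'
#' @param ntree trees per SNP forest.
#' @param corr_threshold predictor correlation above which a note is
#'   emitted (impurity importances of correlated predictors can be
#'   inflated; see the methods vignette).
#' @param max_level maximum tree depth; `NULL` computes it from the sample
#'   size via [max_level_rule()].
#' @param nbins equal-frequency bins per predictor for the cumulative
#'   importance curves (>= 10).
#' @param min_r2 minimum out-of-bag R-squared for a SNP to contribute
#'   (strictly greater than; 0 keeps the positive-R2 convention).
#' @param seed integer seed; fans out deterministically to per-SNP forests.
#' @return list of class `gf_params`.
#' @export
gf_params <- function(ntree = 500L, corr_threshold = 0.5,
                      max_level = NULL, nbins = 50L, min_r2 = 0,
                      seed = 1L) {
  if (ntree < 1) stop("ntree must be >= 1")
  if (nbins < 10) stop("nbins must be >= 10")
  if (!is.null(max_level) && max_level < 1) stop("max_level must be >= 1")
  structure(list(ntree = as.integer(ntree),
                 corr_threshold = corr_threshold,
                 max_level = max_level, nbins = as.integer(nbins),
                 min_r2 = min_r2, seed = as.integer(seed)),
            class = "gf_params")
}

#' Tree-depth rule from the sample size
#'
#' `max_level = log2(0.368 * n / 2)`, rounded to the nearest integer
#' (`rounding = "floor"` for the conservative alternative) and floored at
#' one.
#'
#' @param n_samples number of individuals (>= 12).
#' @param rounding `"round"` or `"floor"`.
#' @return integer depth.
#' @export
max_level_rule <- function(n_samples, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (n_samples < 12) stop("need at least 12 samples for the depth rule")
  lev <- log2(0.368 * n_samples / 2)
  lev <- if (rounding == "round") round(lev) else floor(lev)
  max(1L, as.integer(lev))
}

#' Fit a gradient-forest turnover model
#'
#' Fits one regression forest per SNP (dosage on the predictor table),
#' keeps SNPs with positive out-of-bag R-squared, and accumulates every
#' split's impurity improvement into equal-frequency bins of the split
#' predictor. Each SNP's binned importance is scaled so that its total
#' equals its out-of-bag R-squared (distributed over predictors by their
#' share of the SNP's raw split importance); bins are then averaged over
#' contributing SNPs and cumulated, giving one non-decreasing turnover
#' function `f_v` per predictor with `f_v(min) = 0` and
#' `f_v(max) = overall importance of v`.
#'
#' @param gm imputed [genotype_matrix()] (or numeric dosage matrix).
#' @param predictors_table data frame of climate (and optionally PCNM)
#'   predictors, one row per individual.
#' @param params a [gf_params()] list.
#' @return a `turnover_model`: `functions` (per predictor: bin upper
#'   edges, cumulative importance, observed range), `importance` (named,
#'   decreasing), `r2` (per-SNP out-of-bag R-squared), `n_included`,
#'   `predictors`, `params`.
#' @export
fit_gf <- function(gm, predictors_table, params = gf_params()) {
  Y <- if (inherits(gm, "genotype_matrix")) gm$dosage else as.matrix(gm)
  if (anyNA(Y)) stop("dosages contain missing values; impute first")
  X <- as.matrix(predictors_table)
  if (anyNA(X)) stop("predictors contain missing values")
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("genotypes and predictors disagree in rows")
  preds <- colnames(X)
  if (is.null(preds)) stop("predictors must be named")

  cc <- abs(cor(X))
  diag(cc) <- 0
  if (any(cc > params$corr_threshold, na.rm = TRUE)) {
    pr <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    message("predictors ", preds[pr[1]], " and ", preds[pr[2]],
            sprintf(" correlate at %.2f (> %.2f); impurity importances may be inflated",
                    max(cc), params$corr_threshold))
  }

  max_depth <- if (is.null(params$max_level)) max_level_rule(n)
               else as.integer(params$max_level)
  mtry <- max(1L, floor(p / 3))
  nb <- params$nbins

  ## equal-frequency bin edges per predictor
  edges <- lapply(seq_len(p), function(j) {
    e <- unique(quantile(X[, j], probs = seq(0, 1, length.out = nb + 1),
                         names = FALSE))
    if (length(e) < 2) e <- range(X[, j]) + c(0, 1e-12)
    e
  })
  names(edges) <- preds

  binned <- lapply(edges, function(e) numeric(length(e) - 1))
  r2 <- numeric(ncol(Y))
  n_included <- 0L
  vy_all <- apply(Y, 2, var)

  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (vy_all[j] == 0) { r2[j] <- NA_real_; next }
    fr <- .fit_regression_forest(X, y, params$ntree, max_depth, mtry, 5L,
                                 child_seed(params$seed, j))
    got <- fr$oob_count > 0
    if (!any(got)) { r2[j] <- NA_real_; next }
    pred <- fr$oob_sum[got] / fr$oob_count[got]
    mse <- mean((y[got] - pred)^2)
    vy <- mean((y - mean(y))^2)
    r2[j] <- 1 - mse / vy
    tot_gain <- sum(fr$split_gain)
    if (r2[j] <= params$min_r2 || tot_gain <= 0) next
    n_included <- n_included + 1L
    sc <- r2[j] / tot_gain   # rescales all gains so they sum to oob R2
    for (v in unique(fr$split_var)) {
      sel <- fr$split_var == v
      b <- findInterval(fr$split_value[sel], edges[[v]],
                        all.inside = TRUE)
      add <- tapply(fr$split_gain[sel] * sc, b, sum)
      binned[[v]][as.integer(names(add))] <-
        binned[[v]][as.integer(names(add))] + add
    }
  }
  if (n_included == 0L) stop("no predictive loci (no SNP with positive out-of-bag R2)")

  functions <- lapply(seq_len(p), function(v) {
    bv <- binned[[v]] / n_included
    list(upper = edges[[v]][-1], cum = cumsum(bv),
         range = range(X[, v]))
  })
  names(functions) <- preds
  importance <- vapply(functions, function(f) f$cum[length(f$cum)],
                       numeric(1))
  structure(
    list(functions = functions,
         importance = sort(importance, decreasing = TRUE),
         r2 = r2, n_included = n_included,
         predictors = preds, params = params,
         model_id = sprintf("gf-%d-%d", ncol(Y), params$seed)),
    class = "turnover_model"
  )
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf(
    "turnover_model: %d predictors, %d/%d SNPs with positive out-of-bag R2\n",
    length(x$predictors), x$n_included, length(x$r2)))
  cat("overall importance:\n")
  print(round(x$importance, 5))
  invisible(x)
}

#' Evaluate a turnover function
#'
#' Step-function value of cumulative importance at `x` for predictor `v`;
#' flat (clamped) beyond the training range.
#'
#' @param model a [fit_gf()] model.
#' @param v predictor name.
#' @param x numeric values.
#' @return cumulative importance values, same length as `x`.
#' @export
turnover_at <- function(model, v, x) {
  f <- model$functions[[v]]
  if (is.null(f)) stop("predictor ", v, " absent from model")
  x <- pmin(pmax(x, f$range[1]), f$range[2])
  c(0, f$cum)[findInterval(x, f$upper) + 1]
}

#' Transform climate rows into genomic-scaled space
#'
#' @param model a [fit_gf()] model.
#' @param climate_rows data frame or matrix containing every predictor in
#'   `use_predictors`; values outside the training range are clamped.
#' @param use_predictors predictor subset (default: all in the model).
#' @return numeric matrix, rows x predictors, of cumulative-importance
#'   coordinates.
#' @export
gf_transform <- function(model, climate_rows, use_predictors = NULL) {
  if (is.null(use_predictors)) use_predictors <- model$predictors
  missing_p <- setdiff(use_predictors, model$predictors)
  if (length(missing_p))
    stop("predictor(s) absent from model: ",
         paste(missing_p, collapse = ", "))
  C <- as.data.frame(climate_rows)
  absent <- setdiff(use_predictors, names(C))
  if (length(absent))
    stop("climate rows lack predictor(s): ", paste(absent, collapse = ", "))
  out <- vapply(use_predictors, function(v) turnover_at(model, v, C[[v]]),
                numeric(nrow(C)))
  if (nrow(C) == 1) out <- matrix(out, nrow = 1,
                                  dimnames = list(NULL, use_predictors))
  rownames(out) <- rownames(climate_rows)
  out
}

#' Serialize / restore a turnover model
#'
#' The step functions and metadata are written as portable JSON so a model
#' can be reused across sessions without binary files.
#'
#' @param model a [fit_gf()] model.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_gf <- function(model, path) {
  payload <- list(
    predictors = model$predictors,
    importance = as.list(model$importance),
    n_included = model$n_included,
    model_id = model$model_id,
    functions = lapply(model$functions, function(f)
      list(upper = f$upper, cum = f$cum, range = f$range))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gf
#' @export
read_gf <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  functions <- lapply(payload$functions, function(f)
    list(upper = as.numeric(f$upper), cum = as.numeric(f$cum),
         range = as.numeric(f$range)))
  structure(
    list(functions = functions,
         importance = unlist(payload$importance),
         r2 = NULL, n_included = payload$n_included,
         predictors = payload$predictors,
         params = NULL, model_id = payload$model_id),
    class = "turnover_model"
  )
}
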