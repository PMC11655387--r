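## Turnover visualisation surfaces: PCA -> RGB colouring of transformed
## climate grids, and Procrustes residuals between two turnover maps.

#' Colour a transformed grid by its leading principal components
#'
#' PCA of the genomic-scaled cell vectors; the first three PCs are
#' min--max rescaled to 0--255 and combined into an RGB triplet per cell,
#' so cells with similar predicted genomic composition receive similar
#' colours. Degenerate dimensions are padded with zero channels.
#'
#' @param transformed_grid cells x predictors matrix from
#'   [gf_transform()].
#' @return a `turnover_map`: `pcs` (cells x 3), `rgb` (cells x 3 integer,
#'   0--255), `hex` (per-cell colour string), `explained`.
#' @export
pc_rgb <- function(transformed_grid) {
  X <- as.matrix(transformed_grid)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    warning("constant transformed grid: single colour")
    pcs <- matrix(0, n, 3)
  } else {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(3, sum(pc$sdev > pc$sdev[1] * 1e-10))
    pcs <- cbind(pc$x[, seq_len(k), drop = FALSE],
                 matrix(0, n, 3 - k))
  }
  colnames(pcs) <- paste0("PC", 1:3)
  channel <- apply(pcs, 2, function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) rep(127L, length(v))
    else as.integer(round(255 * (v - r[1]) / diff(r)))
  })
  if (n == 1) channel <- matrix(channel, nrow = 1)
  colnames(channel) <- c("R", "G", "B")
  structure(
    list(pcs = pcs, rgb = channel,
         hex = grDevices::rgb(channel[, 1], channel[, 2], channel[, 3],
                              maxColorValue = 255),
         explained = if (exists("pc", inherits = FALSE))
           pc$sdev^2 / sum(pc$sdev^2) else NULL),
    class = "turnover_map"
  )
}

#' Procrustes residuals between two turnover maps
#'
#' Superimposes the second map's three-PC configuration onto the first by
#' least-squares translation, rotation and uniform scaling, and returns
#' the per-cell distance after superposition -- the classic way to map
#' where genome-wide and candidate-SNP turnover predictions disagree.
#'
#' @param map_a,map_b [pc_rgb()] objects (or plain cells x k coordinate
#'   matrices) over the same cells.
#' @return list with `residuals` (per-cell, >= 0), `rotation`, `scale`,
#'   `ss` (residual sum of squares).
#' @export
procrustes_residuals <- function(map_a, map_b) {
  A <- if (inherits(map_a, "turnover_map")) map_a$pcs else as.matrix(map_a)
  B <- if (inherits(map_b, "turnover_map")) map_b$pcs else as.matrix(map_b)
  if (nrow(A) != nrow(B)) stop("maps must cover the same cells")
  if (nrow(A) < 3) stop("need at least three cells")
  if (ncol(A) != ncol(B)) {
    k <- min(ncol(A), ncol(B))
    A <- A[, seq_len(k), drop = FALSE]
    B <- B[, seq_len(k), drop = FALSE]
  }
  Ac <- scale(A, center = TRUE, scale = FALSE)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  M <- crossprod(Bc, Ac)
  sv <- svd(M)
  if (sum(sv$d) <= 1e-14 * nrow(A))
    stop("rank-deficient configuration: Procrustes fit undefined")
  R <- sv$u %*% t(sv$v)
  ssb <- sum(Bc^2)
  if (ssb == 0) stop("rank-deficient configuration: Procrustes fit undefined")
  s <- sum(sv$d) / ssb
  fit <- s * Bc %*% R
  res <- sqrt(rowSums((Ac - fit)^2))
  names(res) <- rownames(A)
  list(residuals = res, rotation = R, scale = s, ss = sum((Ac - fit)^2))
}
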