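## Principal coordinates of neighbour matrices (PCNM): spatial eigenvectors
## used as geography proxies in gradient-forest models.

#' PCNM spatial eigenvectors
#'
#' Builds the pairwise distance matrix (haversine km for lon/lat, plane
#' Euclidean otherwise), replaces distances beyond the truncation distance
#' `t` with `4 t`, and runs a principal coordinates analysis: eigen-
#' decomposition of the Gower-double-centred `-0.5 * D'^2`. Axes with
#' positive eigenvalues are returned, scaled by the square root of their
#' eigenvalue.
#'
#' @param coords two-column matrix of site coordinates; `(x, y)` in km, or
#'   `(lon, lat)` with `lonlat = TRUE`.
#' @param truncation_km truncation distance `t` in km (> 0).
#' @param lonlat treat coordinates as lon/lat and use haversine distances.
#' @return a `pcnm_axes` object: `vectors` (sites x axes, columns
#'   `PCNM1..k`), `values` (positive eigenvalues, decreasing),
#'   `truncation_km`, and `n_positive`.
#' @export
pcnm <- function(coords, truncation_km, lonlat = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least three sites")
  if (truncation_km <= 0) stop("truncation_km must be positive")
  D <- coord_dist_km(coords, lonlat = lonlat)
  if (max(D) == 0) stop("all coordinates identical: no spatial structure")
  Dt <- D
  Dt[Dt > truncation_km] <- 4 * truncation_km
  A <- -0.5 * Dt^2
  n <- nrow(A)
  ## Gower double-centring
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values))
  pos <- which(e$values > tol)
  if (length(pos) == 0) stop("no positive eigenvalues")
  vec <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  colnames(vec) <- paste0("PCNM", seq_along(pos))
  rownames(vec) <- rownames(coords)
  structure(
    list(vectors = vec, values = e$values[pos],
         truncation_km = truncation_km, n_positive = length(pos)),
    class = "pcnm_axes"
  )
}

#' @export
print.pcnm_axes <- function(x, ...) {
  cat(sprintf("pcnm_axes: %d positive axes (truncation %.1f km)\n",
              x$n_positive, x$truncation_km))
  invisible(x)
}

#' Retain the first half of the positive PCNM axes
#'
#' The broad-scale (leading) half of the positive-eigenvalue axes is kept
#' as the geographic proxy; these denote positive spatial correlation.
#'
#' @param axes a [pcnm()] result.
#' @param halving `"floor"` (default) or `"ceiling"` convention for an odd
#'   number of positive axes.
#' @return a `pcnm_axes` object restricted to the retained axes, with
#'   `n_retained` recorded.
#' @export
retain_half_positive <- function(axes, halving = c("floor", "ceiling")) {
  halving <- match.arg(halving)
  if (axes$n_positive < 1) stop("no positive eigenvalues to halve")
  k <- if (halving == "floor") floor(axes$n_positive / 2)
       else ceiling(axes$n_positive / 2)
  k <- max(k, 1L)
  out <- axes
  out$vectors <- axes$vectors[, seq_len(k), drop = FALSE]
  out$values <- axes$values[seq_len(k)]
  out$n_retained <- k
  out
}
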