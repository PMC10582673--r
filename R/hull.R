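# Convex hull boundary measures without external geometry libraries.
#
# The disparity index needs the boundary measure of the convex hull of PC
# scores: segment length in 1-D, perimeter in 2-D (grDevices::chull),
# surface area in 3-D (incremental hull below). For more than three axes
# the hull is evaluated on the three highest-variance axes and flagged;
# the sum-of-ranges index always uses all axes.

hull_perimeter_2d <- function(P) {
  h <- grDevices::chull(P[, 1], P[, 2])
  v <- P[h, , drop = FALSE]
  sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), , drop = FALSE])^2)))
}

tri_normal <- function(V, f) {
  a <- V[f[2], ] - V[f[1], ]
  b <- V[f[3], ] - V[f[1], ]
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

hull_area_3d <- function(P, eps_frac = 1e-10) {
  n <- nrow(P)
  stopifnot(n >= 4L)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  eps <- eps_frac * scale  # visibility tolerance relative to extent

  # initial extreme tetrahedron
  i1 <- which.min(P[, 1])
  i2 <- which.max(rowSums(sweep(P, 2, P[i1, ])^2))
  ab <- P[i2, ] - P[i1, ]
  d3 <- {
    rel <- sweep(P, 2, P[i1, ])
    cr <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
                rel[, 3] * ab[1] - rel[, 1] * ab[3],
                rel[, 1] * ab[2] - rel[, 2] * ab[1])
    sqrt(rowSums(cr^2))
  }
  i3 <- which.max(d3)
  nrm <- tri_normal(P, c(i1, i2, i3))
  d4 <- abs(as.numeric(sweep(P, 2, P[i1, ]) %*% nrm))
  i4 <- which.max(d4)
  if (d4[i4] <= eps * sqrt(sum(nrm^2))) abort("degenerate 3D point set")

  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i2, i3, i4), c(i3, i1, i4))
  ctr <- colMeans(P[c(i1, i2, i3, i4), , drop = FALSE])
  faces <- lapply(faces, function(f) {
    if (sum(tri_normal(P, f) * (ctr - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
  })

  visible <- function(f, p) {
    nrm <- tri_normal(P, f)
    sum(nrm * (P[p, ] - P[f[1], ])) > eps * sqrt(sum(nrm^2))
  }

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(faces, visible, TRUE, p = p)
    if (!any(vis)) next
    vis_faces <- faces[vis]
    keep_faces <- faces[!vis]
    # horizon: directed edges of visible faces whose reverse edge is not
    # itself in the visible set
    edges <- do.call(rbind, lapply(vis_faces, function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    ek <- paste(edges[, 1], edges[, 2])
    rk <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rk %in% ek), , drop = FALSE]
    new_faces <- lapply(seq_len(nrow(horizon)), function(r)
      c(horizon[r, 1], horizon[r, 2], p))
    faces <- c(keep_faces, new_faces)
  }
  sum(vapply(faces, function(f) {
    0.5 * sqrt(sum(tri_normal(P, f)^2))
  }, 1.0))
}

#' Convex hull boundary measure of a point configuration
#'
#' Boundary measure of the exact convex hull in the affine span of the
#' points: twice nothing in 0-D, segment length in 1-D, perimeter in 2-D,
#' surface area in 3-D. Configurations spanning more than three dimensions
#' are measured on their three highest-variance principal directions and
#' flagged (`projected = TRUE`). Degenerate (lower-rank) configurations are
#' measured in their affine span with the rank reported.
#'
#' @param points an `n x d` numeric matrix.
#' @param rank_tol relative singular-value tolerance for the affine rank.
#' @return List with `measure`, `dim_used`, `rank`, `projected`.
#' @export
hull_measure <- function(points, rank_tol = 1e-9) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 2L) return(list(measure = 0, dim_used = 0L, rank = 0L,
                          projected = FALSE))
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)
  rank <- sum(sv$d > rank_tol * max(sv$d, .Machine$double.eps))
  projected <- rank > 3L
  dim_used <- min(rank, 3L)
  if (dim_used == 0L)
    return(list(measure = 0, dim_used = 0L, rank = 0L, projected = FALSE))
  Q <- Pc %*% sv$v[, seq_len(dim_used), drop = FALSE]
  measure <- switch(dim_used,
                    diff(range(Q[, 1])),
                    hull_perimeter_2d(Q),
                    hull_area_3d(Q))
  list(measure = measure, dim_used = dim_used, rank = rank,
       projected = projected)
}
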