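# Shared fixtures and independent oracles, built in code at test time.

# circle contour of n points, CCW from (r, 0)
circle_contour <- function(n = 1024L, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(th), r * sin(th))
}

ellipse_contour <- function(n = 1024L, a = 2, b = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(a * cos(th), b * sin(th))
}

# independent oracle: Fourier coefficients of the arc-length parametrized
# axis-aligned ellipse, by adaptive quadrature (no shared code with efd())
ellipse_efd_oracle <- function(a = 2, b = 1, harmonics = 1:3) {
  sp <- function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  S <- stats::integrate(sp, 0, 2 * pi, rel.tol = 1e-12)$value
  s_of <- function(th) vapply(th, function(u)
    stats::integrate(sp, 0, u, rel.tol = 1e-12)$value, 1.0)
  fcoef <- function(fun, n, trig) {
    f <- function(th) fun(th) * trig(2 * pi * n * s_of(th) / S) * sp(th)
    2 / S * stats::integrate(f, 0, 2 * pi, rel.tol = 1e-10,
                             subdivisions = 400L)$value
  }
  t(vapply(harmonics, function(n) c(
    a = fcoef(function(t) a * cos(t), n, cos),
    b = fcoef(function(t) a * cos(t), n, sin),
    c = fcoef(function(t) b * sin(t), n, cos),
    d = fcoef(function(t) b * sin(t), n, sin)), c(a = 1, b = 1, c = 1, d = 1)))
}

# brute-force nearest neighbour (R oracle, independent of the kd-tree)
nn_brute <- function(query, ref) {
  idx <- integer(nrow(query))
  d <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- colSums((t(ref) - query[i, ])^2)
    idx[i] <- which.min(dd)
    d[i] <- sqrt(dd[idx[i]])
  }
  list(idx = idx, dist = d)
}

# brute-force point-to-triangle distance (for Hausdorff oracles)
point_tri_dist <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A; ap <- p - A
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - B
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((ap - v * ab)^2)))
  }
  cp <- p - C
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((ap - w * ac)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (B + w * (C - B)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (A + ab * v + ac * w))^2))
}

points_to_mesh_dist <- function(points, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    # prune with vertex distances first
    dv <- sqrt(colSums((t(V) - p)^2))
    near <- which(dv[F[, 1]] <= min(dv) + max_edge_len(mesh))
    min(vapply(near, function(fi)
      point_tri_dist(p, V[F[fi, 1], ], V[F[fi, 2], ], V[F[fi, 3], ]), 1.0))
  }, 1.0)
}

max_edge_len <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  max(sqrt(rowSums((V[F[, 1], ] - V[F[, 2], ])^2)),
      sqrt(rowSums((V[F[, 2], ] - V[F[, 3], ])^2)),
      sqrt(rowSums((V[F[, 3], ] - V[F[, 1], ])^2)))
}

# polygon simplicity for star-shaped outlines: vertex angles strictly
# increasing (mod 2*pi) around the centroid
is_star_simple <- function(p) {
  q <- sweep(p, 2, colMeans(p))
  th <- atan2(q[, 2], q[, 1])
  d <- diff(c(th, th[1] + 2 * pi))
  all((d %% (2 * pi)) < pi) && abs(sum(d %% (2 * pi)) - 2 * pi) < 1e-6
}

# tiny two-species design
tiny_design <- function(n_per = 3L) {
  sp <- c("A_sp", "B_sp")
  rows <- expand.grid(species = sp, sex = c("female", "male"),
                      idx = seq_len(n_per), stringsAsFactors = FALSE)
  tibble::tibble(
    specimen_id = sprintf("%s_%s_%d", rows$species, substr(rows$sex, 1, 1),
                          rows$idx),
    species = rows$species,
    sex = rows$sex,
    strategy = ifelse(rows$species == "A_sp", "pelvic", "transfer"),
    standard_length = 30 + rows$idx,
    side = "right")
}

two_species_tree <- function() {
  ape::read.tree(text = "(A_sp:0.5,B_sp:0.5);")
}

# random proper rotation (R oracle, independent of package internals)
rand_rot3 <- function() {
  repeat {
    q <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(R) > 0) return(R)
  }
}

expect_silent_psm_trace <- function(trace) {
  testthat::expect_true(all(diff(trace) <= 1e-12))
}
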