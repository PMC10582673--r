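# Elliptic Fourier descriptors of closed outlines.
#
# A closed polygonal contour is parametrized by cumulative chord length t in
# [0, T]. The x- and y-projections are piecewise linear in t, and their
# truncated Fourier series gives four coefficients (a_n, b_n, c_n, d_n) per
# harmonic. One harmonic traces an ellipse; adding harmonics refines the
# outline.

as_contour <- function(x) {
  if (inherits(x, "chaincode")) x <- chain_to_contour(x)
  m <- as.matrix(x)
  if (ncol(m) != 2L) abort("a contour must be an n x 2 matrix")
  if (nrow(m) >= 2L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (!all(is.finite(m))) abort("non-finite contour coordinates")
  m
}

#' Signed polygon area (shoelace)
#'
#' Positive for counterclockwise vertex order.
#'
#' @param contour an `n x 2` matrix of polygon vertices (closed implicitly).
#' @return Signed area.
#' @export
polygon_area <- function(contour) {
  p <- as_contour(contour)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(p) {
  if (polygon_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Elliptic Fourier descriptors of a closed contour
#'
#' Computes harmonic coefficients from the chord-length parametrization of a
#' closed polyline. Contours are standardized to counterclockwise order
#' first, so coefficient signs are comparable across specimens. Accepts a
#' coordinate matrix or a [chaincode] object.
#'
#' @param contour `n x 2` matrix (closed polygon; a repeated last vertex is
#'   tolerated) or a [chaincode].
#' @param n_harmonics number of harmonics `N >= 1` (26 is the conventional
#'   choice for bone outlines).
#' @param t optional parameter values of the vertices (non-decreasing,
#'   `t[1] = 0`, implicit period `t[K+1]`); by default the cumulative chord
#'   length. Supplying the parameter makes `efd` the exact adjoint of
#'   [efd_reconstruct()].
#' @return An `efdset`: `A0`, `C0` (curve centroid), `coef` (`N x 4` matrix
#'   with columns `a`, `b`, `c`, `d`), `T` (perimeter), and the source
#'   contour used.
#' @export
efd <- function(contour, n_harmonics = 26L, t = NULL) {
  N <- as.integer(n_harmonics)
  if (N < 1L) abort("`n_harmonics` must be at least 1")
  p0 <- as_contour(contour)
  p <- ensure_ccw(p0)
  if (!is.null(t) && !identical(dim(p), dim(p0)))
    abort("explicit `t` cannot be combined with a clockwise contour")
  K <- nrow(p)
  if (K < 3L) abort("contour needs at least 3 vertices")
  # segment s runs from vertex s to vertex s+1; parameter origin at vertex 1
  d <- p[c(2:K, 1L), , drop = FALSE] - p
  if (is.null(t)) {
    dt <- sqrt(rowSums(d^2))
  } else {
    t <- as.numeric(t)
    if (length(t) != K + 1L)
      abort("`t` must have K+1 values (vertex parameters plus the period)")
    dt <- diff(t)
  }
  if (any(dt <= 0)) {
    if (!is.null(t)) abort("`t` must be strictly increasing")
    warn(sprintf("dropping %d zero-length contour segments", sum(dt == 0)))
    keep <- dt > 0
    p <- p[keep, , drop = FALSE]
    return(efd(p, N))
  }
  Tt <- sum(dt)
  t1 <- cumsum(dt)          # t_p
  t0 <- c(0, t1[-K])        # t_{p-1}
  dx <- d[, 1]; dy <- d[, 2]

  n <- seq_len(N)
  w <- 2 * pi / Tt
  # outer(p, n): K x N matrices of cos/sin at segment ends
  c1 <- cos(outer(t1, n * w)); c0 <- cos(outer(t0, n * w))
  s1 <- sin(outer(t1, n * w)); s0 <- sin(outer(t0, n * w))
  fac <- Tt / (2 * pi^2 * n^2)
  rx <- dx / dt; ry <- dy / dt
  a <- fac * colSums(rx * (c1 - c0))
  b <- fac * colSums(rx * (s1 - s0))
  cc <- fac * colSums(ry * (c1 - c0))
  dd <- fac * colSums(ry * (s1 - s0))

  # centroid of the piecewise-linear curve (mean over the parameter)
  nxt <- p[c(2:K, 1L), , drop = FALSE]
  A0 <- sum(dt * (p[, 1] + nxt[, 1]) / 2) / Tt
  C0 <- sum(dt * (p[, 2] + nxt[, 2]) / 2) / Tt

  structure(list(A0 = A0, C0 = C0,
                 coef = cbind(a = a, b = b, c = cc, d = dd),
                 T = Tt, n_harmonics = N, contour = p),
            class = "efdset")
}

#' @export
print.efdset <- function(x, ...) {
  cat(sprintf("<efdset: %d harmonics, perimeter %.4g%s>\n", x$n_harmonics,
              x$T, if (!is.null(x$normalization)) ", normalized" else ""))
  invisible(x)
}

#' Reconstruct a contour from elliptic Fourier descriptors
#'
#' Evaluates the truncated inverse Fourier sum. With `n_use = 1` the result
#' is an ellipse; increasing `n_use` recovers finer outline structure.
#'
#' @param efdset an `efdset` from [efd()].
#' @param n_use number of harmonics to use (`1 <= n_use <= N`).
#' @param n_points number of evaluation points.
#' @return An `n_points x 2` contour matrix starting at parameter 0.
#' @export
efd_reconstruct <- function(efdset, n_use = efdset$n_harmonics,
                            n_points = 512L) {
  stopifnot(inherits(efdset, "efdset"))
  n_use <- as.integer(n_use)
  if (n_use < 1L || n_use > efdset$n_harmonics)
    abort("`n_use` must lie in 1..N")
  tt <- seq(0, efdset$T, length.out = n_points + 1L)[-(n_points + 1L)]
  n <- seq_len(n_use)
  ph <- outer(tt, n * 2 * pi / efdset$T)
  cs <- cos(ph); sn <- sin(ph)
  co <- efdset$coef
  x <- efdset$A0 + cs %*% co[n, "a"] + sn %*% co[n, "b"]
  y <- efdset$C0 + cs %*% co[n, "c"] + sn %*% co[n, "d"]
  out <- cbind(x = as.numeric(x), y = as.numeric(y))
  attr(out, "t") <- c(tt, efdset$T)   # vertex parameters plus period
  out
}

#' Longest-radius normalization of an outline
#'
#' Standardizes translation, rotation, scale and starting point: the curve
#' centroid moves to the origin, the contour is rotated so the
#' centroid-to-farthest-vertex radius lies on +x, scaled so that radius has
#' unit length, and the start vertex is shifted to the farthest vertex.
#' Coefficients are recomputed in this frame, making them invariant to the
#' pose and digitization start of the input. Reflections are never applied:
#' left and right bones remain distinct.
#'
#' Ties in the longest radius (within `tie_tol`, relative to the radius) are
#' broken deterministically by the smallest arc-length position; a tie sets
#' the `radius_tie` flag and raises a warning.
#'
#' @param efdset an `efdset` from [efd()] (carries its source contour).
#' @param tie_tol relative tolerance for declaring radii tied.
#' @return A normalized `efdset` with a `normalization` record (applied
#'   rotation angle, scale, start-point shift, tie flag).
#' @export
normalize_longest_radius <- function(efdset, tie_tol = 1e-9) {
  stopifnot(inherits(efdset, "efdset"))
  p <- efdset$contour
  K <- nrow(p)
  ctr <- c(efdset$A0, efdset$C0)
  q <- sweep(p, 2, ctr)
  r <- sqrt(rowSums(q^2))
  L <- max(r)
  if (L <= 0) abort("degenerate contour: zero radius")
  tied <- which(r >= L * (1 - tie_tol))
  radius_tie <- length(tied) > 1L
  if (radius_tie)
    warn(sprintf("longest radius tied across %d vertices; using smallest arc-length position",
                 length(tied)))
  i0 <- tied[1]   # vertices are in traversal order, so first = smallest arc length
  ang <- atan2(q[i0, 2], q[i0, 1])
  R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  qn <- (q %*% t(R)) / L
  qn <- qn[c(i0:K, seq_len(i0 - 1L)), , drop = FALSE]  # start at longest radius
  out <- efd(qn, efdset$n_harmonics)
  out$normalization <- list(rotation = -ang, scale = 1 / L,
                            start_shift = i0 - 1L, radius_tie = radius_tie,
                            centroid = ctr, longest_radius = L)
  class(out) <- c("normalized_efd", "efdset")
  out
}

# coefficient vector layout used across the package: a1,b1,c1,d1,a2,...
efd_to_vector <- function(efdset) {
  co <- efdset$coef
  v <- as.numeric(t(co))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), efdset$n_harmonics),
                     rep(seq_len(efdset$n_harmonics), each = 4L))
  v
}

efd_from_vector <- function(v, perimeter = 2 * pi) {
  N <- length(v) %/% 4L
  co <- matrix(v, ncol = 4L, byrow = TRUE,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  structure(list(A0 = 0, C0 = 0, coef = co, T = perimeter,
                 n_harmonics = N, contour = NULL),
            class = "efdset")
}
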