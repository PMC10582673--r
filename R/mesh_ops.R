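# Mesh cleaning, resolution control and surface sampling.
#
# Simplification is shortest-edge collapse with midpoint placement and a
# link-condition guard; upsampling is midpoint (1:4) subdivision. Both keep
# the surface within a thin band of the input at the face counts used here.

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Clean a mesh and resample it to a target face count
#'
#' Merges duplicate vertices, drops degenerate faces, triangulates small
#' boundary loops (hole closing), then adjusts resolution: edge-collapse
#' simplification down to `target_faces`, or midpoint subdivision followed by
#' simplification when the target exceeds the input count. The result is
#' within 10% of `target_faces` (usually exact to one collapse).
#'
#' @param mesh a [trimesh()].
#' @param target_faces desired face count (positive integer).
#' @param merge_tol vertex-merge tolerance as a fraction of the bounding-box
#'   diagonal.
#' @param max_hole_edges boundary loops with at most this many edges are
#'   closed; longer ones are left open with a warning.
#' @return A cleaned [trimesh()] resampled to the target resolution.
#' @export
clean_and_resample <- function(mesh, target_faces, merge_tol = 1e-8,
                               max_hole_edges = 32L) {
  stopifnot(inherits(mesh, "trimesh"), target_faces >= 4)
  V <- mesh$vertices
  F <- mesh$faces

  # merge duplicate vertices
  diag <- max(bbox_diagonal(mesh), .Machine$double.eps)
  key <- apply(round(V / (merge_tol * diag)), 1, paste, collapse = ",")
  map <- match(key, key)                  # first occurrence per duplicate set
  keep <- sort(unique(map))
  remap <- match(map, keep)
  V <- V[keep, , drop = FALSE]
  F[] <- remap[F]

  F <- drop_degenerate_faces(V, F)
  m <- trimesh(V, F, id = mesh$id)
  m <- close_small_holes(m, max_hole_edges)

  nf <- nrow(m$faces)
  if (nf < target_faces) {
    while (nrow(m$faces) < target_faces) m <- subdivide_midpoint(m)
  }
  if (nrow(m$faces) > target_faces) m <- collapse_edges(m, target_faces)
  m
}

drop_degenerate_faces <- function(V, F) {
  if (nrow(F) == 0L) return(F)
  dup <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
  F <- F[!dup, , drop = FALSE]
  if (nrow(F) == 0L) return(F)
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area2 <- cx^2 + cy^2 + cz^2
  F[area2 > 0, , drop = FALSE]
}

boundary_loops <- function(mesh) {
  F <- mesh$faces
  de <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  k <- edge_key(de[, 1], de[, 2])
  cnt <- table(k)
  open <- de[k %in% names(cnt)[cnt == 1L], , drop = FALSE]
  if (nrow(open) == 0L) return(list())
  nxt <- setNames(open[, 2], as.character(open[, 1]))
  used <- rep(FALSE, nrow(open))
  names(used) <- as.character(open[, 1])
  loops <- list()
  remaining <- open
  while (nrow(remaining) > 0L) {
    loop <- remaining[1, 1]
    cur <- remaining[1, 2]
    remaining <- remaining[-1, , drop = FALSE]
    while (cur != loop[1]) {
      loop <- c(loop, cur)
      i <- which(remaining[, 1] == cur)[1]
      if (is.na(i)) break
      cur <- remaining[i, 2]
      remaining <- remaining[-i, , drop = FALSE]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

close_small_holes <- function(mesh, max_hole_edges = 32L) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L) return(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  for (loop in loops) {
    if (length(loop) > max_hole_edges) {
      warn(sprintf("boundary loop of %d edges left open", length(loop)))
      next
    }
    # hole boundary runs opposite to the face winding around it
    if (length(loop) == 3L) {
      F <- rbind(F, rev(loop))
    } else {
      ctr <- colMeans(V[loop, , drop = FALSE])
      V <- rbind(V, ctr)
      ci <- nrow(V)
      lp <- rev(loop)
      F <- rbind(F, cbind(ci, lp, c(lp[-1], lp[1])))
    }
  }
  trimesh(V, F, id = mesh$id)
}

#' @rdname clean_and_resample
#' @export
subdivide_midpoint <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  k <- edge_key(e[, 1], e[, 2])
  uk <- unique(k)
  mid_idx <- nrow(V) + match(k, uk)
  first <- match(uk, k)
  mids <- (V[e[first, 1], , drop = FALSE] + V[e[first, 2], , drop = FALSE]) / 2
  V2 <- rbind(V, mids)
  nf <- nrow(F)
  m12 <- mid_idx[seq_len(nf)]
  m23 <- mid_idx[nf + seq_len(nf)]
  m31 <- mid_idx[2L * nf + seq_len(nf)]
  F2 <- rbind(cbind(F[, 1], m12, m31),
              cbind(m12, F[, 2], m23),
              cbind(m31, m23, F[, 3]),
              cbind(m12, m23, m31))
  trimesh(V2, F2, id = mesh$id)
}

# Edge-collapse simplification with quadric-error-metric placement: each
# vertex accumulates the squared-plane-distance quadric of its incident
# faces; collapses are ordered by quadric cost and the merged vertex is
# placed at the cost minimizer (midpoint fallback for singular quadrics).
collapse_edges <- function(mesh, target_faces) {
  V <- mesh$vertices
  F <- mesh$faces
  alive_f <- rep(TRUE, nrow(F))
  vf <- vector("list", nrow(V))
  for (j in 1:3) {
    sp <- split(seq_len(nrow(F)), F[, j])
    idx <- as.integer(names(sp))
    for (i in seq_along(sp)) vf[[idx[i]]] <- c(vf[[idx[i]]], sp[[i]])
  }
  nf_alive <- nrow(F)

  # per-vertex quadrics (4x4, stored as n x 16)
  Q <- matrix(0, nrow(V), 16L)
  {
    a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    ok <- nn > 0
    nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
    dd <- -(nx * V[F[, 1], 1] + ny * V[F[, 1], 2] + nz * V[F[, 1], 3])
    pl <- cbind(nx, ny, nz, dd)
    for (fi in which(ok)) {
      K <- as.numeric(tcrossprod(pl[fi, ]))
      for (vv in F[fi, ]) Q[vv, ] <- Q[vv, ] + K
    }
  }

  qem_place <- function(u, v) {
    Qe <- matrix(Q[u, ] + Q[v, ], 4L, 4L)
    A <- Qe[1:3, 1:3]
    pos <- tryCatch({
      if (rcond(A) < 1e-10) stop("singular")
      as.numeric(solve(A, -Qe[1:3, 4]))
    }, error = function(e) (V[u, ] + V[v, ]) / 2)
    h <- c(pos, 1)
    list(pos = pos, cost = max(0, sum(h * (Qe %*% h))))
  }

  build_queue <- function() {
    fa <- which(alive_f)
    e <- rbind(F[fa, c(1, 2), drop = FALSE], F[fa, c(2, 3), drop = FALSE],
               F[fa, c(3, 1), drop = FALSE])
    u <- pmin(e[, 1], e[, 2]); v <- pmax(e[, 1], e[, 2])
    dupk <- !duplicated(u * (nrow(V) + 1) + v)
    u <- u[dupk]; v <- v[dupk]
    cost <- vapply(seq_along(u), function(i) qem_place(u[i], v[i])$cost, 1.0)
    o <- order(cost)
    cbind(u[o], v[o])
  }

  while (nf_alive > target_faces) {
    q <- build_queue()
    progressed <- FALSE
    for (r in seq_len(nrow(q))) {
      if (nf_alive <= target_faces) break
      u <- q[r, 1]; v <- q[r, 2]
      fu <- vf[[u]]; fv <- vf[[v]]
      fu <- fu[alive_f[fu]]; fv <- fv[alive_f[fv]]
      if (length(fu) == 0L || length(fv) == 0L) next
      shared <- intersect(fu, fv)
      if (length(shared) == 0L) next
      nu <- setdiff(unique(as.vector(F[fu, , drop = FALSE])), c(u, v))
      nv <- setdiff(unique(as.vector(F[fv, , drop = FALSE])), c(u, v))
      common <- intersect(nu, nv)
      opp <- setdiff(unique(as.vector(F[shared, , drop = FALSE])), c(u, v))
      if (length(common) != length(opp)) next   # link condition
      V[u, ] <- qem_place(u, v)$pos
      Q[u, ] <- Q[u, ] + Q[v, ]
      for (fi in fv) {
        if (!alive_f[fi]) next
        if (fi %in% shared) {
          alive_f[fi] <- FALSE
          nf_alive <- nf_alive - 1L
        } else {
          F[fi, ][F[fi, ] == v] <- u
        }
      }
      vf[[u]] <- unique(c(fu, fv))
      vf[[v]] <- integer(0)
      progressed <- TRUE
    }
    if (!progressed) {
      warn("edge collapse stalled before reaching target face count")
      break
    }
  }
  Fk <- F[alive_f, , drop = FALSE]
  used <- sort(unique(as.vector(Fk)))
  Fk[] <- match(Fk, used)
  trimesh(V[used, , drop = FALSE], Fk, id = mesh$id)
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected to the unit sphere; a standard closed
#' test surface (face count `20 * 4^subdiv`).
#'
#' @param subdiv number of 1:4 subdivisions.
#' @return A [trimesh()].
#' @export
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- trimesh(V / sqrt(rowSums(V^2)), F, id = "icosphere")
  for (i in seq_len(subdiv)) {
    m <- subdivide_midpoint(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  m
}

# run code under a local RNG state; global stream untouched unless seed NULL
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Area-weighted uniform point sampling on a mesh
#'
#' Draws `m` points uniformly with respect to surface area: faces are picked
#' proportionally to their area and positions are uniform in barycentric
#' coordinates. An even point distribution over the surface is what the
#' landmark-free alignment assumes.
#'
#' @param mesh a [trimesh()].
#' @param m number of points (`100 <= m <= 1e7`).
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return A `pointsample`: list with `points` (`m x 3`), `face`, `bary`,
#'   and provenance fields.
#' @export
sample_points <- function(mesh, m, seed = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  if (m < 100) abort("`m` must be at least 100")
  if (m > 1e7) abort("`m` must not exceed 1e7")
  ar <- face_areas(mesh)
  if (sum(ar) <= 0) abort("mesh has zero total area")
  with_local_seed(seed, {
    cs <- cumsum(ar) / sum(ar)
    fid <- findInterval(runif(m), cs) + 1L
    fid[fid > length(ar)] <- length(ar)
    r1 <- sqrt(runif(m))
    r2 <- runif(m)
    u <- 1 - r1
    v <- r1 * (1 - r2)
    w <- r1 * r2
    A <- mesh$vertices[mesh$faces[fid, 1], , drop = FALSE]
    B <- mesh$vertices[mesh$faces[fid, 2], , drop = FALSE]
    C <- mesh$vertices[mesh$faces[fid, 3], , drop = FALSE]
    pts <- A * u + B * v + C * w
    structure(list(points = pts, face = fid, bary = cbind(u, v, w),
                   m = as.integer(m), mesh_id = mesh$id, seed = seed),
              class = "pointsample")
  })
}

#' @export
print.pointsample <- function(x, ...) {
  cat(sprintf("<pointsample: %d points from %s>\n", x$m,
              x$mesh_id %||% "mesh"))
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "pointsample")) x$points
  else if (inherits(x, "trimesh")) x$vertices
  else as.matrix(x)
}
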