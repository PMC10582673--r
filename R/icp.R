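# Rigid(+scale) superimposition of surface point samples.
#
# Pose initialization matches centroids and principal axes (testing all four
# proper axis-sign branches); refinement is iterative closest point with an
# SVD-based least-squares transform per step. Dissimilarity is the
# Procrustes surface metric (PSM), a symmetrized RMS nearest-neighbour
# distance. Reflections are never applied: bones are chiral.

nn_query <- function(query, ref) {
  nn_kdtree(as_points(query), as_points(ref))
}

#' Procrustes surface metric between two aligned point sets
#'
#' `sqrt( sum d(a,B)^2 / (2 m_A) + sum d(b,A)^2 / (2 m_B) )`, the
#' symmetrized root-mean-square nearest-neighbour distance between samples.
#' Zero for identical sets, symmetric by construction. Set
#' `symmetric = FALSE` for the one-directional prototype-to-specimen
#' variant (sensitivity checks).
#'
#' @param a,b point samples ([sample_points()]) or `m x 3` matrices.
#' @param symmetric use both directions (default) or only `a` to `b`.
#' @return Non-negative scalar.
#' @export
psm <- function(a, b, symmetric = TRUE) {
  A <- as_points(a); B <- as_points(b)
  if (nrow(A) == 0L || nrow(B) == 0L) abort("empty point sample")
  dab <- nn_query(A, B)$dist
  if (!symmetric) return(sqrt(mean(dab^2)))
  dba <- nn_query(B, A)$dist
  sqrt(sum(dab^2) / (2 * nrow(A)) + sum(dba^2) / (2 * nrow(B)))
}

rigid_transform <- function(R = diag(3), s = 1, t = c(0, 0, 0)) {
  structure(list(R = R, s = s, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid(+scale) transform to points
#'
#' Rows map as `x -> s * R x + t`.
#'
#' @param points `m x 3` matrix or point sample.
#' @param tf a `rigid_transform`.
#' @return Transformed `m x 3` matrix.
#' @export
apply_rigid <- function(points, tf) {
  sweep(as_points(points) %*% t(tf$R) * tf$s, 2, tf$t, `+`)
}

compose_rigid <- function(inc, cur) {
  # (inc o cur)(x) = s_i R_i (s_c R_c x + t_c) + t_i
  rigid_transform(R = inc$R %*% cur$R, s = inc$s * cur$s,
                  t = inc$s * as.numeric(inc$R %*% cur$t) + inc$t)
}

rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

# least-squares similarity transform mapping paired X onto Y (Umeyama)
fit_similarity <- function(X, Y, allow_scale = TRUE) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- crossprod(Xc, Yc) / nrow(X)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * c(1, 1, d)) / mean(rowSums(Xc^2)) else 1
  t <- my - s * as.numeric(R %*% mx)
  rigid_transform(R = R, s = s, t = t)
}

principal_axes <- function(P) {
  C <- cov(P)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[3] < 1e-12 * e$values[1])
    abort("rank-deficient covariance: points are (near) planar")
  A <- e$vectors
  # canonical signs (projection skewness) so the axis frame — and hence the
  # initialization branch label — is stable across point samples of the
  # same surface; the third axis completes a right-handed frame
  ctr <- sweep(P, 2, colMeans(P))
  for (j in 1:2) {
    sk <- mean((ctr %*% A[, j])^3)
    if (sk < 0) A[, j] <- -A[, j]
  }
  A[, 3] <- c(A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
              A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
              A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2])
  A
}

#' Initialize the pose of a specimen against a prototype
#'
#' Matches centroids and principal axes. All four proper-rotation axis-sign
#' branches are evaluated and the one with the lowest PSM is returned; a
#' mirrored specimen is flagged but never reflected.
#'
#' @param sample,prototype_sample point samples or `m x 3` matrices.
#' @param eval_m number of points used to score the branches.
#' @param allow_scale also match the RMS radii (initial scale estimate).
#' @return List with `transform` (a `rigid_transform`), `branch` (1..4),
#'   `psm`, and `mirror_suspect`.
#' @export
initialize_pose <- function(sample, prototype_sample, eval_m = 500L,
                            allow_scale = TRUE) {
  X <- as_points(sample); P <- as_points(prototype_sample)
  Ax <- principal_axes(X); Ap <- principal_axes(P)
  cx <- colMeans(X); cp <- colMeans(P)
  s0 <- if (allow_scale) {
    sqrt(mean(rowSums(sweep(P, 2, cp)^2)) /
           mean(rowSums(sweep(X, 2, cx)^2)))
  } else 1
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sub <- function(M) {
    if (nrow(M) > eval_m) M[round(seq(1, nrow(M), length.out = eval_m)), ,
                            drop = FALSE] else M
  }
  Xs <- sub(X); Ps <- sub(P)
  best <- NULL
  for (k in seq_along(signs)) {
    R <- Ap %*% diag(signs[[k]]) %*% t(Ax)
    tf <- rigid_transform(R = R, s = s0, t = cp - s0 * as.numeric(R %*% cx))
    v <- psm(apply_rigid(Xs, tf), Ps)
    if (is.null(best) || v < best$psm)
      best <- list(transform = tf, branch = k, psm = v)
  }
  # a mirrored copy aligns poorly on every proper branch; flag, don't fix
  best$mirror_suspect <- {
    Xm <- Xs; Xm[, 1] <- -Xm[, 1]
    Axm <- tryCatch(principal_axes(Xm), error = function(e) NULL)
    if (is.null(Axm)) FALSE else {
      vm <- min(vapply(signs, function(sg) {
        R <- Ap %*% diag(sg) %*% t(Axm)
        tf <- rigid_transform(R = R, s = s0,
                              t = cp - s0 * as.numeric(R %*% colMeans(Xm)))
        psm(apply_rigid(Xm, tf), Ps)
      }, 1.0))
      vm < 0.5 * best$psm
    }
  }
  best
}

#' Iterative closest point superimposition to a prototype
#'
#' Alternates nearest-neighbour correspondences (specimen to prototype)
#' with the SVD least-squares rotation/translation (and optional scale),
#' accepting steps while the PSM improves. The PSM sequence over accepted
#' iterations is non-increasing by construction.
#'
#' @param sample,prototype_sample point samples or `m x 3` matrices.
#' @param allow_scale estimate a uniform scale (Procrustes convention).
#' @param max_iter,tol stopping rule: stop when the PSM improves by less
#'   than `tol` times the prototype bounding-box diagonal, or after
#'   `max_iter` iterations (then `converged = FALSE`).
#' @param init optional initialization (output of [initialize_pose()]).
#' @return An `alignment`: `transform`, `psm`, `psm_trace`, `iterations`,
#'   `converged`, `branch`, `mirror_suspect`.
#' @export
icp_align <- function(sample, prototype_sample, allow_scale = TRUE,
                      max_iter = 200L, tol = 1e-7, init = NULL) {
  X0 <- as_points(sample); P <- as_points(prototype_sample)
  init <- init %||% initialize_pose(X0, P, allow_scale = allow_scale)
  tf <- init$transform
  X <- apply_rigid(X0, tf)
  scale_ref <- bbox_diagonal(P)
  cur_psm <- psm(X, P)
  trace <- cur_psm
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    idx <- nn_query(X, P)$idx
    inc <- fit_similarity(X, P[idx, , drop = FALSE], allow_scale = allow_scale)
    Xn <- apply_rigid(X, inc)
    new_psm <- psm(Xn, P)
    if (new_psm >= cur_psm - tol * scale_ref) {
      converged <- TRUE
      if (new_psm < cur_psm) {   # accept a final sub-tolerance improvement
        tf <- compose_rigid(inc, tf)
        X <- Xn
        cur_psm <- new_psm
        trace <- c(trace, new_psm)
      }
      break
    }
    tf <- compose_rigid(inc, tf)
    X <- Xn
    cur_psm <- new_psm
    trace <- c(trace, new_psm)
  }
  structure(list(transform = tf, psm = cur_psm, psm_trace = trace,
                 iterations = iter, converged = converged,
                 branch = init$branch,
                 mirror_suspect = isTRUE(init$mirror_suspect),
                 aligned = X),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment: PSM %.4g after %d iterations (%s, branch %d)>\n",
              x$psm, x$iterations,
              if (x$converged) "converged" else "not converged", x$branch))
  invisible(x)
}
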