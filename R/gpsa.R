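# Generalized Procrustes surface analysis.
#
# Every specimen is superimposed to a prototype by ICP; each prototype point
# is then "homologized" to its closest specimen point, the prototype is
# replaced by the mean of those homologized points, and the loop repeats
# until the mean PSM stops improving. Ordination is covariance PCA of the
# homologized coordinate rows; per-point deviation is the across-specimen
# RMS distance from the prototype, the scalar painted on heat maps.

#' Generalized surface alignment of a specimen set
#'
#' @param samples named list of point samples ([sample_points()]) or
#'   `m x 3` matrices, one per specimen.
#' @param prototype specimen name (must be in `names(samples)`) or an
#'   `m x 3` matrix of starting prototype points.
#' @param allow_scale estimate per-specimen scale during ICP.
#' @param max_outer maximum outer (prototype-update) iterations.
#' @param tol stop when the mean PSM improves by less than `tol` times the
#'   prototype bounding-box diagonal.
#' @param max_icp_iter per-specimen ICP iteration cap.
#' @param flag_misaligned flag specimens whose final PSM exceeds the group
#'   median + 3 IQR; flagged specimens are excluded from prototype updates
#'   (with a warning) but kept in the output.
#' @return A `gpsa_result`: `prototype_points`, `homologized`
#'   (specimens x 3m), `morphospace`, `deviation` (length m),
#'   `alignments` (per-specimen tibble), `mean_psm_trace`, `centroid_sizes`.
#' @export
gpsa <- function(samples, prototype, allow_scale = TRUE, max_outer = 50L,
                 tol = 1e-7, max_icp_iter = 60L, flag_misaligned = TRUE) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("spec", seq_along(samples))
  ids <- names(samples)
  pts <- lapply(samples, as_points)
  if (is.character(prototype)) {
    if (!prototype %in% ids)
      abort(sprintf("prototype '%s' is not among the specimens", prototype))
    P <- pts[[prototype]]
  } else P <- as_points(prototype)
  m <- nrow(P)
  n <- length(pts)
  scale_ref <- bbox_diagonal(P)
  centroid_sizes <- vapply(pts, centroid_size, 1.0)

  align_all <- function(P) {
    H <- matrix(NA_real_, n, 3L * m, dimnames = list(ids, NULL))
    aligns <- vector("list", n)
    psms <- numeric(n)
    for (i in seq_len(n)) {
      al <- icp_align(pts[[i]], P, allow_scale = allow_scale,
                      max_iter = max_icp_iter)
      aligns[[i]] <- al
      psms[i] <- al$psm
      idx <- nn_query(P, al$aligned)$idx
      H[i, ] <- as.numeric(t(al$aligned[idx, , drop = FALSE]))
    }
    misaligned <- rep(FALSE, n)
    if (flag_misaligned && n >= 4L) {
      # misalignment is a qualitative failure: require the PSM to be an
      # outlier (median + 3 IQR) AND well above the cohort's typical level,
      # so tight identical-shape cohorts are not flagged on sampling noise
      thr <- median(psms) + 3 * IQR(psms)
      misaligned <- psms > thr & psms > 1.5 * median(psms) &
        psms > .Machine$double.eps * scale_ref
    }
    list(P = P, H = H, aligns = aligns, psms = psms,
         misaligned = misaligned, mean_psm = mean(psms))
  }

  # accepted-step outer loop: the recorded mean-PSM trace is non-increasing
  best <- NULL
  mean_trace <- numeric(0)
  for (outer in seq_len(max_outer)) {
    state <- align_all(P)
    if (!is.null(best) &&
        state$mean_psm >= best$mean_psm - tol * scale_ref) {
      if (state$mean_psm < best$mean_psm) {
        best <- state
        mean_trace <- c(mean_trace, state$mean_psm)
      }
      break
    }
    best <- state
    mean_trace <- c(mean_trace, state$mean_psm)
    if (outer == 1L && any(state$misaligned))
      warn(sprintf("%d specimen(s) flagged as misaligned: %s",
                   sum(state$misaligned),
                   paste(ids[state$misaligned], collapse = ", ")))
    use <- if (any(!state$misaligned)) !state$misaligned else rep(TRUE, n)
    P <- matrix(colMeans(state$H[use, , drop = FALSE]), ncol = 3L,
                byrow = TRUE)
  }
  P <- best$P
  H <- best$H
  aligns <- best$aligns
  misaligned <- best$misaligned

  dev2 <- matrix(0, n, m)
  for (i in seq_len(n)) {
    Hi <- matrix(H[i, ], ncol = 3L, byrow = TRUE)
    dev2[i, ] <- rowSums((Hi - P)^2)
  }
  deviation <- sqrt(colMeans(dev2))

  pca <- pca_covariance(H)
  ms <- new_morphospace(pca, ids, kind = "gpsa", n_vars = ncol(H))

  align_tbl <- tibble(
    specimen_id = ids,
    psm = vapply(aligns, `[[`, 1.0, "psm"),
    iterations = vapply(aligns, `[[`, 1L, "iterations"),
    converged = vapply(aligns, `[[`, TRUE, "converged"),
    branch = vapply(aligns, `[[`, 1L, "branch"),
    mirror_suspect = vapply(aligns, `[[`, TRUE, "mirror_suspect"),
    misaligned = misaligned,
    centroid_size = centroid_sizes)

  structure(list(prototype_points = P, homologized = H, morphospace = ms,
                 deviation = deviation, alignments = align_tbl,
                 mean_psm_trace = mean_trace,
                 allow_scale = allow_scale),
            class = "gpsa_result")
}

#' @export
print.gpsa_result <- function(x, ...) {
  cat(sprintf("<gpsa_result: %d specimens, %d prototype points, mean PSM %.4g>\n",
              nrow(x$homologized), nrow(x$prototype_points),
              utils::tail(x$mean_psm_trace, 1)))
  invisible(x)
}

#' @export
tidy.gpsa_result <- function(x, ...) tidy(x$morphospace, ...)

#' @export
glance.gpsa_result <- function(x, ...) {
  tibble(n_specimens = nrow(x$homologized),
         n_points = nrow(x$prototype_points),
         mean_psm = utils::tail(x$mean_psm_trace, 1),
         outer_iterations = length(x$mean_psm_trace),
         n_misaligned = sum(x$alignments$misaligned))
}

#' Per-point loading magnitude of an ordination axis
#'
#' The Euclidean norm of the (x, y, z) loadings per prototype point: where
#' on the surface a principal component moves the shape.
#'
#' @param result a `gpsa_result`.
#' @param pc axis number.
#' @return Numeric vector of length `m` (prototype points).
#' @export
gpsa_pc_field <- function(result, pc = 1L) {
  ms <- result$morphospace
  m <- nrow(result$prototype_points)
  full <- rep(0, 3L * m)
  full[ms$kept_cols] <- ms$rotation[, pc]
  sqrt(rowSums(matrix(full, ncol = 3L, byrow = TRUE)^2))
}

#' Export per-point deviation (heat values) as PLY
#'
#' Writes the prototype points with the across-specimen RMS deviation in a
#' per-vertex `quality` channel, plus one file per requested PC with the
#' axis loading magnitude — the inputs for deviation heat maps.
#'
#' @param result a `gpsa_result`.
#' @param path output `.ply` path for the deviation field.
#' @param pcs axis numbers whose loading fields are written alongside
#'   (suffix `_pc<k>.ply`); `NULL` for none.
#' @return Paths written, invisibly.
#' @export
deviation_heat_export <- function(result, path, pcs = NULL) {
  mesh <- trimesh(result$prototype_points,
                  matrix(integer(0), 0, 3), id = "prototype")
  write_mesh(mesh, path, quality = result$deviation)
  paths <- path
  for (pc in pcs) {
    p2 <- sub("\\.ply$", sprintf("_pc%d.ply", pc), path)
    write_mesh(mesh, p2, quality = gpsa_pc_field(result, pc))
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' @importFrom stats IQR
NULL
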