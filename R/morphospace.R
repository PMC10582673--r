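# Morphospace: covariance PCA over shape descriptors (EFD coefficient
# vectors in 2D, homologized surface coordinates in 3D), with a broken-stick
# retention record and an invertible mapping back to descriptor space for
# wireframe/heat visualisation.

pca_covariance <- function(X, var_tol = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) abort("PCA needs at least 3 specimens")
  v <- apply(X, 2, var)
  keep <- which(v > var_tol)
  dropped <- ncol(X) - length(keep)
  if (length(keep) == 0L) {
    # all shapes identical: a single zero-variance axis
    scores <- matrix(0, nrow(X), 1L,
                     dimnames = list(rownames(X), "PC1"))
    return(list(scores = scores, eigenvalues = 0,
                rotation = matrix(0, ncol(X), 1L),
                center = colMeans(X), kept_cols = integer(0),
                dropped = dropped))
  }
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry positive per axis
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, eigenvalues = pc$sdev^2, rotation = pc$rotation,
       center = pc$center, kept_cols = keep, dropped = dropped)
}

new_morphospace <- function(pca, ids, kind, n_vars, extra = list()) {
  ev <- pca$eigenvalues
  tot <- sum(ev)
  props <- if (tot > 0) ev / tot else rep(0, length(ev))
  rownames(pca$scores) <- ids
  structure(c(list(scores = pca$scores, eigenvalues = ev,
                   proportions = props, retained = seq_along(ev),
                   rotation = pca$rotation, center = pca$center,
                   kept_cols = pca$kept_cols, dropped_cols = pca$dropped,
                   kind = kind, n_vars = n_vars),
              extra),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace (%s): %d specimens, %d axes, %d retained>\n",
              x$kind, nrow(x$scores), length(x$eigenvalues),
              length(x$retained)))
  if (length(x$eigenvalues) > 0) {
    k <- min(6L, length(x$proportions))
    cat("  variance shares:",
        paste(sprintf("%.3f", x$proportions[seq_len(k)]), collapse = " "),
        if (length(x$proportions) > k) "...\n" else "\n")
  }
  invisible(x)
}

#' Principal component analysis of normalized outline coefficients
#'
#' Covariance-matrix PCA of specimens' elliptic Fourier coefficient vectors.
#' Coefficients with negligible variance (< 1e-12) are dropped before the
#' decomposition. Axis signs are fixed deterministically.
#'
#' @param efds a named list of `normalized_efd` objects (one per specimen)
#'   with a common harmonic count, or a numeric matrix of coefficient
#'   vectors (specimens in rows).
#' @param ids specimen identifiers (defaults to list/row names).
#' @return A `morphospace` with scores, eigenvalues, variance proportions
#'   and the loadings needed to invert scores back to outline coefficients.
#' @export
efd_pca <- function(efds, ids = NULL) {
  if (is.matrix(efds)) {
    X <- efds
    Nh <- ncol(X) %/% 4L
  } else {
    Ns <- vapply(efds, function(e) e$n_harmonics, 1L)
    if (length(unique(Ns)) != 1L) abort("all specimens must share one harmonic count")
    Nh <- Ns[1]
    X <- do.call(rbind, lapply(efds, efd_to_vector))
  }
  ids <- ids %||% rownames(X) %||% names(efds) %||%
    paste0("spec", seq_len(nrow(X)))
  pca <- pca_covariance(X)
  new_morphospace(pca, ids, kind = "efd", n_vars = ncol(X),
                  extra = list(n_harmonics = Nh))
}

#' Apply retention and exclusion rules to a morphospace
#'
#' Retains the leading axes selected by the broken-stick rule (or an
#' explicit count) and then removes any axes listed in `excluded_pcs`
#' (e.g. a component judged to be a preparation artifact).
#'
#' @param ms a `morphospace`.
#' @param n_retain number of leading axes; default applies [broken_stick()]
#'   to the eigenvalues (with a floor of one axis).
#' @param excluded_pcs integer axis numbers to drop after retention.
#' @return The `morphospace` with an updated `retained` field.
#' @export
retain_axes <- function(ms, n_retain = NULL, excluded_pcs = integer(0)) {
  stopifnot(inherits(ms, "morphospace"))
  if (is.null(n_retain)) n_retain <- max(1L, broken_stick(ms$eigenvalues))
  n_retain <- min(n_retain, length(ms$eigenvalues))
  keep <- setdiff(seq_len(n_retain), as.integer(excluded_pcs))
  if (length(keep) == 0L) abort("no axes left after exclusions")
  ms$retained <- keep
  ms
}

#' Retained PC scores as a tibble
#'
#' @param x a `morphospace`.
#' @param all return all axes rather than only the retained ones.
#' @param ... unused.
#' @return A tibble with `specimen_id` and one column per PC.
#' @export
tidy.morphospace <- function(x, all = FALSE, ...) {
  ax <- if (all) seq_along(x$eigenvalues) else x$retained
  sc <- x$scores[, ax, drop = FALSE]
  out <- as_tibble(sc, .name_repair = "minimal")
  names(out) <- paste0("PC", ax)
  dplyr::bind_cols(tibble(specimen_id = rownames(x$scores)), out)
}

#' @export
glance.morphospace <- function(x, ...) {
  tibble(n_specimens = nrow(x$scores),
         n_axes = length(x$eigenvalues),
         n_retained = length(x$retained),
         retained_variance = sum(x$proportions[x$retained]),
         kind = x$kind)
}

#' Matrix of retained PC scores
#'
#' @param ms a `morphospace`.
#' @return Numeric matrix (specimens x retained axes).
#' @export
retained_scores <- function(ms) ms$scores[, ms$retained, drop = FALSE]

# invert a point in score space back to the descriptor space
morphospace_invert <- function(ms, score_vec) {
  full <- rep(0, ms$n_vars)
  ax <- seq_along(score_vec)
  contrib <- ms$rotation[, ax, drop = FALSE] %*% score_vec
  full[ms$kept_cols] <- ms$center + as.numeric(contrib)
  if (length(ms$kept_cols) < ms$n_vars && !is.null(ms$fixed_values))
    full[-ms$kept_cols] <- ms$fixed_values[-ms$kept_cols]
  full
}

#' Wireframe outlines along principal components
#'
#' Reconstructs the mean outline and the outlines at +/- `sd_mult` standard
#' deviations along each requested axis by inverting the PCA mapping, the
#' standard way outline shape change along a PC is visualized.
#'
#' @param ms an `efd`-kind `morphospace`.
#' @param pcs axis numbers to visualize.
#' @param sd_mult excursion in within-axis standard deviations.
#' @param n_points points per reconstructed outline.
#' @return A tibble with columns `pc`, `pose` (`-sd`, `mean`, `+sd`),
#'   `x`, `y`, `point`.
#' @export
efd_wireframes <- function(ms, pcs = ms$retained[seq_len(min(3, length(ms$retained)))],
                           sd_mult = 2, n_points = 256L) {
  stopifnot(inherits(ms, "morphospace"))
  if (!identical(ms$kind, "efd")) abort("wireframes need an EFD morphospace")
  mean_vec <- local({
    full <- rep(0, ms$n_vars)
    full[ms$kept_cols] <- ms$center
    full
  })
  rows <- purrr::map_dfr(pcs, function(j) {
    sdj <- sqrt(ms$eigenvalues[j])
    purrr::map_dfr(c(-sd_mult, 0, sd_mult), function(k) {
      vec <- mean_vec
      vec[ms$kept_cols] <- ms$center + ms$rotation[, j] * (k * sdj)
      ctr <- efd_reconstruct(efd_from_vector(vec), n_points = n_points)
      tibble(pc = j,
             pose = c(`-1` = "-sd", `0` = "mean", `1` = "+sd")[as.character(sign(k))],
             point = seq_len(n_points), x = ctr[, 1], y = ctr[, 2])
    })
  })
  rows
}

#' Write wireframe outlines as a minimal SVG file
#'
#' @param wires output of [efd_wireframes()].
#' @param path output `.svg` path.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
write_wireframe_svg <- function(wires, path, width = 300, height = 300) {
  pcs <- unique(wires$pc)
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                     width * length(pcs), height, width * length(pcs), height))
  rng <- max(abs(c(wires$x, wires$y))) * 1.1
  for (i in seq_along(pcs)) {
    sub <- wires[wires$pc == pcs[i], ]
    for (pose in unique(sub$pose)) {
      s2 <- sub[sub$pose == pose, ]
      px <- (s2$x / rng / 2 + 0.5) * width + (i - 1) * width
      py <- (0.5 - s2$y / rng / 2) * height
      col <- c(`-sd` = "#1f77b4", mean = "#333333", `+sd` = "#d62728")[pose]
      lines <- c(lines,
                 sprintf('<polygon points="%s" fill="none" stroke="%s" stroke-width="1"/>',
                         paste(sprintf("%.2f,%.2f", px, py), collapse = " "),
                         col))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Morphospace scatter plot
#'
#' @param object a `morphospace`.
#' @param axes two axis numbers to plot.
#' @param groups optional grouping vector (same order as specimens) mapped
#'   to colour.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.morphospace <- function(object, axes = object$retained[1:2],
                                 groups = NULL, ...) {
  axes <- axes[!is.na(axes)]
  if (length(axes) < 2L) axes <- c(1L, min(2L, length(object$eigenvalues)))
  df <- tibble(x = object$scores[, axes[1]], y = object$scores[, axes[2]],
               specimen_id = rownames(object$scores))
  lab <- function(j) sprintf("PC%d (%.1f%%)", j, 100 * object$proportions[j])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(groups)) {
    df$group <- groups
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$group))
  }
  gg + ggplot2::geom_point() +
    ggplot2::labs(x = lab(axes[1]), y = lab(axes[2])) +
    ggplot2::theme_minimal()
}
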