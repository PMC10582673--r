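# Two-criterion prototype / mesh-resolution selection.
#
# Criterion 1 (alignment consistency): every prototype x face-count combo is
# aligned `repeats` times with fresh point-sample seeds; specimens are
# counted as misaligned if their final PSM is an outlier (median + 3 IQR)
# or their initialization branch is unstable across repeats. Criterion 2
# (disparity screening) then compares the surviving combos: smaller median
# convex hulls with larger ranges indicate less noise in the morphospace.

#' Alignment-consistency screen over prototype and resolution combinations
#'
#' @param meshes named list of [trimesh()] objects (all specimens).
#' @param prototypes specimen ids to test as prototypes (must be in
#'   `names(meshes)`).
#' @param face_counts integer vector of mesh resolutions to test.
#' @param repeats alignment repetitions per combo (fresh sample seeds each
#'   time; sampling is the stochastic element that makes repeats
#'   informative).
#' @param m_points surface sample size per specimen.
#' @param seed integer seed.
#' @param allow_scale,max_outer passed to [gpsa()].
#' @param prototype_only ids in `meshes` used only as starting prototypes:
#'   they are excluded from the specimen set, the misalignment count and
#'   the ordination (useful to evaluate an external or deliberately bad
#'   reference without letting its own score row shape the morphospace).
#' @return A `combo_screen`: tibble with one row per combo (`prototype_id`,
#'   `face_count`, `n_misaligned`, list-columns `misaligned_ids`,
#'   `per_repeat`, `scores` with the last repeat's retained z-scored
#'   ordination, and `scores_raw` with the unstandardized retained scores).
#' @export
consistency_screen <- function(meshes, prototypes, face_counts,
                               repeats = 5L, m_points = 1000L, seed = 1L,
                               allow_scale = TRUE, max_outer = 10L,
                               prototype_only = character(0)) {
  all_ids <- names(meshes)
  if (is.null(all_ids)) abort("`meshes` must be a named list")
  bad <- setdiff(prototypes, all_ids)
  if (length(bad) > 0)
    abort(sprintf("prototype(s) not in dataset: %s",
                  paste(bad, collapse = ", ")))
  ids <- setdiff(all_ids, prototype_only)
  with_local_seed(seed, {
    resampled <- lapply(face_counts, function(fc) {
      lapply(meshes, clean_and_resample, target_faces = fc)
    })
    names(resampled) <- as.character(face_counts)
    combos <- tidyr::expand_grid(face_count = as.integer(face_counts),
                                 prototype_id = prototypes)
    rows <- purrr::pmap(combos, function(face_count, prototype_id) {
      msh <- resampled[[as.character(face_count)]]
      per_repeat <- vector("list", repeats)
      branches <- matrix(NA_integer_, repeats, length(ids),
                         dimnames = list(NULL, ids))
      last <- NULL
      for (r in seq_len(repeats)) {
        sseeds <- sample.int(.Machine$integer.max - 1L, length(all_ids))
        samples <- purrr::imap(msh, function(m, id)
          sample_points(m, m_points, seed = sseeds[match(id, all_ids)]))
        proto <- if (prototype_id %in% prototype_only)
          samples[[prototype_id]]$points else prototype_id
        res <- suppressWarnings(
          gpsa(samples[ids], proto, allow_scale = allow_scale,
               max_outer = max_outer))
        per_repeat[[r]] <- res$alignments
        branches[r, ] <- res$alignments$branch
        last <- res
      }
      psm_flagged <- unique(unlist(lapply(per_repeat, function(a)
        a$specimen_id[a$misaligned])))
      modal <- apply(branches, 2, function(b)
        as.integer(names(which.max(table(b)))))
      unstable <- ids[colSums(branches != rep(modal, each = repeats)) >= 2L]
      mis <- sort(unique(c(psm_flagged, unstable)))
      n_ret <- max(2L, broken_stick(last$morphospace$eigenvalues))
      sc <- retained_scores(retain_axes(last$morphospace, n_ret))
      tibble(prototype_id = prototype_id, face_count = face_count,
             n_misaligned = length(mis),
             misaligned_ids = list(mis),
             per_repeat = list(per_repeat),
             scores = list(zscore_scores(sc)),
             scores_raw = list(sc))
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("combo_screen", class(out))
    out
  })
}

#' Disparity screen over the surviving combinations
#'
#' Keeps the combos with the fewest misaligned specimens (criterion 1 is
#' strictly prior), assembles a single matrix of their z-scored retained
#' ordination scores, bootstraps the sum-of-ranges and convex-hull indices
#' per combo, and chooses the combo with the smallest median hull, breaking
#' remaining ties by the largest median range and then by
#' `(face_count, prototype_id)` order (flagged). Pairwise
#' Bonferroni-corrected t-statistics over the bootstrap distributions are
#' reported alongside.
#'
#' @param screen a `combo_screen` from [consistency_screen()].
#' @param n_boot bootstrap replicates.
#' @param seed optional seed.
#' @param tie_tol relative tolerance for calling two medians tied; the
#'   default (1%) is of the order of the bootstrap error of a median, so
#'   differences smaller than resampling noise do not decide the choice.
#' @return List: `chosen` (one-row tibble), `survivors`, `metrics`
#'   (disparity summary), `ttests`, `tie` flag, `note`.
#' @export
disparity_screen <- function(screen, n_boot = 5000L, seed = NULL,
                             tie_tol = 0.01) {
  stopifnot(inherits(screen, "combo_screen"))
  min_mis <- min(screen$n_misaligned)
  surv <- screen[screen$n_misaligned == min_mis, , drop = FALSE]
  surv <- dplyr::arrange(surv, .data$face_count, .data$prototype_id)
  combo_key <- sprintf("%d:%s", surv$face_count, surv$prototype_id)
  if (nrow(surv) < 2L) {
    return(list(chosen = surv[1, ], survivors = surv, metrics = NULL,
                ttests = NULL, tie = FALSE,
                note = "single surviving combination; disparity screen skipped"))
  }
  n_axes <- min(vapply(surv$scores, ncol, 1L))
  mats <- lapply(surv$scores, function(m) m[, seq_len(n_axes), drop = FALSE])
  big <- do.call(rbind, mats)
  groups <- rep(combo_key, vapply(mats, nrow, 1L))
  disp <- disparity_indices(big, groups, n_boot = n_boot, seed = seed)
  met <- disp$summary
  hull_med <- setNames(met$boot_median[met$index == "hull"],
                       met$group[met$index == "hull"])
  range_med <- setNames(met$boot_median[met$index == "ranges"],
                        met$group[met$index == "ranges"])
  hull_med <- hull_med[combo_key]
  range_med <- range_med[combo_key]
  best_hull <- min(hull_med)
  cand <- which(hull_med <= best_hull * (1 + tie_tol))
  tie <- FALSE
  if (length(cand) > 1L) {
    best_range <- max(range_med[cand])
    cand2 <- cand[range_med[cand] >= best_range * (1 - tie_tol)]
    tie <- length(cand2) > 1L
    cand <- cand2
  }
  chosen <- surv[cand[1], ]
  list(chosen = chosen, survivors = surv, metrics = met,
       ttests = disparity_ttests(disp), tie = tie,
       note = if (tie) "tied combinations; first by (face_count, prototype_id) chosen"
              else NULL)
}
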