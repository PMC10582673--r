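# End-to-end pipeline driver: outline analysis, surface analysis,
# PERMANOVA, disparity and PGLS, with every table written as CSV plus a
# JSON provenance sidecar. All stochastic stages draw from one generator
# seeded by the run configuration, so reruns are byte-identical.

stage <- function(name, log_con, expr) {
  writeLines(sprintf("[%s] stage %s: start", format(Sys.time(), "%H:%M:%S"),
                     name), log_con)
  res <- tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s: FAILED (%s)", name, conditionMessage(e)),
               log_con)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  writeLines(sprintf("[%s] stage %s: done", format(Sys.time(), "%H:%M:%S"),
                     name), log_con)
  res
}

#' Run the full landmark-free analysis pipeline
#'
#' Chains the 2D outline stage (EFD, normalization, PCA), the 3D surface
#' stage (sampling, generalized alignment, ordination, deviation export),
#' PERMANOVA on both morphospaces, group disparity, and PGLS when a tree is
#' supplied. Stage outputs are written to `out_dir` as CSV/PLY with a JSON
#' provenance sidecar echoing the configuration and seed; a log records
#' every stage. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [run_config()].
#' @param design validated design tibble; analyses use the bone given by
#'   its `side` column.
#' @param outlines named list of contours (or [chaincode]s), one per
#'   specimen id.
#' @param meshes optional named list of [trimesh()] per specimen id.
#' @param tree optional `phylo` covering the design species.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the fitted objects (`efd_space`,
#'   `gpsa_result`, PERMANOVA tables, disparity, PGLS scans) and `out_dir`.
#' @export
run_pipeline <- function(config, design, outlines, meshes = NULL,
                         tree = NULL, out_dir = tempfile("morphfree_run_")) {
  stopifnot(inherits(config, "run_config"))
  design <- validate_design(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  set.seed(config$rng_seed)

  check_cover <- function(x, what) {
    if (is.null(names(x))) abort(sprintf("`%s` must be named by specimen", what))
    missing <- setdiff(design$specimen_id, names(x))
    if (length(missing) > 0)
      abort(sprintf("missing %s for specimen(s): %s", what,
                    paste(missing, collapse = ", ")))
    x[design$specimen_id]
  }
  outlines <- check_cover(outlines, "outline")
  if (!is.null(meshes)) meshes <- check_cover(meshes, "mesh")
  results <- list(out_dir = out_dir)

  # ---- 2D outline stage ---------------------------------------------------
  ms2 <- stage("outline_efd", log_con, {
    efds <- purrr::map(outlines, function(ol)
      normalize_longest_radius(efd(ol, config$n_harmonics)))
    coef_mat <- do.call(rbind, purrr::map(efds, efd_to_vector))
    rownames(coef_mat) <- design$specimen_id
    readr::write_csv(dplyr::bind_cols(tibble(specimen_id = design$specimen_id),
                                      as_tibble(coef_mat)),
                     file.path(out_dir, "efd_coefficients.csv"))
    ms <- efd_pca(coef_mat, ids = design$specimen_id)
    ms <- retain_axes(ms, excluded_pcs = config$excluded_pcs)
    readr::write_csv(tidy(ms, all = TRUE), file.path(out_dir, "efd_scores.csv"))
    wf <- efd_wireframes(ms)
    write_wireframe_svg(wf, file.path(out_dir, "efd_wireframes.svg"))
    ms
  })
  results$efd_space <- ms2

  perm2 <- stage("permanova_2d", log_con, {
    tab <- permanova(retained_scores(ms2), design,
                     n_perm = config$n_permutations,
                     seed = sample.int(2^31 - 1, 1))
    readr::write_csv(tab, file.path(out_dir, "permanova_2d.csv"))
    tab
  })
  results$permanova_2d <- perm2

  # ---- 3D surface stage ---------------------------------------------------
  gps <- NULL
  if (!is.null(meshes)) {
    gps <- stage("surface_gpsa", log_con, {
      sseeds <- sample.int(2^31 - 1, length(meshes))
      samples <- purrr::imap(meshes, function(m, id)
        sample_points(m, config$n_sample_points,
                      seed = sseeds[match(id, names(meshes))]))
      proto <- config$prototype_id %||% design$specimen_id[1]
      res <- suppressWarnings(
        gpsa(samples, proto, allow_scale = config$scale_removal))
      res$morphospace <- retain_axes(res$morphospace,
                                     excluded_pcs = config$excluded_pcs)
      readr::write_csv(tidy(res$morphospace, all = TRUE),
                       file.path(out_dir, "gpsa_scores.csv"))
      readr::write_csv(res$alignments,
                       file.path(out_dir, "alignment_report.csv"))
      deviation_heat_export(res, file.path(out_dir, "deviation_heat.ply"),
                            pcs = utils::head(res$morphospace$retained, 2))
      res
    })
    results$gpsa_result <- gps

    results$permanova_3d <- stage("permanova_3d", log_con, {
      tab <- permanova(retained_scores(gps$morphospace), design,
                       n_perm = config$n_permutations,
                       seed = sample.int(2^31 - 1, 1))
      readr::write_csv(tab, file.path(out_dir, "permanova_3d.csv"))
      tab
    })
  }

  stage("permanova_json", log_con, {
    payload <- list(seed = config$rng_seed,
                    n_permutations = config$n_permutations,
                    permanova_2d = as.data.frame(perm2))
    if (!is.null(results$permanova_3d))
      payload$permanova_3d <- as.data.frame(results$permanova_3d)
    jsonlite::write_json(payload, file.path(out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  # ---- disparity ----------------------------------------------------------
  results$disparity <- stage("disparity", log_con, {
    space <- if (!is.null(gps)) gps$morphospace else ms2
    z <- zscore_scores(retained_scores(space))
    grp <- paste(design$strategy, design$sex, sep = "_")
    disp <- disparity_indices(z, grp, n_boot = config$n_bootstrap,
                              seed = sample.int(2^31 - 1, 1))
    readr::write_csv(disp$summary, file.path(out_dir, "disparity.csv"))
    readr::write_csv(disparity_ttests(disp),
                     file.path(out_dir, "disparity_ttests.csv"))
    disp
  })

  # ---- PGLS ---------------------------------------------------------------
  if (!is.null(tree)) {
    results$pgls_2d <- stage("pgls_2d", log_con, {
      tab <- pgls_scan(retained_scores(ms2), design, tree)
      readr::write_csv(tab, file.path(out_dir, "pgls_2d.csv"))
      tab
    })
    if (!is.null(gps)) {
      results$pgls_3d <- stage("pgls_3d", log_con, {
        tab <- pgls_scan(retained_scores(gps$morphospace), design, tree)
        readr::write_csv(tab, file.path(out_dir, "pgls_3d.csv"))
        tab
      })
    }
  }

  stage("provenance", log_con, {
    write_provenance(file.path(out_dir, "provenance.json"), config,
                     extra = list(n_specimens = nrow(design)))
  })
  invisible(results)
}
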