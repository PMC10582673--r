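# Design tables, trees, run configuration and provenance.

#' Validate a specimen design table
#'
#' Required columns: `specimen_id` (unique), `species`, `sex`
#' (female/male), `strategy` (pelvic/transfer, constant within species),
#' `standard_length` (mm, > 0), `side` (left/right).
#'
#' @param design a data frame.
#' @return The design as a tibble, invisibly usable downstream.
#' @export
validate_design <- function(design) {
  req <- c("specimen_id", "species", "sex", "strategy", "standard_length",
           "side")
  missing <- setdiff(req, names(design))
  if (length(missing) > 0)
    abort(sprintf("design lacks column(s): %s", paste(missing, collapse = ", ")))
  dup <- design$specimen_id[duplicated(design$specimen_id)]
  if (length(dup) > 0)
    abort(sprintf("duplicated specimen_id: %s",
                  paste(unique(dup), collapse = ", ")))
  if (!all(design$sex %in% c("female", "male")))
    abort("`sex` must be 'female' or 'male'")
  if (!all(design$strategy %in% c("pelvic", "transfer")))
    abort("`strategy` must be 'pelvic' or 'transfer'")
  if (!all(design$side %in% c("left", "right")))
    abort("`side` must be 'left' or 'right'")
  bad_sl <- !is.finite(design$standard_length) | design$standard_length <= 0
  if (any(bad_sl))
    abort(sprintf("non-positive standard_length for: %s",
                  paste(design$specimen_id[bad_sl], collapse = ", ")))
  per_sp <- tapply(design$strategy, design$species,
                   function(s) length(unique(s)))
  if (any(per_sp > 1))
    abort(sprintf("strategy not constant within species: %s",
                  paste(names(per_sp)[per_sp > 1], collapse = ", ")))
  as_tibble(design)
}

#' Read a specimen design table from CSV
#'
#' @param path CSV path with a header row.
#' @param quiet suppress the factor-level log message.
#' @return A validated design tibble.
#' @export
read_design <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  d <- validate_design(d)
  if (!quiet)
    inform(sprintf(
      "design: %d specimens, %d species, sex {%s}, strategy {%s}, side {%s}",
      nrow(d), length(unique(d$species)),
      paste(sort(unique(d$sex)), collapse = ","),
      paste(sort(unique(d$strategy)), collapse = ","),
      paste(sort(unique(d$side)), collapse = ",")))
  d
}

#' Read a Newick tree and prune it to the design species
#'
#' Branch lengths are required and must be non-negative; polytomies are
#' preserved as true multifurcations. Tips absent from `species` are
#' dropped (logged).
#'
#' @param path Newick file path.
#' @param species character vector of species to keep; `NULL` keeps all.
#' @param quiet suppress the pruning log message.
#' @return A `phylo`.
#' @export
read_tree <- function(path, species = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort(sprintf("could not parse Newick in %s", path))
  if (is.null(tr$edge.length)) abort("tree has no branch lengths")
  if (any(tr$edge.length < 0)) abort("negative branch length in tree")
  if (!is.null(species)) {
    missing <- setdiff(species, tr$tip.label)
    if (length(missing) > 0)
      abort(sprintf("species missing from tree: %s",
                    paste(missing, collapse = ", ")))
    dropped <- setdiff(tr$tip.label, species)
    if (length(dropped) > 0 && !quiet)
      inform(sprintf("pruned %d tip(s) not in design: %s", length(dropped),
                     paste(dropped, collapse = ", ")))
    tr <- ape::keep.tip(tr, species)
  }
  tr
}

#' Run configuration
#'
#' Bundles every tunable the pipeline uses. Defaults follow the package's
#' standard analysis settings: 26 harmonics, 9999 permutations, 5000
#' bootstrap replicates, 5 alignment repeats, and candidate mesh
#' resolutions of 200k/500k/800k faces (scale these down for quick runs).
#'
#' @param n_harmonics elliptic Fourier harmonics.
#' @param n_permutations PERMANOVA permutations.
#' @param n_bootstrap disparity bootstrap replicates.
#' @param n_alignment_repeats repeats in the consistency screen.
#' @param target_face_counts candidate mesh resolutions.
#' @param rng_seed integer seed recorded in every output artifact.
#' @param scale_removal remove size during surface alignment.
#' @param excluded_pcs PC numbers excluded after broken-stick retention
#'   (e.g. an axis judged to be a preparation artifact).
#' @param n_sample_points surface sample size per specimen.
#' @param prototype_id specimen used as starting prototype (`NULL`: first).
#' @return A `run_config` list.
#' @export
run_config <- function(n_harmonics = 26L, n_permutations = 9999L,
                       n_bootstrap = 5000L, n_alignment_repeats = 5L,
                       target_face_counts = c(200000L, 500000L, 800000L),
                       rng_seed = 1L, scale_removal = TRUE,
                       excluded_pcs = integer(0),
                       n_sample_points = 1500L, prototype_id = NULL) {
  cfg <- list(n_harmonics = as.integer(n_harmonics),
              n_permutations = as.integer(n_permutations),
              n_bootstrap = as.integer(n_bootstrap),
              n_alignment_repeats = as.integer(n_alignment_repeats),
              target_face_counts = as.integer(target_face_counts),
              rng_seed = as.integer(rng_seed),
              scale_removal = isTRUE(scale_removal),
              excluded_pcs = as.integer(excluded_pcs),
              n_sample_points = as.integer(n_sample_points),
              prototype_id = prototype_id)
  counts <- c(cfg$n_harmonics, cfg$n_permutations, cfg$n_bootstrap,
              cfg$n_alignment_repeats, cfg$target_face_counts,
              cfg$n_sample_points)
  if (any(!is.finite(counts)) || any(counts < 1))
    abort("all run_config counts must be positive integers")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys match the `run_config()` arguments.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

write_provenance <- function(path, config, extra = list()) {
  payload <- c(list(config = unclass(config),
                    rng_seed = config$rng_seed,
                    config_hash = rlang::hash(unclass(config)),
                    package_version =
                      as.character(utils::packageVersion("morphfree")),
                    r_version = as.character(getRversion()),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
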