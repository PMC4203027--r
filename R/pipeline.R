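#' Build a pipeline run configuration
#'
#' A single flat configuration object for the simulate -> transform ->
#' coefficients -> estimate -> code -> map chain. All study constants are
#' surfaced as named keys: the 5-degree grids, the 15/75 degree regimes, the
#' movement extents, the 75% confidence level, and the 0.09 rad^-1
#' effectiveness threshold.
#'
#' @param taxa character vector naming the taxa to simulate. Names matching
#'   the [make_fixture_suite()] archetypes, optionally suffixed `_a`, `_b`,
#'   ... (e.g. `longtail_a`), map to that archetype's ground truth.
#' @param seed integer master seed; each taxon derives its own record seed.
#' @param ci_level two-sided confidence level, in (0, 1).
#' @param threshold control-effectiveness threshold, rad^-1 (>= 0).
#' @param window slope-window half-width, degrees.
#' @param replicates recordings per position.
#' @param U,rho,nu air/tunnel properties (m/s, kg/m^3, m^2/s).
#' @param snout_vent,planform_area,sensor_offset model geometry shared by the
#'   synthetic taxa (m, m^2, m 3-vector).
#' @param tree_newick newick string for the mapping phylogeny; NULL to map
#'   onto [fixture_tree()].
#' @return validated list of class `run_config`.
#' @export
run_config <- function(taxa = c("sphere", "weathervane",
                                "longtail_a", "longtail_b",
                                "shorttail_a", "shorttail_b",
                                "shorttail_c", "shorttail_d"),
                       seed = 1, ci_level = 0.75, threshold = 0.09,
                       window = 10, replicates = 5,
                       U = 6, rho = 1.204, nu = 1.5e-5,
                       snout_vent = 0.08, planform_area = 0.02,
                       sensor_offset = c(-0.05, 0, 0),
                       tree_newick = NULL) {
  cfg <- list(taxa = taxa, seed = as.integer(seed), ci_level = ci_level,
              threshold = threshold, window = window,
              replicates = replicates, U = U, rho = rho, nu = nu,
              snout_vent = snout_vent, planform_area = planform_area,
              sensor_offset = sensor_offset, tree_newick = tree_newick)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!length(cfg$taxa)) stop("run_config: no taxa")
  if (!(cfg$ci_level > 0 && cfg$ci_level < 1)) {
    stop("run_config: ci_level must lie in (0, 1)")
  }
  if (cfg$threshold < 0) stop("run_config: threshold must be >= 0")
  if (cfg$window <= 0) stop("run_config: window must be > 0")
  if (cfg$replicates < 1) stop("run_config: replicates must be >= 1")
  if (any(c(cfg$U, cfg$rho, cfg$nu, cfg$snout_vent, cfg$planform_area) <= 0)) {
    stop("run_config: air/geometry values must be > 0")
  }
  invisible(cfg)
}

#' Read a flat key-value configuration file (YAML)
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("read_run_config: unknown keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

truth_for_taxon <- function(name, suite) {
  base <- sub("_[a-z]$", "", name)
  if (!base %in% names(suite)) {
    stop("run_pipeline: no ground truth archetype for taxon '", name, "'")
  }
  rename_truth(suite[[base]], name)
}

#' Run the full analysis chain into a directory
#'
#' Simulates raw records for every configured taxon, reduces them to
#' coefficients, estimates the 8 + 12 derivatives, codes the character
#' matrix, writes it as NEXUS/CSV, reconstructs ancestral states on the
#' phylogeny by unordered parsimony, and writes the mapping report. All
#' intermediate tables are persisted, and `manifest.json` records the seed,
#' a hash of the configuration, and MD5 checksums of every output, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param config a [run_config()] (validated again before any stage runs).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage logging to stderr.
#' @return (invisibly) a list with the run directory, the character matrix,
#'   the reconstructions, and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  design <- build_test_design(replicates = config$replicates, U = config$U,
                              rho = config$rho, nu = config$nu,
                              window = config$window)
  suite <- make_fixture_suite()

  records <- stage("simulate", {
    do.call(rbind, lapply(seq_along(config$taxa), function(i) {
      tx <- config$taxa[i]
      truth <- truth_for_taxon(tx, suite)
      geom <- model_geometry(tx, config$snout_vent, config$planform_area,
                             config$sensor_offset)
      rec <- simulate_records(truth, design, geom, seed = config$seed + i)
      log_("simulate", "%s: %d records", tx, nrow(rec))
      rec
    }))
  })
  write_records_csv(records, file.path(out_dir, "records.csv"))

  coefs <- stage("reduce", {
    bf <- to_com_frame(records)
    geom <- model_geometry("shared", config$snout_vent,
                           config$planform_area, config$sensor_offset)
    coefficient_records(bf, geom)
  })
  utils::write.csv(coefs, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  log_("reduce", "%d coefficient records, Re = %.0f", nrow(coefs),
       reynolds(config$U, config$snout_vent, config$nu))

  est <- stage("estimate", {
    estimate_derivatives(coefs, window = config$window,
                         ci_level = config$ci_level)
  })
  utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  log_("estimate", "%d derivative estimates (%d taxa)", nrow(est),
       length(unique(est$taxon)))

  cm <- stage("code", build_character_matrix(est, config$threshold))
  write_nexus_matrix(cm, file.path(out_dir, "matrix.nex"))
  write_matrix_csv(cm, file.path(out_dir, "matrix_discrete.csv"),
                   file.path(out_dir, "matrix_continuous.csv"))

  tree <- stage("map", {
    if (is.null(config$tree_newick)) fixture_tree() else
      ape::read.tree(text = config$tree_newick)
  })
  extra <- setdiff(tree$tip.label, cm$taxa)
  if (length(extra)) {
    stop("pipeline stage 'map' failed: tree tips without data: ",
         paste(extra, collapse = ", "))
  }
  if (length(setdiff(cm$taxa, tree$tip.label))) {
    keep <- intersect(cm$taxa, tree$tip.label)
    log_("map", "restricting matrix to %d tree tips", length(keep))
  }
  recons <- stage("map", reconstruct_all(tree, cm))
  report <- stage("map", summarize_mapping(recons, tree))
  utils::write.csv(report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  scores <- vapply(recons, function(r) r$score, integer(1))
  log_("map", "parsimony scores: %s", paste(scores, collapse = " "))

  cfg_plain <- unclass(config)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_plain, cfg_path)
  outputs <- c("records.csv", "coefficients.csv", "estimates.csv",
               "matrix.nex", "matrix_discrete.csv", "matrix_continuous.csv",
               "report.csv", "tree.nwk")
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = as.list(tools::md5sum(file.path(out_dir, outputs))),
    stages = c("simulate", "reduce", "estimate", "code", "map")
  )
  names(manifest$files) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = out_dir, matrix = cm, reconstructions = recons,
                 report = report, manifest = manifest))
}
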