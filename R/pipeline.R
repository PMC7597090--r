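# Pipeline orchestration: read -> aggregate -> decompose -> enrich ->
# diagnose -> write, driven by a YAML config with full defaulting, seeded
# determinism and per-stage logging. A thin command-line wrapper lives at
# inst/cli/tmea.R.

config_defaults <- function() {
  list(matrix_path = NULL,
       annotation_path = NULL,
       annotation_format = NULL, # inferred from extension when NULL
       replicate_design_path = NULL,
       aggregate_method = "mean",
       pseudocount = 1,
       normalize_columns = FALSE,
       constraints = c(1L, 2L, 3L),
       b = 10000L,
       seed = 1L,
       min_set_size = 5L,
       sampling_mode = "permutation",
       bh_family = "per_constraint_direction",
       p_estimator = "plain",
       output_dir = "tmea_results")
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config file (or takes a named list), rejects unknown keys,
#' fills every unspecified key with its documented default, and checks
#' value constraints (`b >= 100`, existing input paths, known modes).
#' Constraint indices are range-checked later, after decomposition, when the
#' rank is known.
#'
#' @param config Path to a YAML file, or a named list of config values.
#' @return A fully-defaulted list of class `"tmea_config"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)

  if (is.null(cfg$matrix_path)) stop("matrix_path is required")
  if (is.null(cfg$annotation_path)) stop("annotation_path is required")
  for (key in c("matrix_path", "annotation_path", "replicate_design_path")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop(sprintf("%s does not exist: %s", key, cfg[[key]]))
  }
  if (is.null(cfg$annotation_format)) {
    cfg$annotation_format <- if (grepl("\\.gmt$", cfg$annotation_path,
                                       ignore.case = TRUE)) "gmt" else "mapman"
  }
  if (!cfg$annotation_format %in% c("mapman", "gmt"))
    stop("annotation_format must be 'mapman' or 'gmt'")
  if (!cfg$aggregate_method %in% c("mean", "median"))
    stop("aggregate_method must be 'mean' or 'median'")
  if (!cfg$sampling_mode %in% c("permutation", "bootstrap"))
    stop("sampling_mode must be 'permutation' or 'bootstrap'")
  if (!cfg$bh_family %in% c("per_constraint_direction", "per_constraint",
                            "global"))
    stop("invalid bh_family")
  if (!cfg$p_estimator %in% c("plain", "add_one"))
    stop("p_estimator must be 'plain' or 'add_one'")
  if (cfg$b < 100) stop("b must be >= 100")
  if (cfg$min_set_size < 1) stop("min_set_size must be >= 1")
  if (cfg$pseudocount < 0) stop("pseudocount must be >= 0")
  cfg$constraints <- as.integer(cfg$constraints)
  if (length(cfg$constraints) == 0L || any(cfg$constraints < 1))
    stop("constraints must be a nonempty list of indices >= 1")
  cfg$b <- as.integer(cfg$b)
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_set_size <- as.integer(cfg$min_set_size)
  structure(cfg, class = c("tmea_config", "list"))
}

#' Run the full TMEA pipeline
#'
#' Stages: read abundance matrix; optionally aggregate replicates; optionally
#' scale columns; log-transform; surprisal decomposition; free energy and
#' importance spectrum; weight-sum enrichment; WR/CR profile; write all
#' result tables plus a machine-readable run manifest. Identical config and
#' seed produce byte-identical result files. Any stage failure aborts with a
#' stage-named error.
#'
#' @param config A `tmea_config` from [validate_config()], a config file
#'   path, or a named list.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "tmea_config")) config else
    validate_config(config)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  mat <- stage("read_matrix", read_abundance_matrix(cfg$matrix_path))
  message(sprintf("[read_matrix] %d entities x %d columns", nrow(mat),
                  ncol(mat)))
  if (!is.null(cfg$replicate_design_path)) {
    mat <- stage("aggregate_replicates", {
      ddf <- utils::read.delim(cfg$replicate_design_path, sep = "\t",
                               header = TRUE, colClasses = "character")
      design <- replicate_design(stats::setNames(ddf[[2L]], ddf[[1L]]))
      aggregate_replicates(mat, design, cfg$aggregate_method)
    })
  }
  if (isTRUE(cfg$normalize_columns))
    mat <- stage("normalize_columns", normalize_columns(mat))
  catalog <- stage("read_annotation",
                   if (cfg$annotation_format == "gmt")
                     read_gmt(cfg$annotation_path)
                   else read_mapman_mapping(cfg$annotation_path))
  decomp <- stage("decompose",
                  surprisal_decompose(log_transform(mat, cfg$pseudocount)))
  r <- n_constraints(decomp)
  bad <- cfg$constraints[cfg$constraints > r]
  if (length(bad))
    stop(sprintf(
      "stage 'validate_constraints' failed: constraint index %d exceeds rank %d",
      bad[1L], r), call. = FALSE)

  paths <- list()
  paths$decomposition <- stage("write_decomposition",
                               write_decomposition(decomp, cfg$output_dir))
  fe <- stage("free_energy", free_energy(decomp, mat, cfg$constraints))
  paths$free_energy <- file.path(cfg$output_dir, "free_energy.tsv")
  fedf <- data.frame(constraint = c(rownames(fe$per_constraint), "total"),
                     rbind(format(fe$per_constraint, digits = 10, trim = TRUE,
                                  scientific = FALSE),
                           format(rbind(fe$total), digits = 10, trim = TRUE,
                                  scientific = FALSE)),
                     check.names = FALSE)
  utils::write.table(fedf, paths$free_energy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec <- stage("importance_spectrum", importance_spectrum(decomp))
  paths$importance_spectrum <- file.path(cfg$output_dir,
                                         "importance_spectrum.tsv")
  sdf <- data.frame(
    constraint = seq_along(spec$singular_values) - 1L,
    singular_value = sprintf("%.10g", spec$singular_values),
    relative_loss = c(sprintf("%.10g", spec$relative_losses), ""))
  utils::write.table(sdf, paths$importance_spectrum, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  enr <- stage("enrichment",
               run_tmea(decomp, catalog, cfg$constraints, b = cfg$b,
                        min_set_size = cfg$min_set_size, seed = cfg$seed,
                        sampling = cfg$sampling_mode,
                        bh_family = cfg$bh_family,
                        estimator = cfg$p_estimator))
  paths$enrichment <- file.path(cfg$output_dir, "enrichment.tsv")
  write_enrichment_table(enr, paths$enrichment)

  prof <- stage("wrcr_profile",
                wrcr_profile(decomp, catalog, cfg$constraints,
                             min_set_size = cfg$min_set_size))
  paths$wrcr_profile <- file.path(cfg$output_dir, "wrcr_profile.tsv")
  write_wrcr_profile(prof, paths$wrcr_profile)

  paths$manifest <- file.path(cfg$output_dir, "manifest.json")
  manifest <- list(
    package = "tmea",
    package_version = as.character(utils::packageVersion("tmea")),
    r_version = R.version.string,
    parameters = unclass(cfg),
    inputs = list(
      matrix = list(path = cfg$matrix_path,
                    md5 = unname(tools::md5sum(cfg$matrix_path))),
      annotation = list(path = cfg$annotation_path,
                        md5 = unname(tools::md5sum(cfg$annotation_path)))),
    rank = r,
    n_records = nrow(enr))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  message(sprintf("[done] %d result files in %s", length(unlist(paths)),
                  cfg$output_dir))
  invisible(paths)
}
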