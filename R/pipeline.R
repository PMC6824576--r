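# End-to-end workflow: descriptive group comparison -> correlation PCA and
# residual-subspace split on the aggregated discovery groups -> entropy
# screen of residual parameters (discovery, and validation rows if present)
# -> two-step clustering importance cross-check -> aggregate LOF on the
# corroborated parameters -> k-NN classification with stratified CV.
# Validation rows feed only the entropy stage: they disclose entropy
# trends and never enter PCA, clustering or classification.

pipeline_defaults <- function() {
  list(
    input = NULL,               # path to a cohort file, or NULL to simulate
    generator = "collinear",    # "table2" (independent) or "collinear"
    group_sizes = list(EOP = 68, LOP = 43, VALIDATION = 51),
    contamination = NULL,       # list(target_parameters=, prop=, displacement=, mode=, target_groups=)
    eps = 0.01,                 # PCA eigenvalue threshold
    decimals = 2,               # entropy discretization
    entropy_threshold = 3,
    importance_cutoff = 0.05,
    k_lof = 10,
    k_nn = "auto",              # odd integer or "auto" (CV-selected)
    folds = 10,
    n_preclusters = 20,
    use_entropy_flags_only = FALSE,
    seed = 1L)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file path; unknown keys and
#' out-of-range values are hard errors (nothing is silently ignored), and
#' missing keys are filled with documented defaults.
#'
#' @param config Named list, or path to a YAML/JSON config file, or
#'   \code{NULL} for all defaults.
#' @return Normalized configuration list of class \code{pipeline_config}.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (tolower(tools::file_ext(config)) == "json") {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a named list or a file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop("input file not found: ", cfg$input)
  }
  if (!cfg$generator %in% c("table2", "collinear")) {
    stop("generator must be 'table2' or 'collinear'")
  }
  if (!is.numeric(cfg$eps) || cfg$eps < 0) stop("eps must be >= 0")
  if (!(cfg$decimals %in% 0:6)) stop("decimals must be an integer in 0..6")
  if (!is.numeric(cfg$entropy_threshold) || cfg$entropy_threshold < 0) {
    stop("entropy_threshold must be >= 0")
  }
  if (!is.numeric(cfg$importance_cutoff) || cfg$importance_cutoff < 0 ||
      cfg$importance_cutoff > 1) {
    stop("importance_cutoff must lie in [0, 1]")
  }
  if (!is.numeric(cfg$k_lof) || cfg$k_lof < 1) stop("k_lof must be >= 1")
  if (!identical(cfg$k_nn, "auto")) {
    if (!is.numeric(cfg$k_nn) || cfg$k_nn < 1 || cfg$k_nn %% 2 == 0) {
      stop("k_nn must be 'auto' or a positive odd integer")
    }
  }
  if (!is.numeric(cfg$folds) || cfg$folds < 2) stop("folds must be >= 2")
  if (!is.numeric(cfg$n_preclusters) || cfg$n_preclusters < 2) {
    stop("n_preclusters must be >= 2")
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    stop("seed is mandatory (every stochastic step derives from it)")
  }
  if (is.null(cfg$input)) {
    sz <- unlist(cfg$group_sizes)
    disc <- sz[names(sz) %in% c("EOP", "LOP")]
    if (length(disc) == 2 && cfg$folds > min(disc)) {
      stop("folds (", cfg$folds, ") exceeds the smallest discovery group (",
           min(disc), "); use folds <= ", min(disc))
    }
  }
  if (!is.null(cfg$contamination)) {
    cfg$contamination <- do.call(contamination_spec, cfg$contamination)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full anomaly-detection pipeline
#'
#' Executes, in order: group comparison, PCA residual-subspace split on
#' the aggregated EOP+LOP rows, entropy screen of the residual parameters
#' (discovery rows, and validation rows when present), two-step clustering
#' with predictor importance and corroboration, aggregate LOF over the
#' corroborated parameters and k-NN classification with stratified CV.
#' Every intermediate table is written as CSV plus a JSON run manifest;
#' re-running with the same configuration reproduces every table
#' byte-for-byte (the manifest timestamp excepted).
#'
#' @param config A \code{\link{validate_config}}-accepted configuration
#'   (list, file path or \code{NULL}).
#' @param output_dir Directory for stage outputs (created if needed).
#' @return Invisibly, a list with the cohort, every stage result and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, output_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("immunonoise")),
    r_version = R.version.string,
    seed = cfg$seed, stages = list())
  echo <- unclass(cfg)
  echo$contamination <- if (is.null(cfg$contamination)) NULL else
    unclass(cfg$contamination)
  yaml::write_yaml(echo, file.path(output_dir, "config_echo.yaml"))
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      manifest$timestamp <- format(Sys.time(), usetz = TRUE)
      jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[%s] done in %.2fs", name,
                    manifest$stages[[name]]$seconds))
    value
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$input)) {
      read_cohort(cfg$input)
    } else {
      gc_ <- default_table2_config(
        structure = if (cfg$generator == "collinear") "collinear"
        else "independent",
        contamination = cfg$contamination, seed = cfg$seed)
      gc_$group_sizes <- unlist(cfg$group_sizes)
      generate_cohort(gc_)
    }
  })
  write_cohort(cohort, file.path(output_dir, "cohort.csv"))
  manifest$stages$cohort$output <- "cohort.csv"
  results$cohort <- cohort

  discovery <- subset_by_group(cohort, c("EOP", "LOP"))
  has_validation <- "VALIDATION" %in% cohort$group

  results$group_stats <- stage("group_stats", {
    compare_groups(discovery, "EOP", "LOP")
  })
  manifest$stages$group_stats$output <-
    write_stage_csv(results$group_stats, output_dir, "group_comparison.csv") |>
    basename()

  results$subspace <- stage("pca_subspace", {
    decomp <- pca_subspace(discovery$values)
    split <- split_subspaces(decomp, eps = cfg$eps)
    list(decomposition = decomp, split = split)
  })
  scree <- data.frame(component = seq_along(
    results$subspace$decomposition$eigenvalues),
    eigenvalue = results$subspace$decomposition$eigenvalues,
    cumulative_pct = 100 * results$subspace$decomposition$cumulative_fraction)
  write_stage_csv(scree, output_dir, "scree.csv")
  membership <- data.frame(
    parameter = results$subspace$decomposition$parameters,
    subspace = ifelse(results$subspace$decomposition$parameters %in%
                        results$subspace$split$residual_parameters,
                      "residual", "normal"))
  manifest$stages$pca_subspace$output <-
    write_stage_csv(membership, output_dir, "subspace.csv") |> basename()

  residual <- results$subspace$split$residual_parameters
  results$entropy <- stage("entropy", {
    if (!length(residual)) stop("residual subspace is empty at eps = ", cfg$eps)
    disc_rep <- entropy_screen(discovery, residual, cfg$decimals,
                               cfg$entropy_threshold)
    val_rep <- if (has_validation) {
      entropy_screen(subset_by_group(cohort, "VALIDATION"), residual,
                     cfg$decimals, cfg$entropy_threshold)
    }
    list(discovery = disc_rep, validation = val_rep)
  })
  write_stage_csv(results$entropy$discovery, output_dir,
                  "entropy_discovery.csv")
  manifest$stages$entropy$output <- "entropy_discovery.csv"
  if (has_validation) {
    write_stage_csv(results$entropy$validation, output_dir,
                    "entropy_validation.csv")
  }

  results$clustering <- stage("clustering", {
    z <- standardize(discovery$values[, residual, drop = FALSE])
    assignment <- two_step_cluster(z, n_preclusters = cfg$n_preclusters,
                                   k = 2, seed = cfg$seed)
    if (isTRUE(attr(assignment, "degenerate"))) {
      stop("degenerate input: fewer distinct patients than clusters")
    }
    importance <- predictor_importance(z, assignment)
    corroborated <- anomaly_corroboration(results$entropy$discovery,
                                          importance, cfg$importance_cutoff)
    list(assignment = assignment, importance = importance,
         corroborated = corroborated)
  })
  write_stage_csv(data.frame(patient_id = rownames(discovery$values),
                             cluster = results$clustering$assignment),
                  output_dir, "cluster_assignment.csv")
  manifest$stages$clustering$output <-
    write_stage_csv(results$clustering$importance, output_dir,
                    "cluster_importance.csv") |> basename()

  results$classification <- stage("classification", {
    flagged <- results$entropy$discovery$parameter[
      results$entropy$discovery$flagged]
    feats <- if (cfg$use_entropy_flags_only) {
      flagged
    } else if (length(results$clustering$corroborated)) {
      results$clustering$corroborated
    } else {
      # corroboration can be empty when no parameter falls below the
      # importance cutoff; fall back to the entropy flags alone
      message("corroborated set empty; falling back to entropy flags")
      flagged
    }
    if (!length(feats)) stop("no anomaly parameters to classify on")
    scores <- aggregate_lof(cohort, feats, k_lof = cfg$k_lof)
    k_nn <- if (identical(cfg$k_nn, "auto")) {
      select_k(scores$lof, scores$group, folds = cfg$folds, seed = cfg$seed)
    } else cfg$k_nn
    report <- knn_classify_cv(scores$lof, scores$group, k_nn = k_nn,
                              folds = cfg$folds, seed = cfg$seed)
    list(scores = scores, report = report,
         feature_parameters = feats, k_nn = k_nn)
  })
  write_stage_csv(results$classification$scores, output_dir,
                  "lof_scores.csv")
  rep <- results$classification$report
  jsonlite::write_json(
    list(k_nn = rep$k_nn, k_lof = cfg$k_lof, folds = rep$folds,
         seed = rep$seed, positive = rep$positive,
         feature_parameters = results$classification$feature_parameters,
         apparent = rep$apparent, cv = rep$cv),
    file.path(output_dir, "classification.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$stages$classification$output <- "classification.json"

  manifest$timestamp <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
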