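#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list, checks it against the
#' known schema, fills defaults (B = 1000 bootstraps, 100 Louvain restarts,
#' signed modularity, 100-point penalty grid), and rejects unknown keys by
#' name. `seed` is required: every stochastic stage derives its streams
#' from it.
#'
#' @param config path to a YAML or JSON config file, or a named list.
#' @return A validated `run_config` list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("Config file `%s` not found.", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a file path.")
  defaults <- list(
    input = NULL,            # cohort CSV path (or NULL with `synthetic`)
    synthetic = NULL,        # list(seed = <int>) to simulate the study fixture
    group_column = "group",
    group_levels = NULL,
    node_columns = NULL,
    B = 1000L,
    restarts = 100L,
    modularity = "signed",
    lambda = list(n_lambda = 100L, ratio = 0.01),
    gamma = 0,
    threshold = TRUE,
    refit = TRUE,
    seed = NULL,
    out_dir = "cognet_run",
    figure_format = "png"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$seed)) abort("`seed` is required.")
  if (is.null(cfg$input) && is.null(cfg$synthetic)) {
    abort("Provide either `input` (cohort CSV) or a `synthetic` block.")
  }
  if (!is.numeric(cfg$B) || cfg$B < 1) abort("`B` must be >= 1.")
  if (!is.numeric(cfg$restarts) || cfg$restarts < 1) {
    abort("`restarts` must be >= 1.")
  }
  if (!cfg$modularity %in% c("signed", "absolute")) {
    abort("`modularity` must be \"signed\" or \"absolute\".")
  }
  lam_unknown <- setdiff(names(cfg$lambda), c("n_lambda", "ratio"))
  if (length(lam_unknown) > 0) {
    abort(paste0("Unknown lambda key(s): ", paste(lam_unknown, collapse = ", ")))
  }
  cfg$lambda <- modifyList(list(n_lambda = 100L, ratio = 0.01), cfg$lambda)
  cfg$B <- as.integer(cfg$B)
  cfg$restarts <- as.integer(cfg$restarts)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full group-network pipeline
#'
#' Orchestrates, per group: preprocessing (ratio derivation and listwise
#' deletion), graphical-LASSO network estimation with BIC penalty
#' selection, the full-pipeline bootstrap, edge and centrality percentile
#' intervals, best-of-restarts Louvain community detection, and the
#' co-assignment stability matrix; plus the between-group mean tests and
#' all figures. Every artifact is written under `out_dir` and listed in
#' `manifest.json` together with the config hash and seed, so a run is
#' fully reproducible and re-renderable.
#'
#' @param config a `run_config` (or anything [validate_run_config()]
#'   accepts).
#' @param cohort optional in-memory cohort tibble overriding `config$input`.
#' @return The run directory path, invisibly; the manifest is at
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = log_file, append = TRUE)
    inform(msg)
  }
  stage <- function(name, group, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage `%s` failed for group `%s`: %s",
                    name, group, conditionMessage(e)))
    })
  }

  if (is.null(cohort)) {
    cohort <- if (!is.null(cfg$synthetic)) {
      log_line("simulating study fixture (seed %d)",
               cfg$synthetic$seed %||% cfg$seed)
      make_study_fixture(cfg$synthetic$seed %||% cfg$seed)
    } else {
      log_line("reading cohort from %s", cfg$input)
      readr::read_csv(cfg$input, show_col_types = FALSE)
    }
  }
  cohort <- derive_ratio_scores(cohort)
  scores <- stage("preprocess", "all",
                  split_complete_cases(cohort, cfg$node_columns,
                                       cfg$group_column, cfg$group_levels))
  artifacts <- character(0)
  add <- function(path) artifacts[[length(artifacts) + 1]] <<- path

  all_strength <- list()
  all_edges <- list()
  coas <- list()
  for (g in names(scores)) {
    sm <- scores[[g]]
    log_line("group %s: estimating network (n = %d)", g, sm$n)
    fit <- stage("estimate_network", g,
                 estimate_network(sm, n_lambda = cfg$lambda$n_lambda,
                                  lambda_min_ratio = cfg$lambda$ratio,
                                  gamma = cfg$gamma, threshold = cfg$threshold,
                                  refit = cfg$refit))
    add(write_network_csv(fit, file.path(out, paste0(g, "_network.csv"))))
    add(write_network_graphml(fit, file.path(out, paste0(g, "_network.graphml"))))
    add(write_path_csv(fit, file.path(out, paste0(g, "_path.csv"))))

    log_line("group %s: bootstrap (B = %d, restarts = %d)", g, cfg$B,
             cfg$restarts)
    ens <- stage("bootstrap", g,
                 bootstrap_pipeline(sm, B = cfg$B, restarts = cfg$restarts,
                                    seed = derive_seed(cfg$seed, match(g, names(scores))),
                                    mode = cfg$modularity,
                                    n_lambda = cfg$lambda$n_lambda,
                                    lambda_min_ratio = cfg$lambda$ratio,
                                    gamma = cfg$gamma, threshold = cfg$threshold,
                                  refit = cfg$refit))
    s_ci <- strength_ci(ens, fit)
    e_ci <- edge_ci(ens, fit)
    all_strength[[g]] <- s_ci
    all_edges[[g]] <- e_ci
    readr::write_csv(s_ci, file.path(out, paste0(g, "_strength_ci.csv")))
    add(file.path(out, paste0(g, "_strength_ci.csv")))
    readr::write_csv(e_ci, file.path(out, paste0(g, "_edge_ci.csv")))
    add(file.path(out, paste0(g, "_edge_ci.csv")))

    part <- stage("community", g,
                  best_partition(fit$W, restarts = cfg$restarts,
                                 seed = derive_seed(cfg$seed, 1000 + match(g, names(scores))),
                                 mode = cfg$modularity))
    add(write_partition_csv(part, file.path(out, paste0(g, "_partition.csv"))))
    co <- ensemble_coassignment(ens)
    coas[[g]] <- co
    add(write_coassignment_csv(co, file.path(out, paste0(g, "_coassignment.csv"))))

    for (style in c("circular", "spring")) {
      figpaths <- write_figure(
        plot_network(fit, layout = style, partition = part,
                     seed = cfg$seed),
        file.path(out, paste0(g, "_network_", style)),
        format = cfg$figure_format
      )
      add(figpaths[["image"]]); add(figpaths[["manifest"]])
    }
  }

  log_line("group comparisons (standard stage)")
  gs <- stage("groupstats", "all",
              compare_groups(cohort, cfg$node_columns, cfg$group_column))
  add(write_groupstats_csv(gs, file.path(out, "group_comparisons.csv")))

  figpaths <- write_figure(plot_ci(dplyr::bind_rows(all_strength)),
                           file.path(out, "centrality_ci"),
                           format = cfg$figure_format)
  add(figpaths[["image"]]); add(figpaths[["manifest"]])
  figpaths <- write_figure(plot_ci(dplyr::bind_rows(all_edges)),
                           file.path(out, "edge_ci"),
                           format = cfg$figure_format)
  add(figpaths[["image"]]); add(figpaths[["manifest"]])

  labels <- scores[[1]]$labels
  for (node in labels) {
    figpaths <- write_figure(plot_coassignment(coas, node),
                             file.path(out, paste0("coassignment_", gsub("[^A-Za-z0-9]", "", node))),
                             format = cfg$figure_format)
    add(figpaths[["image"]]); add(figpaths[["manifest"]])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cognet")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    groups = names(scores),
    artifacts = basename(unlist(artifacts))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("run complete: %d artifacts", length(artifacts))
  invisible(out)
}
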