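run_config_schema <- list(
  community = NULL,          # path to site x species CSV (cwm mode)
  traits = NULL,             # path to species x trait CSV (required)
  mode = "cwm",              # "cwm" | "direct"
  delim = ",",
  abundance = "auto",        # "auto" | "abundance" | "presence"
  r_star = 0.2,
  alpha = 0.05,
  rule = "p_and_r",
  signed = "abs",
  within_trait = TRUE,
  p_adjust = "none",
  module_method = "fast_greedy",
  b_null = 1000L,
  b_boot = 1000L,
  seed = NULL,
  out_dir = NULL
)

#' Read and validate a run configuration
#'
#' Flat key/value YAML; unknown keys are errors (a typo must never silently
#' change a threshold), and numeric fields are range-checked. A seed is
#' required whenever a stochastic step (null models, bootstrap, stochastic
#' module detection) can run.
#'
#' @param config path to a YAML file, or a named list of settings.
#' @return A validated, fully populated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a named list.")
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(run_config_schema, config, keep.null = TRUE)
  if (!cfg$mode %in% c("cwm", "direct")) abort("`mode` must be 'cwm' or 'direct'.")
  if (!cfg$rule %in% c("p_and_r", "p_only", "r_only")) abort("invalid `rule`.")
  if (!cfg$signed %in% c("abs", "positive_only")) abort("invalid `signed`.")
  if (!cfg$module_method %in% c("fast_greedy", "louvain", "leiden")) {
    abort("invalid `module_method`.")
  }
  check_scalar_number(cfg$r_star, "r_star", 0, 1)
  check_scalar_number(cfg$alpha, "alpha", 0, 1)
  cfg$b_null <- check_count(cfg$b_null, "b_null")
  cfg$b_boot <- check_count(cfg$b_boot, "b_boot")
  if (is.null(cfg$traits)) abort("`traits` (species x trait CSV path) is required.")
  if (cfg$mode == "cwm" && is.null(cfg$community)) {
    abort("`community` (site x species CSV path) is required in cwm mode.")
  }
  if (is.null(cfg$seed) &&
      (cfg$module_method != "fast_greedy" || cfg$b_null > 0L || cfg$b_boot > 0L)) {
    abort("`seed` is required when any stochastic step is enabled.")
  }
  structure(cfg, class = "run_config")
}

pipeline_observations <- function(cfg) {
  traits <- read_trait_table(cfg$traits, delim = cfg$delim)
  tvm <- expand_traits(traits)
  if (cfg$mode == "cwm") {
    community <- read_site_species(cfg$community, mode = cfg$abundance, delim = cfg$delim)
    compute_cwm(community, tvm, mode = cfg$abundance)
  } else {
    direct_trait_matrix(tvm)
  }
}

pipeline_network <- function(cfg, observations) {
  trait_network(
    observations,
    r_star = cfg$r_star, alpha = cfg$alpha, rule = cfg$rule,
    signed = cfg$signed, within_trait = cfg$within_trait, p_adjust = cfg$p_adjust
  )
}

write_provenance <- function(cfg, net, out_dir, extra = list()) {
  prov <- c(
    list(
      package = "traitnets",
      version = as.character(utils::packageVersion("traitnets")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(cfg),
      steps = c(
        "read species x trait table; one-hot expand categorical traits",
        if (cfg$mode == "cwm") "read site x species matrix; compute community-weighted means"
        else "use species x trait-value matrix directly (no site structure)",
        "pairwise product-moment correlation with t-distribution p-values",
        sprintf("threshold: rule %s, r* = %s, alpha = %s, %s", cfg$rule,
                cfg$r_star, cfg$alpha, cfg$signed),
        "assemble undirected trait network; compute metrics"
      ),
      dropped_nodes = net$provenance$dropped_nodes
    ),
    extra
  )
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  path
}

#' Build a trait network and its metric report from a configuration
#'
#' End-to-end workflow: read inputs, expand traits, compute CWMs (or go
#' direct), correlate, threshold, assemble the network, compute metrics,
#' and write every artifact (GraphML, edge list, node table, metric
#' JSON/CSV, CWM CSV in cwm mode, provenance JSON) to `out_dir`. Input
#' validation failures abort with a diagnostic naming the offending row or
#' column.
#'
#' @param config path to a YAML config or a named list (see
#'   [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list: `config`, `observations`, `network`,
#'   `metrics`, `paths` (files written).
#' @export
run_build <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  say <- function(...) if (!quiet) inform(sprintf(...))
  say("building trait network (%s mode)", cfg$mode)
  obs <- pipeline_observations(cfg)
  say("observations: %d rows x %d trait values", nrow(obs), ncol(obs) - 1L)
  net <- pipeline_network(cfg, obs)
  metrics <- network_metrics(net, module_method = cfg$module_method, seed = cfg$seed)
  say("network: %d nodes, %d edges; Q = %.3f, density = %.3f, centralization = %.3f",
      metrics$summary$n_nodes, metrics$summary$n_edges, metrics$summary$modularity,
      metrics$summary$edge_density, metrics$summary$centralization)

  paths <- character()
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    paths <- export_network(net, cfg$out_dir)
    if (cfg$mode == "cwm") {
      paths[["cwm"]] <- file.path(cfg$out_dir, "cwm.csv")
      write_cwm(obs, paths[["cwm"]])
    }
    paths[["metrics_json"]] <- file.path(cfg$out_dir, "metrics.json")
    jsonlite::write_json(
      c(as.list(metrics$summary),
        list(nodes = metrics$nodes)),
      paths[["metrics_json"]], auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    paths[["metrics_csv"]] <- file.path(cfg$out_dir, "metrics.csv")
    readr::write_csv(metrics$summary, paths[["metrics_csv"]])
    paths[["module_csv"]] <- file.path(cfg$out_dir, "modules.csv")
    readr::write_csv(metrics$nodes[, c("node", "module")], paths[["module_csv"]])
    paths[["provenance"]] <- write_provenance(cfg, net, cfg$out_dir)
    say("wrote %d files to %s", length(paths), cfg$out_dir)
  }
  invisible(list(config = cfg, observations = obs, network = net,
                 metrics = metrics, paths = paths))
}

#' Compare two conditions via bootstrap network ensembles
#'
#' Runs the build pipeline for both configurations, bootstraps each
#' observation set `b_boot` times, and compares every metric between the
#' two ensembles ([compare_groups()]). The two configurations must share
#' all pipeline settings (threshold, rule, mode, replicate counts) —
#' otherwise the comparison would be confounded and is refused. `b_boot`
#' must be at least 2 (with a single replicate per group the tests are
#' undefined).
#'
#' @param config_a,config_b configs for the two groups (YAML paths or
#'   lists); they may differ only in inputs, seed and output directory.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list: `comparison` (a [compare_groups()] tibble),
#'   `ensembles`, `builds`, `paths`.
#' @export
run_compare <- function(config_a, config_b, quiet = FALSE) {
  cfg_a <- read_run_config(config_a)
  cfg_b <- read_run_config(config_b)
  shared <- c("mode", "r_star", "alpha", "rule", "signed", "within_trait",
              "p_adjust", "module_method", "b_boot", "abundance")
  diff <- shared[!vapply(shared, function(k) identical(cfg_a[[k]], cfg_b[[k]]), TRUE)]
  if (length(diff) > 0L) {
    abort(sprintf(
      "pipeline settings differ between the two configs (%s); comparison would be confounded.",
      paste(diff, collapse = ", ")
    ))
  }
  if (cfg_a$b_boot < 2L) {
    abort("`b_boot` must be at least 2: tests are undefined on single-replicate ensembles.")
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  boot_one <- function(cfg, label) {
    obs <- pipeline_observations(cfg)
    say("group %s: %d observations; bootstrapping %d replicates", label, nrow(obs), cfg$b_boot)
    bootstrap_ensemble(
      obs, B = cfg$b_boot, seed = cfg$seed,
      r_star = cfg$r_star, alpha = cfg$alpha, rule = cfg$rule,
      signed = cfg$signed, within_trait = cfg$within_trait, p_adjust = cfg$p_adjust
    )
  }
  ens_a <- boot_one(cfg_a, "A")
  ens_b <- boot_one(cfg_b, "B")
  comparison <- compare_groups(ens_a, ens_b)

  paths <- character()
  out_dir <- cfg_a$out_dir
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths[["comparison_csv"]] <- file.path(out_dir, "comparison.csv")
    readr::write_csv(comparison, paths[["comparison_csv"]])
    paths[["comparison_json"]] <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(comparison, paths[["comparison_json"]],
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths[["replicates_csv"]] <- file.path(out_dir, "bootstrap_replicates.csv")
    readr::write_csv(
      dplyr::bind_rows(A = ens_a$metrics, B = ens_b$metrics, .id = "group"),
      paths[["replicates_csv"]]
    )
    paths[["report"]] <- file.path(out_dir, "comparison.txt")
    withr::with_output_sink(paths[["report"]], print(comparison))
    say("wrote %d files to %s", length(paths), out_dir)
  }
  invisible(list(comparison = comparison,
                 ensembles = list(a = ens_a, b = ens_b),
                 configs = list(a = cfg_a, b = cfg_b), paths = paths))
}

#' Test a configured network against the Erdős–Rényi null
#'
#' Builds the observed network from a configuration, generates `b_null`
#' G(n, m) replicates and reports permutation p-values per metric
#' ([null_test()]); flags metrics with `p < alpha` on either side.
#'
#' @inheritParams run_build
#' @return Invisibly, a list: `build`, `test` (a [null_test()] tibble),
#'   `paths`.
#' @export
run_null_test <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  build <- run_build(cfg, quiet = quiet)
  test <- null_test(build$network, B = cfg$b_null, seed = cfg$seed, alpha = cfg$alpha)
  if (!quiet) {
    for (i in seq_len(nrow(test))) {
      inform(sprintf(
        "%s: observed %.4f vs null %.4f +/- %.4f (p greater %.4g, less %.4g)",
        test$metric[i], test$observed[i], test$null_mean[i], test$null_sd[i],
        test$p_greater[i], test$p_less[i]
      ))
    }
  }
  paths <- character()
  if (!is.null(cfg$out_dir)) {
    paths[["null_test_csv"]] <- file.path(cfg$out_dir, "null_test.csv")
    readr::write_csv(as_tibble(test), paths[["null_test_csv"]])
    paths[["null_test_json"]] <- file.path(cfg$out_dir, "null_test.json")
    jsonlite::write_json(as_tibble(test), paths[["null_test_json"]],
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(build = build, test = test, paths = paths))
}
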