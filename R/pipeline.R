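#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the synthetic-cohort
#' settings (or paths to real inputs), the module-partition settings, the
#' atrophy transform, and the FDR threshold.
#'
#' @param simulation A [sim_config()] describing the cohort to generate;
#'   ignored when `paths` is supplied.
#' @param paths Optional list with `atlas` (region TSV), `cohort` (CSV) and
#'   `connectome_dir` (directory of per-subject-visit connectome CSVs with
#'   JSON side-cars) to run on real data instead of a simulation.
#' @param gammas Resolution parameters for the module-count sensitivity loop
#'   (default `c(0.6, 1, 1.7)`).
#' @param gamma_primary Resolution used for the main analysis (default 1,
#'   classic modularity).
#' @param n_runs Louvain repetitions per consensus partition (default 1000).
#' @param tau Agreement threshold for the consensus (default 0.5).
#' @param consensus `"agreement"` or `"modal"` (see
#'   [consensus_partition()]).
#' @param partition_visits `"baseline"` (default) or `"all"`: which visits
#'   enter the all-participant average network that is partitioned.
#' @param transform Atrophy transform variant (see [transform_score()]).
#' @param q_threshold FDR significance threshold (default 0.05).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            paths = NULL,
                            gammas = c(0.6, 1, 1.7),
                            gamma_primary = 1,
                            n_runs = 1000,
                            tau = 0.5,
                            consensus = c("agreement", "modal"),
                            partition_visits = c("baseline", "all"),
                            transform = c("logistic", "literal"),
                            q_threshold = 0.05,
                            seed = 1L) {
  stopifnot(all(gammas > 0), gamma_primary > 0, n_runs >= 1,
            tau > 0, tau < 1, q_threshold > 0, q_threshold < 1)
  structure(
    list(simulation = simulation, paths = paths,
         gammas = gammas, gamma_primary = gamma_primary,
         n_runs = as.integer(n_runs), tau = tau,
         consensus = match.arg(consensus),
         partition_visits = match.arg(partition_visits),
         transform = match.arg(transform),
         q_threshold = q_threshold, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` mapping is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulation %||% list()
  if (!is.null(sim_args$base_weights)) {
    sim_args$base_weights <- unlist(sim_args$base_weights)
  }
  if (!is.null(sim_args$edge_density)) {
    sim_args$edge_density <- unlist(sim_args$edge_density)
  }
  if (!is.null(sim_args$rate_coeffs)) {
    sim_args$rate_coeffs <- unlist(sim_args$rate_coeffs)
  }
  raw$simulation <- do.call(sim_config, sim_args)
  do.call(pipeline_config, raw)
}

load_dataset_from_paths <- function(paths) {
  atlas <- read_region_table(paths$atlas)
  cohort <- read_cohort(paths$cohort)
  files <- list.files(paths$connectome_dir, pattern = "\\.(csv|tsv)$",
                      full.names = TRUE)
  observations <- lapply(files, read_connectome, atlas = atlas)
  long_dataset(atlas, observations, cohort)
}

#' Run the full length-atrophy analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), all-participant
#' average network construction, consensus module partitioning at each
#' resolution in `gammas` (the `gamma_primary` partition drives the rest),
#' connection subtype classification and aggregation, per-connection
#' longitudinal mixed-effects group contrasts with per-subtype FDR, the
#' edge-level atrophy table on the baseline control-average network, the
#' length-atrophy Spearman correlations (cross-sectional and longitudinal),
#' and the subtype path-length ANOVA with Tukey-Kramer post-hoc
#' comparisons. Re-running with the same configuration reproduces all
#' numbers exactly.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`: a list with elements
#'   `config`, `dataset`, `truth` (when simulated), `partitions` (one
#'   [consensus_partition()] glance per gamma plus the primary partition),
#'   `connections`, `subtype_counts`, `models`, `atrophy`, `correlation`
#'   (tidied cross-sectional and longitudinal results), `anova`, `tukey`,
#'   and `reconciliation` (pair counts).
#' @export
run_pipeline <- function(config) {
  stage <- function(name) message("[", name, "] ", appendLF = FALSE)

  stage("data")
  if (!is.null(config$paths)) {
    dataset <- load_dataset_from_paths(config$paths)
    truth <- NULL
  } else {
    sim <- config$simulation
    sim$seed <- child_seed(config$seed, "simulate")
    out <- simulate_cohort(sim)
    dataset <- out$dataset
    truth <- out$truth
  }
  atlas <- dataset$atlas
  message(length(dataset$observations), " observations, ",
          nrow(atlas), " regions")

  stage("partition")
  visits <- if (config$partition_visits == "baseline") 1L else NULL
  W_avg <- average_connectomes(dataset, visits = visits)
  cort <- atlas$tissue_class == "cortical"
  W_cort <- W_avg[cort, cort]
  partitions <- lapply(config$gammas, function(g) {
    consensus_partition(W_cort, gamma = g, n_runs = config$n_runs,
                        tau = config$tau,
                        seed = child_seed(config$seed, paste0("partition", g)),
                        method = config$consensus)
  })
  names(partitions) <- paste0("gamma_", config$gammas)
  primary_idx <- which(config$gammas == config$gamma_primary)
  partition <- if (length(primary_idx) == 1) {
    partitions[[primary_idx]]
  } else {
    consensus_partition(W_cort, gamma = config$gamma_primary,
                        n_runs = config$n_runs, tau = config$tau,
                        seed = child_seed(config$seed, "partition_primary"),
                        method = config$consensus)
  }
  message(partition$n_modules, " modules at gamma ", config$gamma_primary)

  stage("classify")
  connections <- enumerate_subtype_connections(atlas, partition)
  subtype_counts <- dplyr::count(connections, .data$subtype,
                                 name = "n_connections")
  message(nrow(connections), " subtype connections")

  stage("model")
  strengths <- subtype_strength_table(dataset, connections)
  long_tab <- build_long_table(dataset, strengths)
  models <- fit_subtype_models(long_tab)
  message(nrow(models), " effect tests")

  stage("atrophy")
  atab <- atrophy_table(dataset, partition, transform = config$transform)
  message(nrow(atab), " region-pair connections")

  stage("correlate")
  cor_cross <- length_atrophy_correlation(atab$L, atab$score_cross)
  cor_long <- length_atrophy_correlation(atab$L, atab$score_long)
  aov_tab <- anova_subtypes(atab)
  tukey <- tukey_kramer(atab)
  message("rho_cross = ", format(cor_cross$rho, digits = 3),
          ", rho_long = ", format(cor_long$rho, digits = 3))

  structure(
    list(
      config = config, dataset = dataset, truth = truth,
      partitions = dplyr::bind_rows(lapply(partitions, glance)),
      partition = partition,
      connections = connections, subtype_counts = subtype_counts,
      models = models, atrophy = atab,
      correlation = dplyr::bind_rows(
        cross_sectional = tidy(cor_cross),
        longitudinal = tidy(cor_long), .id = "analysis"
      ),
      anova = aov_tab, tukey = tukey,
      reconciliation = tibble::tibble(
        n_pairs_expected = count_connection_level_pairs(atlas),
        n_pairs_analyzed = cor_cross$n,
        n_excluded = cor_cross$n_excluded
      )
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  partitions (module count per gamma):\n")
  print(as.data.frame(x$partitions[, c("gamma", "n_modules", "Q")]),
        row.names = FALSE, digits = 3)
  cat("  subtype connections:\n")
  print(as.data.frame(x$subtype_counts), row.names = FALSE)
  cat("  length-atrophy correlation:\n")
  print(as.data.frame(x$correlation), row.names = FALSE, digits = 3)
  cat("  subtype path-length ANOVA: F(", x$anova$df1, ",", x$anova$df2,
      ") = ", format(x$anova$F_value, digits = 5), "\n", sep = "")
  sig <- sum(x$models$q_value < x$config$q_threshold)
  cat("  mixed-model effects with q <", x$config$q_threshold, ":", sig,
      "of", nrow(x$models), "\n")
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' Writes the report's tables as CSVs plus a JSON summary into a directory.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$models, file.path(dir, "models.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(report$atrophy),
                   file.path(dir, "atrophy.csv"), progress = FALSE)
  readr::write_csv(report$tukey, file.path(dir, "tukey.csv"), progress = FALSE)
  readr::write_csv(report$partition$assignment,
                   file.path(dir, "partition.csv"), progress = FALSE)
  summary <- list(
    seed = report$config$seed,
    partitions = report$partitions[, c("gamma", "n_modules", "Q")],
    subtype_counts = report$subtype_counts,
    correlation = report$correlation,
    anova = report$anova,
    reconciliation = report$reconciliation
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
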