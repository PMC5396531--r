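#' Configuration for the synthetic longitudinal connectome cohort
#'
#' Defines the study conditions the generator emulates: a two-group
#' (control vs premanifest HD) cohort followed over three annual visits, on a
#' parcellation of 70 cortical regions (3 planted modules per hemisphere) and
#' 4 striatal regions, with connection strengths that in the preHD group
#' decline at rates increasing with topological path length.
#'
#' @param n_controls,n_preHD Number of subjects per group. Defaults 85 / 82
#'   echo the per-visit maxima of the emulated cohort.
#' @param n_visits Number of annual visits (default 3; times 0, 1, 2 years).
#' @param modules_per_hemisphere Planted cortical modules per hemisphere
#'   (default 3, i.e. 6 modules).
#' @param n_cortical Total cortical regions, split as evenly as possible
#'   across the planted modules (default 70, must be even).
#' @param cortical_per_module If given, overrides `n_cortical` with
#'   `2 * modules_per_hemisphere * cortical_per_module` equally sized modules.
#' @param n_striatal Striatal regions, alternately assigned to hemispheres
#'   (default 4: caudate and putamen bilaterally).
#' @param base_weights Named mean edge weight per connection subtype, on the
#'   original (not log) scale. The default hierarchy intramodular >
#'   intrahemispheric > interhemispheric > cortico_striatal plants both the
#'   modular structure and the path-length ordering in which cortico-striatal
#'   connections are topologically longest.
#' @param edge_density Named per-subtype probability that a region pair
#'   receives an edge. Defaults to 1 (a full weighted connectome, as produced
#'   by SIFT2-style weighting without graph thresholding).
#' @param noise_sd SD of multiplicative log-normal noise, applied per edge
#'   per visit and also as the edge-level jitter of the base network.
#' @param baseline_deficit Cross-sectional log-scale strength reduction in
#'   preHD per unit of true path length (lambda; default 0.2).
#' @param rate_coeffs Named `c(kappa0=, kappa1=)`: preHD per-year log-scale
#'   decline is `kappa0 + kappa1 * L` for a connection with true path length
#'   `L` (defaults 0.02 and 0.05).
#' @param covariate_effects List of log-scale multiplicative covariate
#'   effects on global connection strength: `age` (per year from the cohort
#'   mean of 45), `sex_F` (female vs male), `site` (vector of per-site
#'   offsets, recycled over sites).
#' @param subject_intercept_sd,subject_slope_sd SDs of per-subject log-scale
#'   random intercepts and per-year random slopes (global scaling factors).
#' @param missing_visit_prob Probability that each visit after the first is
#'   missing, independently per subject-visit (visit 1 is always kept).
#' @param cognition_coupling Correlation-like weight in `[0,1]` linking the
#'   standardized baseline interhemispheric strength to the simulated global
#'   cognitive composite.
#' @param seed Integer master seed; every random stage derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 85L,
                       n_preHD = 82L,
                       n_visits = 3L,
                       modules_per_hemisphere = 3L,
                       n_cortical = 70L,
                       cortical_per_module = NULL,
                       n_striatal = 4L,
                       base_weights = c(intramodular = 20, intrahemispheric = 4,
                                        interhemispheric = 1.5,
                                        cortico_striatal = 0.8),
                       edge_density = c(intramodular = 1, intrahemispheric = 1,
                                        interhemispheric = 1, cortico_striatal = 1),
                       noise_sd = 0.1,
                       baseline_deficit = 0.2,
                       rate_coeffs = c(kappa0 = 0.02, kappa1 = 0.05),
                       covariate_effects = list(age = -0.005, sex_F = -0.02,
                                                site = c(0, 0.03, -0.03, 0.01)),
                       subject_intercept_sd = 0.05,
                       subject_slope_sd = 0.02,
                       missing_visit_prob = 0.15,
                       cognition_coupling = 0.5,
                       seed = 1L) {
  if (!is.null(cortical_per_module)) {
    n_cortical <- 2L * as.integer(modules_per_hemisphere) *
      as.integer(cortical_per_module)
  }
  cfg <- list(
    n_controls = as.integer(n_controls), n_preHD = as.integer(n_preHD),
    n_visits = as.integer(n_visits),
    modules_per_hemisphere = as.integer(modules_per_hemisphere),
    n_cortical = as.integer(n_cortical), n_striatal = as.integer(n_striatal),
    base_weights = base_weights, edge_density = edge_density,
    noise_sd = noise_sd, baseline_deficit = baseline_deficit,
    rate_coeffs = rate_coeffs, covariate_effects = covariate_effects,
    subject_intercept_sd = subject_intercept_sd,
    subject_slope_sd = subject_slope_sd,
    missing_visit_prob = missing_visit_prob,
    cognition_coupling = cognition_coupling,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_controls >= 1, cfg$n_preHD >= 1, cfg$n_visits >= 1,
    cfg$modules_per_hemisphere >= 1, cfg$n_cortical >= 2,
    cfg$n_cortical %% 2 == 0, cfg$n_striatal >= 0,
    all(c("intramodular", "intrahemispheric", "interhemispheric",
          "cortico_striatal") %in% names(cfg$base_weights)),
    all(cfg$base_weights > 0),
    all(cfg$edge_density >= 0 & cfg$edge_density <= 1),
    cfg$noise_sd >= 0,
    all(c("kappa0", "kappa1") %in% names(cfg$rate_coeffs)),
    cfg$missing_visit_prob >= 0, cfg$missing_visit_prob <= 1,
    cfg$cognition_coupling >= 0, cfg$cognition_coupling <= 1,
    cfg$subject_intercept_sd >= 0, cfg$subject_slope_sd >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

# deterministic child seed for a named stage, derived from a master seed
child_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 1009 + h * 7919) %% 2147483629)
}

#' Generate a synthetic region atlas with planted cortical modules
#'
#' Cortical regions are split evenly into `2 * modules_per_hemisphere`
#' contiguous module blocks (left-hemisphere modules first); striatal regions
#' alternate hemispheres. The planted module assignment is attached as the
#' `"planted_modules"` attribute (a tibble with `region_id`, `name`,
#' `module`).
#'
#' @param config A [sim_config()].
#' @return A [region_atlas] with the `planted_modules` attribute.
#' @export
simulate_atlas <- function(config) {
  mph <- config$modules_per_hemisphere
  per_hemi <- config$n_cortical / 2L
  sizes <- rep(per_hemi %/% mph, mph)
  extra <- per_hemi %% mph
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rows <- list()
  module <- integer(0)
  for (h_idx in seq_along(c("L", "R"))) {
    h <- c("L", "R")[h_idx]
    for (m in seq_len(mph)) {
      mod_global <- (h_idx - 1L) * mph + m
      nm <- sprintf("ctx_%s_m%d_%02d", h, m, seq_len(sizes[m]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = nm, hemisphere = h, tissue_class = "cortical"
      )
      module <- c(module, rep(mod_global, sizes[m]))
    }
  }
  if (config$n_striatal > 0) {
    str_names <- if (config$n_striatal == 4L) {
      c("caudate_L", "putamen_L", "caudate_R", "putamen_R")
    } else {
      sprintf("striatal_%s_%d", rep(c("L", "R"), length.out = config$n_striatal),
              seq_len(config$n_striatal))
    }
    str_hemi <- rep(c("L", "R"), length.out = config$n_striatal)
    if (config$n_striatal == 4L) str_hemi <- c("L", "L", "R", "R")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = str_names, hemisphere = str_hemi, tissue_class = "striatal"
    )
  }
  atlas <- region_atlas(dplyr::bind_rows(rows))
  cortical <- atlas[atlas$tissue_class == "cortical", ]
  attr(atlas, "planted_modules") <- tibble::tibble(
    region_id = cortical$region_id, name = cortical$name, module = module
  )
  atlas
}

# subtype of every unordered region pair under the planted partition
pair_subtypes_from_planted <- function(atlas, planted) {
  module_of <- rep(NA_integer_, nrow(atlas))
  module_of[planted$region_id + 1L] <- planted$module
  classify_pair_matrix(atlas, module_of)
}

#' Generate the noiseless-template base network
#'
#' Draws a symmetric base network `B`: each included region pair gets weight
#' `base_weight[subtype] * exp(noise_sd * z)` with `z ~ N(0, 1)`, edges kept
#' with per-subtype probability `edge_density`. Striatal-striatal pairs are
#' never connected (they are excluded from all analyses). If the resulting
#' graph is disconnected, a minimal backbone of weakest-subtype edges joins
#' the components so that all path lengths are finite.
#'
#' True path lengths `L*` are computed once from `B` (inverse-weight
#' Dijkstra), so "true" topological length is well-defined independent of
#' per-visit sampling noise.
#'
#' @param config A [sim_config()].
#' @param atlas Atlas from [simulate_atlas()] (regenerated if omitted).
#' @return A list of class `sim_ground_truth` with elements `atlas`,
#'   `partition` (planted module tibble), `B`, `L_star`, `rate`
#'   (matrix of true per-year preHD log-decline rates,
#'   `-(kappa0 + kappa1 * L*)` on included pairs), and `config`.
#' @export
simulate_base_network <- function(config, atlas = NULL) {
  if (is.null(atlas)) atlas <- simulate_atlas(config)
  planted <- attr(atlas, "planted_modules")
  set.seed(child_seed(config$seed, "base_network"))
  n <- nrow(atlas)
  subtype <- pair_subtypes_from_planted(atlas, planted)
  B <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
  ut <- which(upper.tri(B))
  st <- subtype[ut]
  included <- !is.na(st) & st != "excluded"
  base_w <- config$base_weights[st[included]]
  dens <- config$edge_density[st[included]]
  keep <- stats::runif(sum(included)) <= dens
  w <- base_w * exp(config$noise_sd * stats::rnorm(sum(included)))
  w[!keep] <- 0
  B[ut[included]] <- w
  B <- B + t(B)
  # connect components through weakest-subtype backbone edges if needed
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  while (comp$no > 1) {
    a <- which(comp$membership == 1)[1]
    b <- which(comp$membership == 2)[1]
    B[a, b] <- B[b, a] <- min(config$base_weights)
    g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    comp <- igraph::components(g)
  }
  L_star <- path_length_matrix(B)
  k0 <- config$rate_coeffs[["kappa0"]]
  k1 <- config$rate_coeffs[["kappa1"]]
  rate <- -(k0 + k1 * L_star)
  rate[!is.finite(L_star)] <- NA_real_
  diag(rate) <- 0
  structure(
    list(atlas = atlas, partition = planted, B = B, L_star = L_star,
         rate = rate, config = config),
    class = "sim_ground_truth"
  )
}

#' Generate a synthetic longitudinal two-group connectome cohort
#'
#' Control observations are `W_ij(t) = B_ij * exp(eta_i(t) + eps)`, preHD
#' observations additionally decay as
#' `exp(-lambda * L*_ij - (kappa0 + kappa1 * L*_ij) * t)`, where `lambda` is
#' the cross-sectional baseline deficit per unit path length, the rate term
#' makes topologically longer connections degenerate faster, `eta_i(t)`
#' collects subject-level covariate effects plus random intercept/slope, and
#' `eps ~ N(0, noise_sd^2)` is per-edge per-visit log-normal noise.
#' Degeneration acts on the log scale and linearly in time, so weights stay
#' positive and per-subject least-squares slopes estimate the planted rates.
#'
#' Each visit after the first is dropped independently with probability
#' `missing_visit_prob`. The simulated global cognitive composite is the
#' standardized baseline total interhemispheric strength mixed with
#' independent noise at weight `cognition_coupling`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a [long_dataset]) and `truth`
#'   (the `sim_ground_truth` from [simulate_base_network()]).
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_base_network(config)
  atlas <- truth$atlas
  n <- nrow(atlas)
  set.seed(child_seed(config$seed, "cohort"))

  n_tot <- config$n_controls + config$n_preHD
  cohort <- tibble::tibble(
    subject_id = c(sprintf("ctrl_%03d", seq_len(config$n_controls)),
                   sprintf("preHD_%03d", seq_len(config$n_preHD))),
    group = rep(c("control", "preHD"), c(config$n_controls, config$n_preHD)),
    age = round(pmin(pmax(stats::rnorm(n_tot, 45, 8), 23), 64), 1),
    sex = sample(c("M", "F"), n_tot, replace = TRUE),
    site = sample(paste0("site_", seq_along(config$covariate_effects$site)),
                  n_tot, replace = TRUE),
    education = sample(1:6, n_tot, replace = TRUE),
    CAG = ifelse(rep(c(FALSE, TRUE), c(config$n_controls, config$n_preHD)),
                 sample(40:48, n_tot, replace = TRUE), NA_integer_)
  )

  eff <- config$covariate_effects
  site_idx <- as.integer(sub("site_", "", cohort$site))
  cov_shift <- eff$age * (cohort$age - 45) +
    eff$sex_F * (cohort$sex == "F") + eff$site[site_idx]
  u_int <- stats::rnorm(n_tot, 0, config$subject_intercept_sd)
  u_slp <- stats::rnorm(n_tot, 0, config$subject_slope_sd)

  ut <- which(upper.tri(truth$B) & truth$B > 0)
  logB_ut <- log(truth$B[ut])
  L_ut <- truth$L_star[ut]
  lam <- config$baseline_deficit
  k0 <- config$rate_coeffs[["kappa0"]]
  k1 <- config$rate_coeffs[["kappa1"]]

  # visit schedule: first visit always observed
  kept <- matrix(TRUE, n_tot, config$n_visits)
  if (config$n_visits > 1) {
    kept[, -1] <- stats::runif(n_tot * (config$n_visits - 1)) >=
      config$missing_visit_prob
  }

  observations <- vector("list", sum(kept))
  k <- 0L
  for (s in seq_len(n_tot)) {
    is_hd <- cohort$group[s] == "preHD"
    for (v in seq_len(config$n_visits)) {
      if (!kept[s, v]) next
      t_yr <- v - 1L
      mu <- logB_ut + cov_shift[s] + u_int[s] + u_slp[s] * t_yr
      if (is_hd) mu <- mu - lam * L_ut - (k0 + k1 * L_ut) * t_yr
      w_ut <- exp(mu + config$noise_sd * stats::rnorm(length(ut)))
      W <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
      W[ut] <- w_ut
      W <- W + t(W)
      k <- k + 1L
      observations[[k]] <- connectome_obs(cohort$subject_id[s], v, W,
                                          atlas = atlas)
    }
  }

  # cognitive composite from baseline interhemispheric strength
  inter_ut <- which(pair_subtypes_from_planted(atlas, truth$partition)[ut] ==
                      "interhemispheric")
  base_obs_idx <- match(cohort$subject_id,
                        vapply(observations, function(o)
                          if (o$visit == 1L) o$subject_id else NA_character_,
                          character(1)))
  inter_strength <- vapply(observations[base_obs_idx], function(o)
    sum(o$W[ut][inter_ut]), numeric(1))
  z_inter <- as.numeric(scale(log(inter_strength)))
  rho <- config$cognition_coupling
  cohort$cognition <- rho * z_inter +
    sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_tot)

  dataset <- long_dataset(atlas, observations, cohort)
  list(dataset = dataset, truth = truth)
}
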