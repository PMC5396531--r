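subtype_levels <- c("intramodular", "intrahemispheric", "interhemispheric",
                    "cortico_striatal")

# module id per region (NA for striatal), from a module_partition, a named
# vector, or a tibble(name/region_id, module)
module_lookup <- function(atlas, partition) {
  if (inherits(partition, "module_partition")) partition <- partition$assignment
  if (is.data.frame(partition)) {
    module_of <- rep(NA_integer_, nrow(atlas))
    if ("region_id" %in% names(partition)) {
      module_of[match(partition$region_id, atlas$region_id)] <- partition$module
    } else {
      module_of[match(partition$name, atlas$name)] <- partition$module
    }
  } else if (!is.null(names(partition))) {
    module_of <- as.integer(partition[atlas$name])
  } else {
    stop("partition must be a module_partition, a data frame, or a named vector",
         call. = FALSE)
  }
  missing_cortical <- atlas$tissue_class == "cortical" & is.na(module_of)
  if (any(missing_cortical)) {
    stop("partition does not cover cortical region(s): ",
         paste(utils::head(atlas$name[missing_cortical], 3), collapse = ", "),
         call. = FALSE)
  }
  module_of
}

# n x n character matrix of subtypes given per-region module ids
classify_pair_matrix <- function(atlas, module_of) {
  n <- nrow(atlas)
  is_str <- atlas$tissue_class == "striatal"
  hemi <- atlas$hemisphere
  out <- matrix(NA_character_, n, n, dimnames = list(atlas$name, atlas$name))
  str_i <- outer(is_str, is_str, `&`)
  cs <- outer(is_str, !is_str, `&`) | outer(!is_str, is_str, `&`)
  same_mod <- outer(module_of, module_of, `==`)
  same_hemi <- outer(hemi, hemi, `==`)
  cc <- outer(!is_str, !is_str, `&`)
  out[cc & same_mod] <- "intramodular"
  out[cc & !same_mod & same_hemi] <- "intrahemispheric"
  out[cc & !same_hemi] <- "interhemispheric"
  out[cs] <- "cortico_striatal"
  out[str_i] <- "excluded"
  diag(out) <- NA_character_
  out
}

#' Classify a region pair into a connection subtype
#'
#' The four-way classification of white matter connections: a
#' striatal-cortical pair is `cortico_striatal` (regardless of hemisphere
#' crossing); a cortical pair within one module is `intramodular`; between
#' modules in the same hemisphere, `intrahemispheric`; between hemispheres,
#' `interhemispheric`. Striatal-striatal pairs are `excluded` (connections
#' within the striatum are not analyzed). Symmetric in `i` and `j`.
#'
#' @param i,j Region ids (0-based integers) or region names; `i != j`.
#' @param atlas A [region_atlas].
#' @param partition A [consensus_partition()] result (or an assignment tibble
#'   / named vector) covering all cortical regions.
#' @return One of `"cortico_striatal"`, `"interhemispheric"`,
#'   `"intrahemispheric"`, `"intramodular"`, `"excluded"`.
#' @export
classify_pair <- function(i, j, atlas, partition) {
  idx <- function(x) {
    pos <- if (is.character(x)) match(x, atlas$name) else match(x, atlas$region_id)
    if (is.na(pos)) stop("unknown region: ", x, call. = FALSE)
    pos
  }
  pi <- idx(i)
  pj <- idx(j)
  if (pi == pj) stop("i and j must differ", call. = FALSE)
  module_of <- module_lookup(atlas, partition)
  classify_pair_matrix(atlas, module_of)[pi, pj]
}

#' All analyzed region pairs with their subtype labels
#'
#' Enumerates every cortical-cortical and striatal-cortical region pair
#' (striatal-striatal pairs are excluded by construction), labelled with the
#' connection subtype and the module-level endpoints used for aggregation
#' (striatal regions are pooled into a single `"STR"` endpoint).
#'
#' @inheritParams classify_pair
#' @return Tibble with columns `i`, `j` (0-based region ids, `i < j`),
#'   `name_i`, `name_j`, `subtype`, `endpoint_1`, `endpoint_2`, `connection`.
#' @export
connection_pairs <- function(atlas, partition) {
  module_of <- module_lookup(atlas, partition)
  sub_m <- classify_pair_matrix(atlas, module_of)
  ut <- which(upper.tri(sub_m), arr.ind = TRUE)
  lab <- sub_m[upper.tri(sub_m)]
  keep <- !is.na(lab) & lab != "excluded"
  ut <- ut[keep, , drop = FALSE]
  lab <- lab[keep]
  ep <- function(pos) {
    ifelse(atlas$tissue_class[pos] == "striatal", "STR",
           paste0("M", module_of[pos]))
  }
  e1 <- ep(ut[, 1])
  e2 <- ep(ut[, 2])
  # order endpoints canonically: STR first, then module number
  mnum <- function(e) {
    out <- rep(-1L, length(e))
    m <- e != "STR"
    out[m] <- as.integer(sub("M", "", e[m]))
    out
  }
  swap <- mnum(e1) > mnum(e2)
  tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  tibble::tibble(
    i = atlas$region_id[ut[, 1]], j = atlas$region_id[ut[, 2]],
    name_i = atlas$name[ut[, 1]], name_j = atlas$name[ut[, 2]],
    subtype = factor(lab, levels = subtype_levels),
    endpoint_1 = e1, endpoint_2 = e2,
    connection = paste0(substr(lab, 1, 5), ":", e1, "-", e2)
  )
}

#' Enumerate module-level subtype connections
#'
#' Groups the analyzed region pairs into module-level connections: one
#' cortico-striatal connection per cortical module (striatum pooled across
#' hemispheres), one interhemispheric connection per cross-hemisphere module
#' pair, one intrahemispheric connection per within-hemisphere module pair,
#' and one intramodular connection per module. For 3 modules per hemisphere
#' and a non-empty striatum this yields 6 + 9 + 6 + 6 = 27 connections.
#'
#' @inheritParams classify_pair
#' @return Tibble with one row per subtype connection: `connection`,
#'   `subtype`, `endpoint_1`, `endpoint_2`, `n_pairs`, and `pairs` (a
#'   list-column of member region-pair tibbles).
#' @export
enumerate_subtype_connections <- function(atlas, partition) {
  connection_pairs(atlas, partition) |>
    dplyr::group_by(.data$connection, .data$subtype, .data$endpoint_1,
                    .data$endpoint_2) |>
    tidyr::nest(pairs = c("i", "j", "name_i", "name_j")) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_pairs = vapply(.data$pairs, nrow, integer(1))) |>
    dplyr::arrange(.data$subtype, .data$endpoint_1, .data$endpoint_2)
}

#' Aggregate connection strength over member region pairs
#'
#' The strength of a module-level connection is the sum of the weights of
#' its member region pairs.
#'
#' @param W Connectivity matrix over the atlas.
#' @param pairs Data frame with 0-based columns `i`, `j` (one member region
#'   pair per row).
#' @return Summed strength (a single number).
#' @export
aggregate_strength <- function(W, pairs) {
  sum(W[cbind(pairs$i + 1L, pairs$j + 1L)])
}

#' Per-observation strengths of all subtype connections
#'
#' @param dataset A [long_dataset].
#' @param connections Result of [enumerate_subtype_connections()].
#' @return Long tibble: `subject_id`, `visit`, `connection`, `subtype`,
#'   `strength`.
#' @export
subtype_strength_table <- function(dataset, connections) {
  idx <- lapply(connections$pairs, function(p) cbind(p$i + 1L, p$j + 1L))
  purrr::map_dfr(dataset$observations, function(o) {
    tibble::tibble(
      subject_id = o$subject_id, visit = o$visit,
      connection = connections$connection, subtype = connections$subtype,
      strength = vapply(idx, function(ix) sum(o$W[ix]), numeric(1))
    )
  })
}

#' Voxel-connectivity-profile thresholding and volume normalization
#'
#' Standalone arithmetic of the VCP connectivity estimate: a striatal voxel
#' counts as connected to a cortical target if at least `threshold` (default
#' 1%, inclusive) of its streamlines reach that target; the count of
#' connected voxels is normalized by the summed seed and target volumes.
#'
#' @param voxel_fractions Numeric vector in `[0, 1]`: per-voxel fraction of
#'   streamlines reaching the target.
#' @param vol_seed,vol_target Seed and target region volumes in mm^3 (> 0).
#' @param threshold Connection threshold on the streamline fraction.
#' @return Normalized connectivity (units 1/mm^3).
#' @export
vcp_normalize <- function(voxel_fractions, vol_seed, vol_target,
                          threshold = 0.01) {
  if (any(voxel_fractions < 0 | voxel_fractions > 1)) {
    stop("voxel fractions must lie in [0, 1]", call. = FALSE)
  }
  if (vol_seed <= 0 || vol_target <= 0) {
    stop("volumes must be positive", call. = FALSE)
  }
  sum(voxel_fractions >= threshold) / (vol_seed + vol_target)
}
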