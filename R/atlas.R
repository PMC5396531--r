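#' Construct a region atlas
#'
#' A region atlas is the parcellation that indexes every connectivity matrix:
#' an ordered table of brain regions with a hemisphere label and a tissue
#' class. Region ids are assigned 0-based in row order, so the atlas fixes the
#' matrix row/column order once and for all downstream stages.
#'
#' @param regions A data frame with columns `name`, `hemisphere` (`"L"` or
#'   `"R"`) and `tissue_class` (`"cortical"` or `"striatal"`).
#'
#' @return A tibble of class `region_atlas` with columns `region_id` (0-based
#'   integer), `name`, `hemisphere`, `tissue_class`.
#'
#' @details Names must be unique and each hemisphere must contain at least one
#'   cortical region; striatal regions are optional. Cortical regions carry
#'   module assignments downstream, striatal regions form the seed set for
#'   cortico-striatal connections.
#'
#' @examples
#' region_atlas(data.frame(
#'   name = c("preCG_L", "preCG_R", "caudate_L"),
#'   hemisphere = c("L", "R", "L"),
#'   tissue_class = c("cortical", "cortical", "striatal")
#' ))
#' @export
region_atlas <- function(regions) {
  regions <- tibble::as_tibble(regions)
  required <- c("name", "hemisphere", "tissue_class")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("region table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_hemi <- which(!regions$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0) {
    stop("unknown hemisphere token ", dQuote(regions$hemisphere[bad_hemi[1]]),
         " in row ", bad_hemi[1], call. = FALSE)
  }
  bad_class <- which(!regions$tissue_class %in% c("cortical", "striatal"))
  if (length(bad_class) > 0) {
    stop("unknown tissue_class token ", dQuote(regions$tissue_class[bad_class[1]]),
         " in row ", bad_class[1], call. = FALSE)
  }
  dup <- regions$name[duplicated(regions$name)]
  if (length(dup) > 0) {
    stop("duplicate region name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (h in c("L", "R")) {
    if (!any(regions$hemisphere == h & regions$tissue_class == "cortical")) {
      stop("atlas must contain at least one cortical region in hemisphere ", h,
           call. = FALSE)
    }
  }
  atlas <- tibble::tibble(
    region_id = seq_len(nrow(regions)) - 1L,
    name = as.character(regions$name),
    hemisphere = as.character(regions$hemisphere),
    tissue_class = as.character(regions$tissue_class)
  )
  class(atlas) <- c("region_atlas", class(atlas))
  atlas
}

#' Read a region atlas from a TSV file
#'
#' @param path Path to a tab-separated file with header columns `name`,
#'   `hemisphere`, `tissue_class`. Region ids are assigned in file order.
#'
#' @return A [region_atlas] tibble.
#' @export
read_region_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  atlas <- region_atlas(tab)
  message("read_region_table: ", nrow(atlas), " regions (",
          sum(atlas$tissue_class == "cortical"), " cortical, ",
          sum(atlas$tissue_class == "striatal"), " striatal)")
  atlas
}

#' Write a region atlas to a TSV file
#'
#' @param atlas A [region_atlas].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(atlas, path) {
  readr::write_tsv(atlas[, c("name", "hemisphere", "tissue_class")], path,
                   progress = FALSE)
  invisible(path)
}

n_regions <- function(atlas) nrow(atlas)

cortical_ids <- function(atlas) atlas$region_id[atlas$tissue_class == "cortical"]

striatal_ids <- function(atlas) atlas$region_id[atlas$tissue_class == "striatal"]

#' Number of region-pair connections entering the edge-level analysis
#'
#' All cortical-cortical pairs plus all striatal-cortical pairs;
#' striatal-striatal pairs are excluded by construction. For the reference
#' 70-cortical, 4-striatal parcellation this is `choose(70, 2) + 4 * 70 =
#' 2695` connections, giving a Spearman correlation with `n - 2 = 2693`
#' degrees of freedom.
#'
#' @param atlas A [region_atlas].
#' @return Integer count of included region pairs.
#' @export
count_connection_level_pairs <- function(atlas) {
  n_c <- sum(atlas$tissue_class == "cortical")
  n_s <- sum(atlas$tissue_class == "striatal")
  as.integer(choose(n_c, 2) + n_s * n_c)
}
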