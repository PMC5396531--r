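#' Construct a single connectome observation
#'
#' One subject-visit weighted, undirected connectivity matrix. Weights are
#' unitless streamline-weight sums (e.g. SIFT2-weighted streamline counts);
#' absent connections are zero weights, not missing values.
#'
#' @param subject_id Subject identifier (string).
#' @param visit Visit number, integer `>= 1`. The model time metric is
#'   `time = visit - 1` years, so visit 1 is baseline.
#' @param W Square numeric matrix; must be symmetric (tolerance `1e-9`),
#'   non-negative, with an exactly zero diagonal.
#' @param atlas Optional [region_atlas]; if supplied, the matrix dimension
#'   must match and dimnames are set to region names.
#'
#' @return An object of class `connectome_obs`: a list with elements
#'   `subject_id`, `visit`, `time` and `W`.
#'
#' @details After the symmetry check passes, `W` is replaced by
#'   `(W + t(W)) / 2` so that downstream arithmetic sees an exactly symmetric
#'   matrix even when file round-trips introduced last-bit asymmetry.
#' @export
connectome_obs <- function(subject_id, visit, W, atlas = NULL) {
  stopifnot(is.matrix(W), is.numeric(W))
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (!is.null(atlas) && nrow(W) != nrow(atlas)) {
    stop("matrix dimension ", nrow(W), " does not match atlas with ",
         nrow(atlas), " regions", call. = FALSE)
  }
  asym <- max(abs(W - t(W)))
  if (asym > 1e-9) {
    stop("connectivity matrix is asymmetric (max |W - t(W)| = ",
         format(asym), ")", call. = FALSE)
  }
  if (any(W < 0)) stop("negative connection weight", call. = FALSE)
  if (any(diag(W) != 0)) stop("diagonal must be exactly zero", call. = FALSE)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (!is.null(atlas)) dimnames(W) <- list(atlas$name, atlas$name)
  visit <- as.integer(visit)
  if (is.na(visit) || visit < 1L) stop("visit must be an integer >= 1", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), visit = visit,
         time = visit - 1L, W = W),
    class = "connectome_obs"
  )
}

#' @export
print.connectome_obs <- function(x, ...) {
  cat("<connectome_obs> subject", x$subject_id, "visit", x$visit,
      "|", nrow(x$W), "x", ncol(x$W), "regions, total weight",
      format(sum(x$W) / 2, digits = 4), "\n")
  invisible(x)
}

#' Read a connectome matrix from file
#'
#' Two plain-text dialects are supported. A dense CSV carries an `n x n`
#' matrix with a header row of region names; it must be symmetric to within
#' `1e-9`. An edge-list TSV carries columns `i`, `j`, `weight` with 0-based
#' region indices, `i < j` (undirected half-matrix), no duplicate pairs;
#' unlisted pairs are zero.
#'
#' @param path Input path. Format is chosen by extension (`.csv` dense,
#'   `.tsv` edge list) unless `format` is given.
#' @param atlas A [region_atlas] defining dimension and region order.
#' @param subject_id,visit Observation metadata. If `NULL`, a JSON side-car
#'   file `<path>.json` with fields `subject_id` and `visit` is read.
#' @param format `"dense"`, `"edgelist"`, or `NULL` to infer from extension.
#'
#' @return A [connectome_obs].
#' @export
read_connectome <- function(path, atlas, subject_id = NULL, visit = NULL,
                            format = NULL) {
  if (is.null(subject_id) || is.null(visit)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) {
      stop("subject_id/visit not given and no side-car file ", side, call. = FALSE)
    }
    meta <- jsonlite::read_json(side)
    if (is.null(subject_id)) subject_id <- meta$subject_id
    if (is.null(visit)) visit <- meta$visit
  }
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path)) "edgelist" else "dense"
  }
  n <- nrow(atlas)
  if (format == "dense") {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    W <- as.matrix(tab)
    if (!is.numeric(W)) stop("dense connectome contains non-numeric entries", call. = FALSE)
    if (!identical(colnames(W), atlas$name)) {
      stop("dense connectome header does not match atlas region names", call. = FALSE)
    }
    rownames(W) <- colnames(W)
  } else {
    edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("i", "j", "weight") %in% names(edges))) {
      stop("edge list must have columns i, j, weight", call. = FALSE)
    }
    if (any(edges$i >= edges$j)) {
      stop("edge list must satisfy i < j (undirected half-matrix)", call. = FALSE)
    }
    if (anyDuplicated(edges[, c("i", "j")]) > 0) {
      stop("duplicate edge in edge list", call. = FALSE)
    }
    if (any(edges$i < 0 | edges$j > n - 1)) {
      stop("edge index outside atlas range 0..", n - 1, call. = FALSE)
    }
    if (any(edges$weight < 0)) stop("negative connection weight", call. = FALSE)
    W <- matrix(0, n, n, dimnames = list(atlas$name, atlas$name))
    W[cbind(edges$i + 1L, edges$j + 1L)] <- edges$weight
    W[cbind(edges$j + 1L, edges$i + 1L)] <- edges$weight
  }
  connectome_obs(subject_id, visit, W, atlas = atlas)
}

#' Write a connectome observation to file
#'
#' The dense CSV dialect round-trips weights bit-identically (shortest
#' round-trippable decimal representation). A JSON side-car `<path>.json`
#' with the subject id and visit is written alongside.
#'
#' @param obs A [connectome_obs].
#' @param path Output path (`.csv` for dense, `.tsv` for edge list).
#' @param format `"dense"` (default) or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(obs, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  W <- obs$W
  if (format == "dense") {
    readr::write_csv(tibble::as_tibble(W, .name_repair = "minimal"), path,
                     progress = FALSE)
  } else {
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    edges <- tibble::tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                            weight = W[idx])
    edges <- edges[order(edges$i, edges$j), ]
    readr::write_tsv(edges, path, progress = FALSE)
  }
  jsonlite::write_json(list(subject_id = obs$subject_id, visit = obs$visit),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Average connectivity matrices over a selection of observations
#'
#' Element-wise arithmetic mean of the selected matrices, e.g. the
#' group-average network over all control baseline scans that module
#' partitioning and path-length computation run on.
#'
#' @param dataset A [long_dataset].
#' @param subjects Optional character vector of subject ids to keep
#'   (default: all).
#' @param visits Optional integer vector of visits to keep (default: all).
#'
#' @return A symmetric numeric matrix.
#' @export
average_connectomes <- function(dataset, subjects = NULL, visits = NULL) {
  obs <- dataset$observations
  keep <- vapply(obs, function(o) {
    (is.null(subjects) || o$subject_id %in% subjects) &&
      (is.null(visits) || o$visit %in% visits)
  }, logical(1))
  obs <- obs[keep]
  if (length(obs) == 0) stop("no observations selected", call. = FALSE)
  Reduce(`+`, lapply(obs, `[[`, "W")) / length(obs)
}
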