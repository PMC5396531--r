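#' Single Louvain community-detection run
#'
#' One run of the (randomized) multilevel Louvain algorithm on a weighted
#' undirected network, maximizing Newman-Girvan modularity at resolution
#' `gamma`. Module labels are canonicalized so that modules are numbered by
#' the lowest node index they contain, making assignments comparable across
#' runs.
#'
#' @param W Symmetric non-negative weight matrix (typically the cortical
#'   submatrix of a group-average connectome), with region names as dimnames.
#' @param gamma Resolution parameter (> 0); `gamma = 1` is classic
#'   modularity.
#' @param seed Optional integer seed fixing the randomized sweep.
#' @return Named integer vector: module id (1-based, contiguous) per node.
#' @export
louvain_once <- function(W, gamma = 1, seed = NULL) {
  g <- graph_from_weights(W)
  louvain_once_graph(g, gamma, seed, node_names = rownames(W))
}

graph_from_weights <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (nrow(W) == 0) stop("empty graph", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-9) stop("W must be symmetric", call. = FALSE)
  if (any(W < 0)) stop("W must be non-negative", call. = FALSE)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

louvain_once_graph <- function(g, gamma, seed, node_names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  memb <- igraph::membership(
    igraph::cluster_louvain(g, resolution = gamma)
  )
  out <- canonicalize_modules(as.integer(memb))
  names(out) <- node_names %||% igraph::V(g)$name
  out
}

# relabel modules 1..k in order of the lowest contained node index
canonicalize_modules <- function(assignment) {
  first_seen <- unique(assignment)
  match(assignment, first_seen)
}

#' Weighted modularity of an assignment
#'
#' Newman-Girvan modularity `Q` of a node-to-module assignment on a weighted
#' undirected network, at resolution `gamma`:
#' `Q = (1/2m) * sum_ij (W_ij - gamma * k_i k_j / 2m) delta(c_i, c_j)`.
#'
#' @param W Symmetric non-negative weight matrix.
#' @param assignment Integer module ids covering all nodes of `W`.
#' @param gamma Resolution parameter.
#' @return Modularity `Q` (a real number).
#' @export
modularity_score <- function(W, assignment, gamma = 1) {
  if (length(assignment) != nrow(W)) {
    stop("assignment must cover all nodes of W", call. = FALSE)
  }
  g <- graph_from_weights(W)
  igraph::modularity(g, membership = as.integer(assignment),
                     weights = igraph::E(g)$weight, resolution = gamma)
}

#' Consensus modular partition over repeated Louvain runs
#'
#' Runs Louvain `n_runs` times (fresh randomization per run), builds the
#' module co-assignment frequency ("agreement") matrix, and derives a stable
#' consensus assignment. The default `"agreement"` method is
#' agreement-matrix consensus: the agreement matrix is thresholded at `tau`
#' and itself re-clustered by `n_runs` Louvain runs, iterating until all runs
#' return the same partition. The `"modal"` method instead returns the most
#' frequent canonicalized single-run assignment.
#'
#' @param W Symmetric non-negative weight matrix (cortical group-average
#'   network).
#' @param gamma Resolution parameter for the initial runs.
#' @param n_runs Number of Louvain repetitions (the reference analysis uses
#'   1000).
#' @param tau Agreement threshold in (0, 1) below which co-assignment
#'   frequencies are zeroed before re-clustering (default 0.5).
#' @param seed Master seed; per-run seeds are spawned deterministically.
#' @param max_iter Iteration cap for the consensus loop; non-convergence
#'   raises a `connatrophy_consensus_error` carrying the last agreement
#'   matrix in its `agreement` field.
#' @param method `"agreement"` (default) or `"modal"`.
#'
#' @return An object of class `module_partition`: list with `assignment`
#'   (tibble `name`, `module`), `gamma`, `n_runs`, `tau`, `method`,
#'   `agreement` (co-assignment frequency matrix of the initial runs), `Q`
#'   (modularity of the consensus assignment at `gamma`), `n_modules`,
#'   `n_iter`.
#' @export
consensus_partition <- function(W, gamma = 1, n_runs = 1000, tau = 0.5,
                                seed = NULL, max_iter = 50,
                                method = c("agreement", "modal")) {
  method <- match.arg(method)
  stopifnot(n_runs >= 1, tau > 0, tau < 1, gamma > 0)
  g <- graph_from_weights(W)
  node_names <- rownames(W) %||% as.character(seq_len(nrow(W)))
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)

  runs <- run_louvain_batch(g, gamma, run_seeds, node_names)
  agreement0 <- agreement_matrix(runs)
  dimnames(agreement0) <- list(node_names, node_names)

  if (method == "modal") {
    keys <- apply(runs, 1, paste, collapse = ",")
    modal_key <- names(sort(table(keys), decreasing = TRUE))[1]
    final <- as.integer(strsplit(modal_key, ",")[[1]])
    n_iter <- 0L
  } else {
    A <- agreement0
    converged <- FALSE
    n_iter <- 0L
    final <- runs[1, ]
    while (n_iter < max_iter) {
      n_iter <- n_iter + 1L
      A_thr <- A
      A_thr[A_thr < tau] <- 0
      diag(A_thr) <- 0
      g_A <- igraph::graph_from_adjacency_matrix(A_thr, mode = "undirected",
                                                 weighted = TRUE)
      iter_seeds <- sample.int(2147483646L, n_runs)
      runs_A <- run_louvain_batch(g_A, 1, iter_seeds, node_names)
      final <- runs_A[1, ]
      if (all(apply(runs_A, 1, identical, y = final))) {
        converged <- TRUE
        break
      }
      A <- agreement_matrix(runs_A)
    }
    if (!converged) {
      rlang::abort(
        paste0("consensus did not converge within ", max_iter, " iterations"),
        class = "connatrophy_consensus_error", agreement = A
      )
    }
  }

  final <- canonicalize_modules(final)
  structure(
    list(
      assignment = tibble::tibble(name = node_names, module = final),
      gamma = gamma, n_runs = as.integer(n_runs), tau = tau, method = method,
      agreement = agreement0,
      Q = modularity_score(W, final, gamma),
      n_modules = length(unique(final)), n_iter = n_iter
    ),
    class = "module_partition"
  )
}

run_louvain_batch <- function(g, gamma, seeds, node_names) {
  t(vapply(seeds, function(s) {
    unname(louvain_once_graph(g, gamma, s, node_names = NULL))
  }, integer(length(node_names))))
}

#' Co-assignment frequency matrix of a set of partitions
#'
#' @param runs Integer matrix, one partition per row.
#' @return Symmetric matrix of pairwise co-assignment frequencies in
#'   `[0, 1]`, diagonal 1.
#' @export
agreement_matrix <- function(runs) {
  n <- ncol(runs)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(runs))) {
    M <- stats::model.matrix(~ factor(runs[r, ]) - 1)
    A <- A + tcrossprod(M)
  }
  A <- A / nrow(runs)
  diag(A) <- 1
  A
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition>", x$n_modules, "modules | gamma =", x$gamma,
      "| Q =", format(x$Q, digits = 4), "| method =", x$method,
      "(", x$n_runs, "runs,", x$n_iter, "consensus iterations )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
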