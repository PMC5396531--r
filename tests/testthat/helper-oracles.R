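# Independent brute-force oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Floyd-Warshall all-pairs shortest paths over an edge-length matrix
fw_shortest_paths <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# naive double-loop weighted modularity at resolution gamma
modularity_naive <- function(W, assignment, gamma = 1) {
  two_m <- sum(W)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (assignment[i] == assignment[j]) {
        q <- q + W[i, j] - gamma * k[i] * k[j] / two_m
      }
    }
  }
  as.numeric(q / two_m)
}

# all set partitions of 1..n as restricted growth strings (assignment vectors)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, max_label) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      grow(c(prefix, lab), max(max_label, lab))
    }
  }
  grow(integer(0), 0L)
  out
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# block matrix of two disjoint unit-weight cliques of size k
two_cliques <- function(k) {
  W <- matrix(0, 2 * k, 2 * k)
  W[seq_len(k), seq_len(k)] <- 1
  W[k + seq_len(k), k + seq_len(k)] <- 1
  diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("n", seq_len(2 * k))
  W
}

# small hand-built atlas: per-hemisphere cortical counts plus striatal regions
tiny_atlas <- function(n_L = 2, n_R = 2, striatal = character(0)) {
  df <- data.frame(
    name = c(sprintf("ctx_L_%d", seq_len(n_L)), sprintf("ctx_R_%d", seq_len(n_R)),
             striatal),
    hemisphere = c(rep("L", n_L), rep("R", n_R),
                   ifelse(grepl("_L", striatal), "L", "R")),
    tissue_class = c(rep("cortical", n_L + n_R),
                     rep("striatal", length(striatal)))
  )
  region_atlas(df)
}

# symmetric random weight matrix with zero diagonal
random_symmetric <- function(n, density = 1, max_w = 5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  keep <- stats::runif(length(ut)) < density
  W[ut[keep]] <- stats::runif(sum(keep), 0.1, max_w)
  W <- W + t(W)
  rownames(W) <- colnames(W) <- paste0("n", seq_len(n))
  W
}

# longitudinal data generated exactly from the group-contrast mixed model
make_eq1_data <- function(n_per_group = 30, n_visits = 3,
                          alpha = 10, beta = -0.2, gam = 0, delta = 0,
                          theta_age = 0, sd_int = 1, sd_slope = 0.3,
                          sd_resid = 0.5, n_sites = 2) {
  n <- 2 * n_per_group
  subj <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("control", "preHD"), each = n_per_group),
    age = round(stats::runif(n, 30, 60), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    site = sample(paste0("site_", seq_len(n_sites)), n, replace = TRUE),
    education = sample(1:6, n, replace = TRUE),
    a_i = stats::rnorm(n, 0, sd_int),
    b_i = stats::rnorm(n, 0, sd_slope)
  )
  tidyr::expand_grid(subj, visit = seq_len(n_visits)) |>
    dplyr::mutate(
      time = .data$visit - 1,
      g = as.integer(.data$group == "preHD"),
      strength = alpha + beta * .data$time + gam * .data$g +
        delta * .data$g * .data$time + theta_age * .data$age +
        .data$a_i + .data$b_i * .data$time +
        stats::rnorm(dplyr::n(), 0, sd_resid)
    ) |>
    dplyr::select(-"a_i", -"b_i", -"g")
}
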