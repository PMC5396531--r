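striatum4 <- c("caudate_L", "putamen_L", "caudate_R", "putamen_R")

# atlas with n_L / n_R cortical regions per module list and 4 striatal
module_atlas <- function(sizes_L, sizes_R, striatal = striatum4) {
  atlas <- tiny_atlas(sum(sizes_L), sum(sizes_R), striatal)
  partition <- tibble::tibble(
    name = atlas$name[atlas$tissue_class == "cortical"],
    module = c(rep(seq_along(sizes_L), sizes_L),
               rep(length(sizes_L) + seq_along(sizes_R), sizes_R))
  )
  list(atlas = atlas, partition = partition)
}

test_that("pairs classify by striatal membership, module and hemisphere", {
  ma <- module_atlas(c(2, 2), c(2, 2))
  expect_equal(classify_pair("caudate_L", "ctx_L_1", ma$atlas, ma$partition),
               "cortico_striatal")
  expect_equal(classify_pair("caudate_L", "ctx_R_1", ma$atlas, ma$partition),
               "cortico_striatal")
  expect_equal(classify_pair("ctx_L_1", "ctx_L_2", ma$atlas, ma$partition),
               "intramodular")
  expect_equal(classify_pair("ctx_L_1", "ctx_L_3", ma$atlas, ma$partition),
               "intrahemispheric")
  expect_equal(classify_pair("ctx_L_1", "ctx_R_1", ma$atlas, ma$partition),
               "interhemispheric")
  expect_equal(classify_pair("caudate_L", "putamen_R", ma$atlas, ma$partition),
               "excluded")
  # symmetric in its arguments
  expect_equal(classify_pair("ctx_R_1", "ctx_L_1", ma$atlas, ma$partition),
               "interhemispheric")
  expect_error(classify_pair("nope", "ctx_L_1", ma$atlas, ma$partition),
               "unknown region")
  expect_error(classify_pair("ctx_L_1", "ctx_L_1", ma$atlas, ma$partition),
               "differ")
})

test_that("subtype connection counts follow the module combinatorics", {
  # 3 modules per hemisphere with striatum: 6 CS, 9 inter, 6 intra, 6 intram
  ma <- module_atlas(c(2, 2, 2), c(2, 2, 2))
  conns <- enumerate_subtype_connections(ma$atlas, ma$partition)
  counts <- table(conns$subtype)
  expect_equal(unname(counts[["cortico_striatal"]]), 6)
  expect_equal(unname(counts[["interhemispheric"]]), 9)
  expect_equal(unname(counts[["intrahemispheric"]]), 6)
  expect_equal(unname(counts[["intramodular"]]), 6)

  # one module per hemisphere, no striatum
  ma2 <- module_atlas(3, 3, striatal = character(0))
  counts2 <- table(enumerate_subtype_connections(ma2$atlas, ma2$partition)$subtype)
  expect_equal(unname(counts2[["cortico_striatal"]]), 0)
  expect_equal(unname(counts2[["interhemispheric"]]), 1)
  expect_equal(unname(counts2[["intrahemispheric"]]), 0)
  expect_equal(unname(counts2[["intramodular"]]), 2)

  # asymmetric 2 left / 4 right modules: inter 8, intra 1 + 6 = 7, intram 6, CS 6
  ma3 <- module_atlas(c(2, 2), c(2, 2, 2, 2))
  counts3 <- table(enumerate_subtype_connections(ma3$atlas, ma3$partition)$subtype)
  expect_equal(unname(counts3[["interhemispheric"]]), 8)
  expect_equal(unname(counts3[["intrahemispheric"]]), 7)
  expect_equal(unname(counts3[["intramodular"]]), 6)
  expect_equal(unname(counts3[["cortico_striatal"]]), 6)
})

test_that("subtype connections partition the analyzed pairs exactly", {
  ma <- module_atlas(c(3, 2, 2), c(2, 3, 2))
  conns <- enumerate_subtype_connections(ma$atlas, ma$partition)
  members <- dplyr::bind_rows(conns$pairs)
  keys <- paste(members$i, members$j)
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(nrow(members), count_connection_level_pairs(ma$atlas))
  expect_equal(sum(conns$n_pairs), count_connection_level_pairs(ma$atlas))
})

test_that("aggregate strengths sum member pairs and conserve total weight", {
  ma <- module_atlas(c(2, 2), c(2, 2))
  n <- nrow(ma$atlas)
  expect_equal(aggregate_strength(matrix(0, n, n),
                                  data.frame(i = c(0, 1), j = c(2, 3))), 0)
  W0 <- matrix(0, n, n)
  W0[cbind(c(1, 2, 3), c(5, 6, 7))] <- c(1, 2, 3)
  W0 <- W0 + t(W0)
  expect_equal(aggregate_strength(W0, data.frame(i = c(0, 1, 2), j = c(4, 5, 6))), 6)

  set.seed(30)
  W <- random_symmetric(n)
  conns <- enumerate_subtype_connections(ma$atlas, ma$partition)
  total <- sum(vapply(conns$pairs, function(p) {
    s <- 0
    for (r in seq_len(nrow(p))) s <- s + W[p$i[r] + 1, p$j[r] + 1]
    s
  }, numeric(1)))
  agg <- sum(vapply(conns$pairs, aggregate_strength, W = W, numeric(1)))
  expect_equal(agg, total, tolerance = 1e-12)
  # conservation against the full included-pair sum
  pairs <- connection_pairs(ma$atlas, ma$partition)
  expect_equal(agg, sum(W[cbind(pairs$i + 1, pairs$j + 1)]), tolerance = 1e-12)
})

test_that("VCP thresholding applies an inclusive 1% rule with volume normalization", {
  expect_equal(vcp_normalize(c(0.5, 0.005, 0.02), 100, 300), 2 / 400)
  expect_equal(vcp_normalize(c(0.001, 0.004), 50, 50), 0)
  # a fraction of exactly 1% counts as connected
  expect_equal(vcp_normalize(0.01, 60, 40), 1 / 100)
  expect_error(vcp_normalize(0.5, 0, 10), "positive")
  expect_error(vcp_normalize(1.5, 10, 10), "\\[0, 1\\]")
})
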