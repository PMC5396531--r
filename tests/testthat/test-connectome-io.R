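make_obs <- function(atlas, fill = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(atlas)
  W <- fill %||% random_symmetric(n)
  rownames(W) <- colnames(W) <- atlas$name
  connectome_obs("s1", 1, W, atlas = atlas)
}

test_that("edge lists are mirrored and validated", {
  atlas <- tiny_atlas(2, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("i\tj\tweight", "0\t1\t2.0"), path)
  obs <- read_connectome(path, atlas, subject_id = "s1", visit = 1)
  expect_equal(obs$W[1, 2], 2)
  expect_equal(obs$W[2, 1], 2)
  expect_equal(sum(obs$W), 4)

  writeLines(c("i\tj\tweight", "1\t0\t2.0"), path)
  expect_error(read_connectome(path, atlas, "s1", 1), "i < j")
  writeLines(c("i\tj\tweight", "0\t1\t2.0", "0\t1\t1.0"), path)
  expect_error(read_connectome(path, atlas, "s1", 1), "duplicate")
  writeLines(c("i\tj\tweight", "0\t1\t-1"), path)
  expect_error(read_connectome(path, atlas, "s1", 1), "negative")
})

test_that("dense matrices must be symmetric, non-negative, zero-diagonal", {
  W <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(connectome_obs("s", 1, W), "asymmetric")
  W2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(connectome_obs("s", 1, W2), "negative")
  W3 <- matrix(c(1, 2, 2, 0), 2, 2)
  expect_error(connectome_obs("s", 1, W3), "diagonal")
  # near-symmetric input is symmetrized after passing the tolerance check
  W4 <- matrix(c(0, 1, 1 + 1e-12, 0), 2, 2)
  obs <- connectome_obs("s", 1, W4)
  expect_identical(obs$W, t(obs$W))
})

test_that("dense CSV round-trip reproduces weights bit-identically", {
  atlas <- tiny_atlas(3, 2, "caudate_L")
  obs <- make_obs(atlas, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectome(obs, path)
  back <- read_connectome(path, atlas)  # metadata from side-car
  expect_identical(back$W, obs$W)
  expect_equal(back$subject_id, "s1")
  expect_equal(back$visit, 1L)

  epath <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(obs, epath, format = "edgelist")
  back2 <- read_connectome(epath, atlas)
  expect_equal(back2$W, obs$W, tolerance = 1e-12)
})

test_that("averaging matches the elementwise oracle and its degenerate cases", {
  atlas <- tiny_atlas(3, 2)
  obs <- lapply(1:3, function(s) {
    o <- make_obs(atlas, seed = s)
    o$subject_id <- paste0("s", s)
    o
  })
  cohort <- data.frame(subject_id = paste0("s", 1:3), group = "control",
                       age = 40, sex = "M", site = "a", education = 3)
  ds <- long_dataset(atlas, obs, cohort)

  avg <- average_connectomes(ds)
  oracle <- matrix(0, 5, 5)
  for (o in obs) for (i in 1:5) for (j in 1:5) {
    oracle[i, j] <- oracle[i, j] + o$W[i, j] / 3
  }
  expect_equal(unname(avg), oracle, tolerance = 1e-12)

  # single selection returns that matrix; k copies of one matrix return it
  expect_identical(average_connectomes(ds, subjects = "s2"), obs[[2]]$W)
  same <- lapply(1:4, function(v) connectome_obs("s1", v, obs[[1]]$W))
  ds2 <- long_dataset(atlas, same, cohort)
  expect_equal(average_connectomes(ds2), obs[[1]]$W, tolerance = 1e-15)

  expect_error(average_connectomes(ds, subjects = "nobody"), "no observations")
})

test_that("long tables carry time = visit - 1 and enforce referential integrity", {
  atlas <- tiny_atlas(2, 2)
  obs <- list(make_obs(atlas), connectome_obs("s1", 2, make_obs(atlas)$W),
              connectome_obs("s1", 3, make_obs(atlas)$W),
              connectome_obs("s2", 1, make_obs(atlas)$W))
  cohort <- data.frame(subject_id = c("s1", "s2"), group = c("control", "preHD"),
                       age = c(40, 50), sex = c("M", "F"), site = "a",
                       education = 3)
  ds <- long_dataset(atlas, obs, cohort)

  strengths <- tibble::tibble(
    subject_id = c("s1", "s1", "s1", "s2"), visit = c(1L, 2L, 3L, 1L),
    strength = 1:4
  )
  lt <- build_long_table(ds, strengths)
  expect_equal(nrow(lt), 4)
  expect_equal(lt$time[lt$subject_id == "s1"], c(0, 1, 2))
  expect_equal(lt$time[lt$subject_id == "s2"], 0)
  expect_equal(lt$group[lt$subject_id == "s2"], "preHD")

  expect_error(
    build_long_table(ds, tibble::tibble(subject_id = "ghost", visit = 1L,
                                        strength = 1)),
    "not in cohort"
  )
  # duplicate visits are rejected at dataset construction
  expect_error(
    long_dataset(atlas, c(obs, obs[2]), cohort),
    "strictly increasing"
  )
})
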