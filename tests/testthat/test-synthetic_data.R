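# Synthetic-data generator: planted truth, matrices, catalogs.

test_that("planted truths are deterministic, orthonormal, with the stated spectrum", {
  t1 <- make_truth(n_entities = 120, n_conditions = 8, rank = 3, seed = 5)
  t2 <- make_truth(n_entities = 120, n_conditions = 8, rank = 3, seed = 5)
  expect_identical(t1$true_weights, t2$true_weights)
  expect_identical(t1$true_potentials, t2$true_potentials)
  gram <- crossprod(t1$true_weights)
  expect_equal(gram, diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(t1$true_weights[, 1] > 0)) # positive baseline weights

  # noiseless matrix reproduces the designed singular values
  t0 <- make_truth(n_entities = 120, n_conditions = 8, rank = 3,
                   noise_sd = 0, seed = 6)
  x <- synthesize_matrix(t0)
  d <- surprisal_decompose(log_transform(x, 0))
  expect_equal(d$singular_values[1:4], t0$singular_values, tolerance = 1e-8)
  expect_equal(recovery_fraction(d, 3), 1, tolerance = 1e-10)

  # decayed spectrum has an elbow at the designed rank
  expect_equal(t0$singular_values[3] / t0$singular_values[2], 0.6,
               tolerance = 1e-12)

  # rank 0: baseline-only matrix
  tr0 <- make_truth(n_entities = 50, n_conditions = 5, rank = 0, seed = 7,
                    noise_sd = 0)
  d0 <- surprisal_decompose(log_transform(synthesize_matrix(tr0), 0))
  expect_equal(sum(d0$singular_values > 1e-8), 1L)

  expect_error(make_truth(n_entities = 10, n_conditions = 3, rank = 5),
               "exceeds")
})

test_that("noise lowers recovery at fixed truncation (in expectation)", {
  rec_at <- function(noise, seed) {
    tr <- make_truth(n_entities = 150, n_conditions = 8, rank = 3,
                     noise_sd = noise, seed = seed)
    d <- surprisal_decompose(log_transform(synthesize_matrix(tr,
                                                             seed = seed), 0))
    recovery_fraction(d, 2) # k < r
  }
  seeds <- 1:10
  lo <- mean(vapply(seeds, function(s) rec_at(0.2, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) rec_at(1.0, s), numeric(1)))
  expect_gt(lo, hi)
})

test_that("estimated potentials recover the truth at low noise", {
  tr <- make_truth(n_entities = 300, n_conditions = 10, rank = 3,
                   noise_sd = 0.001, seed = 17)
  d <- surprisal_decompose(log_transform(synthesize_matrix(tr, seed = 18), 0))
  for (a in 0:3) {
    est <- d$potentials[a + 1L, ]
    tru <- tr$true_potentials[a + 1L, ]
    s <- alignment_sign(est, tru)
    expect_lt(sqrt(sum((s * est - tru)^2)) / sqrt(sum(tru^2)), 1e-3)
  }
})

test_that("planted catalogs respect sizes, record the truth, and error on thin tails", {
  tr <- make_truth(n_entities = 400, seed = 21)
  cat_ <- plant_catalog(tr, n_null_sets = 50, set_size_range = c(8, 20),
                        planted = list(
                          list(archetype = "shift", size = 25, strength = 10),
                          list(archetype = "single", size = 18,
                               n_extreme = 2, tail_quantile = 0.98),
                          list(archetype = "subgroup", size = 21,
                               block_size = 7, tail_quantile = 0.9)),
                        seed = 22)
  expect_length(cat_, 53L)
  null_sizes <- lengths(cat_$sets[grep("^null_", names(cat_$sets))])
  expect_true(all(null_sizes >= 8 & null_sizes <= 20))
  planted <- attr(cat_, "planted")
  expect_equal(nrow(planted), 3L)
  expect_setequal(planted$archetype, c("shift", "single", "subgroup"))
  # planted members exist among the entities and are recorded
  single_ids <- strsplit(planted$planted_ids[planted$archetype == "single"],
                         ",")[[1]]
  expect_length(single_ids, 2L)
  expect_true(all(single_ids %in% tr$entity_ids))
  expect_true(all(single_ids %in% cat_$sets[["planted_single_02"]]))
  # the recorded extremes sit in the upper tail of the oriented weights
  w <- tr$true_weights[, 2]
  expect_true(all(w[single_ids] >= stats::quantile(w[w > 0], 0.95)))

  expect_error(
    plant_catalog(tr, 0, planted = list(list(archetype = "single",
                                             n_extreme = 2,
                                             tail_quantile = 1))),
    "tail too small")
  expect_error(plant_catalog(tr, 5, set_size_range = c(3, 10)), ">= 5")

  # deterministic per seed
  cat2 <- plant_catalog(tr, n_null_sets = 50, set_size_range = c(8, 20),
                        planted = list(
                          list(archetype = "shift", size = 25, strength = 10),
                          list(archetype = "single", size = 18,
                               n_extreme = 2, tail_quantile = 0.98),
                          list(archetype = "subgroup", size = 21,
                               block_size = 7, tail_quantile = 0.9)),
                        seed = 22)
  expect_identical(cat_$sets, cat2$sets)
})

test_that("a planted single-extreme set beats any count-based within-set test", {
  # the weight-sum statistic fires on one/two dominant entities while the
  # overlap of the set with any fixed extreme-weight tail stays tiny
  tr <- make_truth(n_entities = 2000, seed = 41)
  x <- synthesize_matrix(tr, seed = 42)
  d <- surprisal_decompose(log_transform(x, 0))
  cat_ <- plant_catalog(tr, n_null_sets = 40,
                        planted = list(list(archetype = "single", size = 20,
                                            n_extreme = 2,
                                            tail_quantile = 0.998,
                                            constraint = 1,
                                            direction = "positive")),
                        seed = 43)
  res <- run_tmea(d, cat_, 1, b = 10000, seed = 44)
  align <- alignment_sign(constraint_weights(d, 1), tr$true_weights[, 2])
  dirx <- aligned_direction("positive", align)
  row <- res[res$fas_id == "planted_single_01" & res$direction == dirx, ]
  expect_lt(row$q_bh, 0.05)
  # count-based view: members in the top-5% tail of the constraint weights
  w <- constraint_weights(d, 1) * align
  tail5 <- names(w)[w >= stats::quantile(w, 0.95)]
  overlap <- length(intersect(cat_$sets[["planted_single_01"]], tail5))
  expect_lte(overlap, 4L) # far below any useful overrepresentation signal
})

test_that("fixture files round-trip the synthetic study", {
  tr <- make_truth(n_entities = 80, n_conditions = 6, rank = 2, seed = 61)
  x <- synthesize_matrix(tr, seed = 62)
  cat_ <- plant_catalog(tr, n_null_sets = 8, set_size_range = c(5, 10),
                        seed = 63)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_fixtures(tr, x, cat_, dir)
  expect_true(all(file.exists(paths)))
  back <- read_abundance_matrix(paths[1])
  expect_equal(unclass(back), unclass(x), tolerance = 1e-6)
  gmt <- read_gmt(paths[2])
  expect_identical(gmt$sets, cat_$sets)
  sidecar <- jsonlite::read_json(paths[3])
  expect_equal(sidecar$n_entities, 80L)
  expect_equal(length(sidecar$singular_values), 3L)
})
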