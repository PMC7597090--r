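# Directional weight-sum test: splits, Monte Carlo p-values against the
# enumeration oracle, BH adjustment, the full run_tmea surface.

test_that("directional splits follow the strict-sign definition", {
  w <- c(a = 1, b = 2, c = -3, d = 0)
  sp <- split_directional(w, c("a", "b", "c", "d"), "S1", 1)
  expect_equal(sp$s_plus, 2L)
  expect_equal(sp$w_hat_plus, 3)
  expect_equal(sp$s_minus, 1L)
  expect_equal(sp$w_hat_minus, -3)
  expect_equal(sp$n_zero, 1L)
  # partition identity: directional sums add up to the nonzero-member total
  expect_equal(sp$w_hat_plus + sp$w_hat_minus, sum(w[w != 0]))

  allpos <- split_directional(c(a = 1, b = 2), c("a", "b"), "S2", 1)
  expect_equal(allpos$s_minus, 0L)
  expect_equal(allpos$w_hat_minus, 0)

  expect_error(split_directional(w, character(0), "S3", 1), "empty")
  expect_message(
    spm <- split_directional(w, c("a", "zz"), "S4", 1), "unmeasured")
  expect_equal(spm$n_unmeasured, 1L)
})

test_that("Monte Carlo p-values agree with exhaustive enumeration", {
  # pool {1,2,3}, subsets of size 2: sums 3, 4, 5 -> P(W >= 5) = 1/3
  expect_equal(exact_subset_pvalue(c(1, 2, 3), 2, 5, "positive"), 1 / 3)
  pv <- monte_carlo_pvalue(c(1, 2, 3), 2, 5, b = 10000,
                           direction = "positive", seed = 5)
  ci <- 2.576 * sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(pv$p - 1 / 3), ci + 1e-4)

  # a few random same-sign pools against the oracle at loose Monte Carlo
  # tolerance
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    s <- sample(2:4, 1)
    pool <- round(runif(n, 0.1, 2), 3)
    obs <- sum(pool[sample.int(n, s)])
    pe <- exact_subset_pvalue(pool, s, obs, "positive")
    pm <- monte_carlo_pvalue(pool, s, obs, b = 20000,
                             direction = "positive", seed = 100 + i)$p
    expect_lt(abs(pm - pe), 3.3 * sqrt(pe * (1 - pe) / 20000) + 2e-4)
  }
})

test_that("degenerate and boundary pools give p = 1", {
  pv <- monte_carlo_pvalue(c(1, 1, 1), 2, 2, b = 500,
                           direction = "positive", seed = 1)
  expect_equal(pv$p, 1) # every resample sums to 2 >= 2, ties inclusive

  pool <- c(0.5, 1, 2, 4)
  wmin <- sum(sort(pool)[1:2])
  pv2 <- monte_carlo_pvalue(pool, 2, wmin, b = 500,
                            direction = "positive", seed = 2)
  expect_equal(pv2$p, 1) # no subset sums below the two smallest
})

test_that("p is monotone in the observed sum and a multiple of 1/b", {
  pool <- exp(rnorm(30))
  obs <- seq(1, 8, length.out = 12)
  p <- vapply(obs, function(w)
    monte_carlo_pvalue(pool, 5, w, b = 2000, direction = "positive",
                       seed = 77)$p, numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_equal(p * 2000, round(p * 2000), tolerance = 1e-9)

  neg <- -pool
  pn <- vapply(-obs, function(w)
    monte_carlo_pvalue(neg, 5, w, b = 2000, direction = "negative",
                       seed = 77)$p, numeric(1))
  expect_true(all(diff(pn) <= 0)) # more negative sums are more extreme
})

test_that("the estimator contract holds: seeds, bootstrap, add-one", {
  pool <- exp(rnorm(15))
  a <- monte_carlo_pvalue(pool, 4, 3, b = 3000, direction = "positive",
                          seed = 9)
  b <- monte_carlo_pvalue(pool, 4, 3, b = 3000, direction = "positive",
                          seed = 9)
  expect_identical(a$p, b$p) # bitwise reproducible
  expect_equal(a$resolution, 1 / 3000)
  expect_equal(a$p, a$n_extreme / a$b)

  boot <- monte_carlo_pvalue(pool, 4, 3, b = 1000, direction = "positive",
                             seed = 9, replace = TRUE)
  expect_true(boot$p >= 0 && boot$p <= 1)
  add1 <- monte_carlo_pvalue(pool, 4, 3, b = 1000, direction = "positive",
                             seed = 9, estimator = "add_one")
  expect_equal(add1$p, (add1$n_extreme + 1) / 1001)

  expect_error(monte_carlo_pvalue(pool, 20, 3, 100, "positive"), "pool size")
  expect_error(monte_carlo_pvalue(pool, 4, 3, 0, "positive"), "b must be")
  expect_error(monte_carlo_pvalue(pool, 4, 3, 100, "negative"),
               "strictly negative")
})

test_that("BH adjustment reproduces the step-up hand examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9),
               tolerance = 1e-12)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_tmea filters by measured size, sorts, and is reproducible", {
  truth <- make_truth(n_entities = 300, seed = 31)
  x <- synthesize_matrix(truth, seed = 32)
  d <- surprisal_decompose(log_transform(x, 0))
  sets <- list(big = truth$entity_ids[1:20],
               small = truth$entity_ids[21:24], # 4 measured members
               partial = c(truth$entity_ids[25:40], "UNMEASURED1"))
  cat_ <- annotation_catalog(sets)
  expect_message(
    res <- run_tmea(d, cat_, 1:2, b = 500, min_set_size = 5, seed = 99),
    "absent from the matrix")
  expect_false("small" %in% res$fas_id)
  expect_true(all(c("big", "partial") %in% res$fas_id))
  expect_equal(res$set_size[res$fas_id == "partial"][1], 16L)
  # two directional descriptors per constraint for every tested FAS
  expect_setequal(unique(res$direction), c("positive", "negative"))
  # sorted by (constraint, direction, q, fas)
  expect_false(is.unsorted(res$constraint))
  # reproducible bitwise
  res2 <- suppressMessages(
    run_tmea(d, cat_, 1:2, b = 500, min_set_size = 5, seed = 99))
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # subset ordering inside run does not change per-test results: a different
  # catalog order yields the same rows (substream seeds per FAS)
  res3 <- suppressMessages(
    run_tmea(d, annotation_catalog(rev(sets)), 1:2, b = 500,
             min_set_size = 5, seed = 99))
  r3 <- as.data.frame(res3)[order(res3$constraint, res3$direction,
                                  res3$fas_id), ]
  r1 <- as.data.frame(res)[order(res$constraint, res$direction,
                                 res$fas_id), ]
  rownames(r1) <- rownames(r3) <- NULL
  expect_equal(r1, r3)

  expect_warning(run_tmea(d, annotation_catalog(list(tiny = sets$small)),
                          1, b = 500, seed = 1), "no FAS")
  expect_error(run_tmea(d, cat_, 99, b = 500, seed = 1), "constraint indices")
})

test_that("a strongly shifted planted set is recovered with small q", {
  truth <- make_truth(n_entities = 600, seed = 51)
  x <- synthesize_matrix(truth, seed = 52)
  d <- surprisal_decompose(log_transform(x, 0))
  cat_ <- plant_catalog(truth, n_null_sets = 25,
                        planted = list(list(archetype = "shift",
                                            strength = 25, size = 25,
                                            constraint = 1,
                                            direction = "positive")),
                        seed = 53)
  res <- run_tmea(d, cat_, 1, b = 2000, seed = 54)
  align <- alignment_sign(constraint_weights(d, 1),
                          truth$true_weights[, 2])
  dirx <- aligned_direction("positive", align)
  q <- res$q_bh[res$fas_id == "planted_shift_01" & res$direction == dirx]
  expect_lt(q, 0.05)
})
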