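test_that("frequency counts are an exact histogram with conserved totals", {
  fc <- frequency_counts(c(1, 1, 2, 3))
  expect_identical(fc$F, c(`1` = 2L, `2` = 1L, `3` = 1L))
  expect_identical(fc$s_obs, 4L)
  expect_identical(fc$N, 7L)
  expect_identical(frequency_counts(5)$F, c(`5` = 1L))
  empty <- frequency_counts(integer(0))
  expect_identical(empty$s_obs, 0L)
  expect_identical(empty$N, 0L)

  set.seed(501)
  for (rep in 1:10) {
    av <- sample(1:40, sample(1:80, 1), replace = TRUE)
    fc <- frequency_counts(av)
    expect_identical(sum(fc$F), length(av))
    expect_identical(sum(as.integer(names(fc$F)) * fc$F), sum(av))
  }
})

test_that("bias-corrected Chao1 matches hand evaluation and its bounds", {
  expect_identical(chao1_corrected(c(2, 3, 4)), 3)       # F1 = 0
  expect_identical(chao1_corrected(c(1, 1, 2, 3)), 4.5)
  expect_identical(chao1_corrected(c(1, 1, 1)), 6)
  expect_error(chao1_corrected(integer(0)), "empty")

  set.seed(502)
  for (rep in 1:20) {
    av <- sample(1:15, sample(2:60, 1), replace = TRUE)
    est <- chao1_corrected(av)
    expect_gte(est, length(av))
    expect_identical(est == length(av), sum(av == 1) <= 1)
    # permutation invariance
    expect_identical(est, chao1_corrected(sample(av)))
  }
})

test_that("ACE matches hand evaluation, its degenerate branches, and vegan", {
  expect_equal(ace(c(1, 2, 10, 15)), 755 / 144, tolerance = 1e-12)  # = 5.2430556
  expect_identical(ace(c(11, 12, 15)), 3L)      # no rare clusters
  expect_identical(ace(c(1, 1, 1)), 6)          # zero coverage -> Chao1 fallback
  expect_error(ace(integer(0)), "empty")

  set.seed(503)
  for (rep in 1:25) {
    av <- sample(1:25, sample(4:60, 1), replace = TRUE)
    er <- vegan::estimateR(matrix(av, nrow = 1))
    expect_equal(chao1_corrected(av), unname(er["S.chao1", 1]), tolerance = 1e-10)
    expect_equal(ace(av), unname(er["S.ACE", 1]), tolerance = 1e-10)
  }
})

test_that("rarefied subsamples respect the hypergeometric expectation", {
  set.seed(504)
  av <- c(1L, 1L, 2L, 3L, 5L, 8L, 13L, 21L, 40L)
  assignments <- setNames(rep(seq_along(av) - 1L, av),
                          paste0("r", seq_len(sum(av))))
  expect_identical(sort(rarefy_counts(assignments, sum(av))), sort(av))
  expect_length(rarefy_counts(assignments, 0), 0L)
  expect_error(rarefy_counts(assignments, sum(av) + 1), "depth")

  # closed form agrees with vegan's independent implementation
  for (depth in c(5, 20, 50))
    expect_equal(expected_rarefied_richness(av, depth),
                 as.numeric(vegan::rarefy(matrix(av, nrow = 1), depth)),
                 tolerance = 1e-9)

  # Monte-Carlo mean within 3 MC standard errors of the closed form
  depth <- 30
  draws <- replicate(400, length(rarefy_counts(assignments, depth)))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected_rarefied_richness(av, depth)), 3 * se)
})

test_that("rarefaction curves end exactly at the full-data estimates", {
  comm <- fx_comm25()
  cm <- greedy_cluster(comm$reads, 0.03)
  av <- abundance_vector(cm)
  n <- nrow(comm$reads)

  one <- rarefaction_curve(cm, step = n, iters = 1, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(one$mean_obs, as.numeric(length(av)))
  expect_identical(one$mean_chao1, chao1_corrected(av))
  expect_identical(one$mean_ace, ace(av))

  crv <- rarefaction_curve(cm, step = 25, iters = 10, seed = 2)
  expect_identical(crv$depth[nrow(crv)], n)
  expect_equal(crv$mean_obs[nrow(crv)], length(av))
  expect_equal(crv$mean_chao1[nrow(crv)], chao1_corrected(av))

  # all-singleton assignment: observed richness equals depth exactly, so the
  # averaged curve is strictly increasing with endpoint N
  singl <- setNames(0:99, paste0("s", 1:100))
  crs <- rarefaction_curve(singl, step = 10, iters = 3, seed = 3)
  expect_identical(crs$mean_obs, as.numeric(crs$depth))
  expect_true(all(diff(crs$mean_obs) > 0))
})

test_that("last-k diagnostics summarize the curve tail", {
  curve <- structure(
    data.frame(depth = seq(100, 2000, by = 100),
               mean_obs = rep(7, 20),
               mean_chao1 = as.numeric(1:20),
               mean_ace = seq(2, 40, by = 2)),
    class = c("rarefaction_curve", "data.frame"))
  expect_identical(last_k_average(curve, 10, "obs"), 7)
  expect_identical(last_k_average(curve, 10, "chao1"), 15.5)
  expect_error(last_k_average(curve[1:5, ], 10), "fewer than")

  expect_identical(curve_slope(curve, 10, "obs"), 0)
  expect_identical(curve_slope(curve, 10, "chao1"), 1)   # common difference
  expect_identical(curve_slope(curve, 10, "ace"), 2)
  expect_gt(curve_slope(curve, 5, "chao1"), 0)
  expect_error(curve_slope(curve[1:10, ], 10), "k \\+ 1")
})

test_that("log-normal fitting recovers generating parameters and flags degeneracy", {
  deg <- fit_lognormal(rep(3L, 20))
  expect_true(deg$degenerate)
  expect_identical(deg$sigma_hat, 0)
  expect_identical(deg$mu_hat, log(3))
  expect_error(fit_lognormal(1:5), "at least 10")

  set.seed(505)
  sizes <- sample_abundances(5000, 1.0, 1.2)
  fit <- fit_lognormal(sizes)
  expect_lt(abs(fit$mu_hat - 1.0), 3 * fit$sd_mu)
  expect_lt(abs(fit$sigma_hat - 1.2), 3 * fit$sd_sigma)

  # the naive log-moment fit is biased on this discretized data: farther from
  # the truth than the censored fit on both parameters
  mom <- fit_lognormal(sizes, method = "moments")
  expect_gt(abs(mom$mu_hat - 1.0), abs(fit$mu_hat - 1.0))
  expect_gt(abs(mom$sigma_hat - 1.2), abs(fit$sigma_hat - 1.2))

  # doubling every size shifts the log-location by log 2 and leaves the
  # log-scale spread untouched (exact for the moment estimator)
  m1 <- fit_lognormal(sizes, method = "moments")
  m2 <- fit_lognormal(2L * sizes, method = "moments")
  expect_equal(m2$mu_hat - m1$mu_hat, log(2), tolerance = 1e-12)
  expect_equal(m2$sigma_hat, m1$sigma_hat, tolerance = 1e-12)
})
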