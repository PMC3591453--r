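test_that("mutation events honor their type and count", {
  set.seed(301)
  s <- random_sequence(1000)
  expect_identical(mutate_sequence(s, 0), s)

  # substitution-only: Hamming distance bounded by the event count
  subs_only <- mutation_spec(0.5, 0.5, 0, 0)
  for (rep in 1:5) {
    m <- mutate_sequence(s, 5, subs_only)
    expect_identical(nchar(m), 1000L)
    hamming <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
    expect_lte(hamming, 5)
  }

  # transitions on an all-A sequence can only produce G
  allA <- strrep("A", 50)
  m <- mutate_sequence(allA, 1, mutation_spec(1, 0, 0, 0))
  tab <- table(strsplit(m, "")[[1]])
  expect_identical(as.integer(tab[["G"]]), 1L)
  expect_identical(as.integer(tab[["A"]]), 49L)

  # indels change the length by exactly one per event
  expect_identical(nchar(mutate_sequence(s, 1, mutation_spec(0, 0, 1, 0))), 1001L)
  expect_identical(nchar(mutate_sequence(s, 1, mutation_spec(0, 0, 0, 1))), 999L)
  expect_error(mutate_sequence("A", 1, mutation_spec(0, 0, 0, 1)), "length-1")
  expect_error(mutation_spec(0.5, 0.5, 0.5, 0), "sum to 1")
  expect_error(mutation_spec(-0.1, 1.1, 0, 0), "non-negative")
})

test_that("mutate_to_distance lands inside the acceptance band", {
  set.seed(302)
  s250 <- random_sequence(250)
  s592 <- random_sequence(592)
  expect_identical(mutate_to_distance(s250, 0, tol = 0.003), s250)
  # audited with the independent DP oracle over many seeded calls
  for (rep in 1:60) {
    m <- mutate_to_distance(s250, 0.0125, tol = 0.003)
    d <- nw_oracle(s250, m)$distance
    expect_gte(d, 0.0095); expect_lte(d, 0.0155)
  }
  for (rep in 1:20) {
    m <- mutate_to_distance(s592, 0.035, tol = 0.003)
    d <- nw_oracle(s592, m)$distance
    expect_gte(d, 0.032); expect_lte(d, 0.038)
  }
  expect_error(mutate_to_distance(s250, 0.5, max_events = 3), "failed to reach")
})

test_that("generated seed sets are mutually separated", {
  set.seed(303)
  one <- generate_seed_set(1, 100)
  expect_identical(nrow(one), 1L)

  seeds <- generate_seed_set(20, 600, 0.03)
  d <- utils::combn(20, 2, function(ix)
    pairwise_distance(seeds$sequence[ix[1]], seeds$sequence[ix[2]]))
  expect_length(d, 190L)
  expect_true(all(d > 0.03))

  # infeasible regime: cannot place 2 seeds at 90% separation on 10-mers
  expect_error(generate_seed_set(2, 10, 0.9, max_attempts = 30), "attempts")
})

test_that("greedy representative selection keeps exactly the separated prefix-survivors", {
  set.seed(304)
  far <- generate_seed_set(5, 200, 0.1)
  expect_identical(select_seed_representatives(far, 0.03)$id, far$id)

  s <- random_sequence(200)
  pool <- seq_records(c("a", "dup", "near", "b"),
                      c(s, s, mutate_to_distance(s, 0.01, tol = 0.003),
                        far$sequence[1]))
  kept <- select_seed_representatives(pool, 0.03)
  expect_identical(kept$id, c("a", "b"))
  expect_error(select_seed_representatives(pool[0, ], 0.03), "non-empty")
})

test_that("abundance sampling follows the discretized log-normal law", {
  set.seed(305)
  expect_true(all(sample_abundances(200, 0, 1e-9) == 1L))
  expect_true(all(sample_abundances(200, log(3), 1e-9) == 3L))
  x <- sample_abundances(5000, 1, 1)
  expect_gte(min(x), 1L)
  # sample mean of log counts vs the exact discretized expectation
  want <- discretized_lognormal_mean_log(1, 1)
  se <- sd(log(x)) / sqrt(length(x))
  expect_lt(abs(mean(log(x)) - want), 3 * se)
  expect_error(sample_abundances(10, 1, 0), "sigma")
})

test_that("built communities carry an exact planted truth", {
  comm <- fx_comm25()
  expect_identical(nrow(comm$reads), as.integer(sum(comm$truth)))
  expect_true(all(comm$reads$otu %in% comm$seeds$id))
  expect_identical(
    as.integer(table(factor(comm$reads$otu, levels = names(comm$truth)))),
    unname(comm$truth))

  # all pairwise seed distances exceed the design separation
  ds <- utils::combn(nrow(comm$seeds), 2, function(ix)
    pairwise_distance(comm$seeds$sequence[ix[1]], comm$seeds$sequence[ix[2]]))
  expect_true(all(ds > comm$design$seed_min_separation))

  # every non-seed read sits within member_distance + tol of its seed
  seed_seq <- setNames(comm$seeds$sequence, comm$seeds$id)
  d_to_seed <- vapply(seq_len(nrow(comm$reads)), function(i)
    pairwise_distance(comm$reads$sequence[i], seed_seq[[comm$reads$otu[i]]]),
    numeric(1))
  expect_true(all(d_to_seed <= comm$design$member_distance +
                    comm$design$distance_tol))
  # the first member of each OTU is the unmutated seed
  expect_true(all(seed_seq %in% comm$reads$sequence))

  tiny <- build_community(community_design(3, 0, 1e-9,
                                           seed_min_separation = 0.06),
                          seed = 5)
  expect_identical(nrow(tiny$reads), 3L)
  expect_setequal(tiny$reads$sequence, tiny$seeds$sequence)
})

test_that("replication multiplies reads and truth exactly and kills singletons", {
  comm <- fx_comm25()
  expect_identical(replicate_community(comm, 1), comm)
  x2 <- replicate_community(comm, 2)
  expect_identical(nrow(x2$reads), 2L * nrow(comm$reads))
  expect_identical(x2$truth, comm$truth * 2L)
  expect_false(anyDuplicated(x2$reads$id) > 0)

  cm <- greedy_cluster(x2$reads, 0.03)
  expect_length(singleton_ids(cm), 0L)
})
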