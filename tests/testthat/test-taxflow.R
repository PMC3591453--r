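test_that("quality filtering applies inclusive length bounds and the N rule", {
  reads <- seq_records(
    paste0("q", 1:10),
    c("ACGT", "ACG", "AC", "A", "ACGTN",
      "NACGT", "ACGTAC", "ACGTA", "ACGTACG", "ACGTACGTA"))
  # min_len 4 drops 3 short reads; max_n = 0 drops the 2 reads with N
  qf <- quality_filter(reads, min_len = 4, max_n = 0)
  expect_identical(nrow(qf$kept), 5L)
  expect_setequal(qf$dropped_ids, c("q2", "q3", "q4", "q5", "q6"))
  # boundary length is kept
  expect_true("q1" %in% qf$kept$id)
  # N allowed when max_n covers it
  qf2 <- quality_filter(reads, min_len = 4, max_n = 1)
  expect_true(all(c("q5", "q6") %in% qf2$kept$id))
})

test_that("exclusion lists remove exactly the named reads", {
  set.seed(601)
  reads <- seq_records(paste0("r", 1:10),
                       replicate(10, random_sequence(50)))
  expect_identical(remove_excluded(reads, character(0)), reads)
  expect_identical(nrow(remove_excluded(reads, reads$id)), 0L)
  kept <- remove_excluded(reads, c("r2", "r7"))
  expect_identical(kept$id, setdiff(reads$id, c("r2", "r7")))
  expect_warning(remove_excluded(reads, "ghost"), "not present")
})

test_that("taxonomy partition is a true partition with the U/N ratio", {
  set.seed(602)
  reads <- seq_records(paste0("r", 1:100),
                       replicate(100, random_sequence(60)))
  tax <- taxonomy_table(paste0("r", 1:83),
                        c(rep("target", 80), rep("contaminant", 3)))
  part <- partition_by_taxonomy(reads, tax)   # r84..r100 absent -> unclassified
  expect_identical(unname(part$counts[c("target", "contaminant", "unclassified")]),
                   c(80L, 3L, 17L))
  expect_identical(part$u_n_ratio, 0.17)
  expect_setequal(c(part$target$id, part$contaminant$id, part$unclassified$id),
                  reads$id)

  all_t <- partition_by_taxonomy(reads, taxonomy_table(reads$id,
                                                       rep("target", 100)))
  expect_identical(nrow(all_t$contaminant), 0L)
  expect_identical(nrow(all_t$unclassified), 0L)
})

test_that("the naive shared-k-mer classifier labels by best reference", {
  set.seed(603)
  refs <- generate_seed_set(4, 250, 0.2)
  refs$group <- c("target", "target", "contaminant", "contaminant")
  member <- mutate_to_distance(refs$sequence[2], 0.0125)
  reads <- seq_records(c("exact", "member", "noise"),
                       c(refs$sequence[1], member, random_sequence(250)))
  tax <- naive_classifier(reads, refs, k = 8, min_score = 0.5)
  expect_identical(tax$group[tax$read_id == "exact"], "target")
  expect_identical(tax$group[tax$read_id == "member"], "target")
  expect_identical(tax$group[tax$read_id == "noise"], "unclassified")
  expect_error(naive_classifier(reads, refs[0, ]), "non-empty")
})

test_that("unclassified singleton removal drops exactly the singleton clusters", {
  set.seed(604)
  # all mutually distant: everything is a singleton and everything is dropped
  far <- generate_seed_set(5, 250, 0.2)
  res <- filter_unclassified_singletons(far, 0.03)
  expect_identical(nrow(res$survivors), 0L)
  expect_setequal(res$dropped_ids, far$id)

  # every read duplicated: no singleton clusters can exist
  dup <- seq_records(paste0(rep(far$id, 2), c(rep("", 5), rep(".b", 5))),
                     rep(far$sequence, 2))
  res2 <- filter_unclassified_singletons(dup, 0.03)
  expect_identical(nrow(res2$survivors), 10L)
  expect_length(res2$dropped_ids, 0L)

  # planted OTUs of sizes 8,5,4,2,1: only the size-1 OTU is dropped
  planted <- make_planted(c(8, 5, 4, 2, 1), seed = 605)
  res3 <- filter_unclassified_singletons(planted, 0.03)
  expect_identical(nrow(res3$survivors), 19L)
  expect_length(res3$dropped_ids, 1L)
  expect_identical(planted$otu[planted$id %in% res3$dropped_ids],
                   planted$otu[nrow(planted)])

  none <- filter_unclassified_singletons(planted[0, ], 0.03)
  expect_identical(nrow(none$survivors), 0L)
})

test_that("pooling concatenates disjoint groups unchanged", {
  set.seed(606)
  target <- seq_records(paste0("t", 1:80), replicate(80, random_sequence(40)))
  surv <- seq_records(paste0("u", 1:15), replicate(15, random_sequence(40)))
  pooled <- pool_reads(target, surv)
  expect_identical(nrow(pooled), 95L)
  expect_identical(pooled$sequence, c(target$sequence, surv$sequence))
  expect_identical(pool_reads(target, surv[0, ]), target)
  expect_error(pool_reads(target, target[1, ]), "both groups")
})

test_that("the degenerate pipeline equals plain clustering and is deterministic", {
  comm <- fx_comm25()
  cfg <- run_config(rng_seed = 11, rarefaction_step = 50)
  rep1 <- run_pipeline(comm$reads, taxonomy = NULL, config = cfg)
  plain <- greedy_cluster(comm$reads, 0.03)
  av <- abundance_vector(plain)
  expect_identical(rep1$estimate$s_obs, length(av))
  expect_identical(rep1$estimate$chao1, chao1_corrected(av))
  expect_identical(rep1$estimate$ace, ace(av))
  expect_identical(unname(rep1$counts["pooled"]), nrow(comm$reads))

  rep2 <- run_pipeline(comm$reads, taxonomy = NULL, config = cfg)
  expect_identical(rep1$counts, rep2$counts)
  expect_identical(rep1$estimate, rep2$estimate)
  expect_identical(rep1$curve, rep2$curve)
})
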