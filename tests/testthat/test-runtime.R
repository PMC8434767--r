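test_that("round-robin placement deals evenly and keeps nesting co-located", {
  cfg <- cluster_config(n_partitions = 4)
  tbl <- tibble::tibble(x = 1:10)
  pb <- round_robin_partition(tbl, cfg)
  expect_equal(sort(vapply(pb$partitions, nrow, integer(1)),
                    decreasing = TRUE), c(3L, 3L, 2L, 2L))
  expect_equal(pb$guarantee, "none")

  # nested tuples travel with their parents
  nested <- tibble::tibble(k = c("a", "b"),
                           bag = list(list(list(g = "x"), list(g = "y")),
                                      list()))
  pb2 <- round_robin_partition(nested, cluster_config(2))
  expect_equal(nrcshred:::tbl_deep_count(pb2$partitions[[1]]), 3L)

  # empty input: all partitions empty
  pb3 <- round_robin_partition(tbl[0, ], cfg)
  expect_true(all(vapply(pb3$partitions, nrow, integer(1)) == 0L))
})

test_that("key shuffles establish co-residency and conserve tuples", {
  cfg <- cluster_config(n_partitions = 4, hash_seed = 3)
  set.seed(5)
  tbl <- tibble::tibble(k = sample(letters[1:6], 40, replace = TRUE),
                        v = rnorm(40))
  pb <- round_robin_partition(tbl, cfg)
  st <- new_exec_stats()
  sh <- shuffle_by_key(pb, "k", cfg, st)
  expect_equal(sh$guarantee, "k")
  expect_equal(sum(vapply(sh$partitions, nrow, integer(1))), nrow(tbl))
  # full-scan audit: each key lives in exactly one partition
  homes <- lapply(sh$partitions, function(df) unique(df$k))
  expect_equal(sum(lengths(homes)), length(unique(tbl$k)))
  expect_gt(st$shuffled_tuples, 0)

  # re-shuffling data already in place moves nothing
  st2 <- new_exec_stats()
  sh2 <- shuffle_by_key(sh, "k", cfg, st2)
  expect_equal(st2$shuffled_tuples, 0)

  # the skew pathology: one key collapses onto a single partition
  one <- tibble::tibble(k = rep("z", 20), v = 1:20)
  sh3 <- shuffle_by_key(round_robin_partition(one, cfg), "k", cfg)
  expect_equal(sum(vapply(sh3$partitions, nrow, integer(1)) > 0), 1L)
})

test_that("broadcast accounting charges size times partitions", {
  cfg <- cluster_config(n_partitions = 4)
  st <- new_exec_stats()
  broadcast(tibble::tibble(x = 1:5), cfg, st)
  expect_equal(st$broadcast_tuples, 20)
  broadcast(tibble::tibble(x = integer(0)), cfg, st)
  expect_equal(st$broadcast_tuples, 20)
})

test_that("execution is deterministic and partition-local at one partition", {
  sch <- omics_schemas()
  ds <- generate_dataset(gen_config(n_samples = 15, seed = 101))
  p <- program_suite("SGHybridScores")$SGHybridScores
  cfg <- cluster_config(n_partitions = 3, hash_seed = 7)
  r1 <- run_standard(p, sch, ds$data, cfg)
  r2 <- run_standard(p, sch, ds$data, cfg)
  expect_identical(r1$results, r2$results)
  expect_equal(r1$stats$shuffled_tuples, r2$stats$shuffled_tuples)
  expect_equal(r1$stats$max_partition_load, r2$stats$max_partition_load)

  # a single partition never moves anything
  r3 <- run_standard(p, sch, ds$data, cluster_config(n_partitions = 1))
  expect_equal(r3$stats$shuffled_tuples, 0)
})

test_that("the partition tuple cap reproduces the memory-pressure failure", {
  sch <- omics_schemas()
  ds <- generate_dataset(gen_config(n_samples = 30, seed = 111))
  p <- program_suite("SGHybridScores")$SGHybridScores
  cfg <- cluster_config(n_partitions = 2, partition_cap = 5)
  expect_error(run_standard(p, sch, ds$data, cfg), "cap exceeded")
})

test_that("the shredded route carries a lower maximum partition load when
           inner collections are large", {
  sch <- omics_schemas()
  # few top-level tuples with large inner bags: the standard route keeps
  # whole nested objects together while shredding distributes the children
  ds <- generate_dataset(gen_config(n_samples = 6, mutations_per_sample = 12,
                                    candidates_range = c(4L, 6L),
                                    p_empty_candidates = 0,
                                    genes_per_sample = 5, seed = 121))
  p <- program_suite("OccurGrouped")$OccurGrouped
  cfg <- cluster_config(n_partitions = 4)
  std <- run_standard(p, sch, ds$data, cfg)
  shr <- run_shredded(p, sch, ds$data, config = cfg)
  expect_true(bag_equal(std$results$OccurGrouped,
                        shr$results$OccurGrouped))
  expect_lt(shr$stats$max_partition_load, std$stats$max_partition_load)
})
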