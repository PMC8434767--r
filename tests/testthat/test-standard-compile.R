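test_that("compiled plans have the expected operator structure", {
  sch <- omics_schemas()
  suite <- program_suite()

  # the tumor-grouped program: flatten of candidates, joins against
  # CopyNumber and Samples, grouping back by the maintained id prefixes
  comp <- compile_standard(suite$TGHybridScores, sch)
  plan <- comp$plans$TGHybridScores$plan
  ops <- vapply(plan_ops(plan), function(p) p$op, character(1))
  expect_true("flatten" %in% ops)
  expect_true("join" %in% ops)
  expect_true(sum(ops == "group") >= 2)  # scores and samples levels
  scans <- vapply(plan_ops(plan, "scan"), function(p) p$name, character(1))
  expect_true(all(c("Occurrences", "CopyNumber", "Samples") %in% scans))

  # a flat program compiles without any flatten
  plan2 <- comp$plans$TumorSites$plan
  expect_length(plan_ops(plan2, "flatten"), 0)
  expect_length(plan_ops(plan2, "distinct"), 1)

  # plans print and serialize
  expect_match(format(plan), "OuterFlatten")
  expect_no_error(jsonlite::fromJSON(plan_to_json(plan)))
})

test_that("outer-flatten cardinality law and the naive loss phenomenon", {
  # definition: one padded row per empty parent
  r <- outer_flatten_cardinality(2, c(2, 0))
  expect_equal(r$outer, 3)
  expect_equal(r$naive, 2)
  # with no empty parents both flavors agree
  r <- outer_flatten_cardinality(3, c(1, 2, 5))
  expect_equal(r$outer, r$naive)
  expect_error(outer_flatten_cardinality(2, c(1, -1)), "negative")
  expect_error(outer_flatten_cardinality(2, c(1, 1, 1)), "one entry")

  # parents with empty inner bags survive the standard route but are lost
  # by the naive inner flatten
  sch <- omics_schemas()
  ds <- generate_dataset(gen_config(n_samples = 20, p_empty_candidates = 0.4,
                                    seed = 31))
  n_empty <- sum(vapply(ds$data$Occurrences, function(o)
    length(o$candidates) == 0, logical(1)))
  expect_gt(n_empty, 0)
  p <- program_suite("OccurrProj")$OccurrProj
  ref <- eval_reference(p, ds$data)$OccurrProj
  std <- run_standard(p, sch, ds$data)$results$OccurrProj
  naive <- run_standard(p, sch, ds$data, naive = TRUE)$results$OccurrProj
  expect_true(bag_equal(ref, std))
  expect_equal(length(std), length(ds$data$Occurrences))
  expect_equal(length(naive), length(ds$data$Occurrences) - n_empty)
})

test_that("projection pushdown prunes scans to the used attributes", {
  sch <- omics_schemas()
  p <- program_suite("OccurAgg")$OccurAgg
  comp <- compile_standard(p, sch)
  plan <- push_projections(comp$plans$OccurAgg$plan)

  # the Occurrences scans retain only sid plus candidates{gene, impact}
  kept <- list()
  for (pr in plan_ops(plan, "project")) {
    if (pr$inputs[[1]]$op == "scan" && pr$inputs[[1]]$name == "Occurrences") {
      for (e in pr$exprs) {
        if (e$kind == "colref") kept[[length(kept) + 1L]] <- e$name
        if (e$kind == "prunebag")
          kept[[length(kept) + 1L]] <- paste0(e$col, "{",
            paste(sort(names(e$fields)), collapse = ","), "}")
      }
    }
  }
  expect_true("sid" %in% unlist(kept))
  expect_true("candidates{gene,impact}" %in% unlist(kept))
  expect_false("mutationId" %in% unlist(kept))

  # pushdown is a fixpoint
  again <- push_projections(plan)
  expect_identical(format(again), format(plan))

  # results are unchanged, on shipped and random programs
  ds <- generate_dataset(gen_config(n_samples = 15, seed = 41))
  comp2 <- comp
  comp2$plans$OccurAgg$plan <- plan
  expect_true(bag_equal(
    execute_standard(comp, ds$data)$results$OccurAgg,
    execute_standard(comp2, ds$data)$results$OccurAgg))
  msch <- mini_schemas()
  for (seed in c(2, 3, 6)) {
    rp <- random_program(seed)
    inp <- mini_inputs(seed + 60)
    c0 <- compile_standard(rp, msch)
    c1 <- c0
    c1$plans$P$plan <- push_projections(c0$plans$P$plan)
    expect_true(bag_equal(execute_standard(c0, inp)$results$P,
                          execute_standard(c1, inp)$results$P))
  }
})

test_that("partial-aggregate pushdown preserves results and cuts shuffling", {
  sch <- omics_schemas()
  p <- program_suite("OccurAgg")$OccurAgg
  ds <- generate_dataset(gen_config(n_samples = 30, genes_per_sample = 8,
                                    candidates_range = c(2L, 4L), seed = 51))
  comp <- compile_standard(p, sch)
  comp2 <- comp
  comp2$plans$OccurAgg$plan <-
    push_partial_aggregates(comp$plans$OccurAgg$plan)
  # the rewrite introduced a local pre-aggregation below the join
  locals <- Filter(function(x) isTRUE(x$local),
                   plan_ops(comp2$plans$OccurAgg$plan, "sumby"))
  expect_gte(length(locals), 1)
  cfg <- cluster_config(n_partitions = 4)
  r0 <- execute_standard(comp, ds$data, cfg)
  r1 <- execute_standard(comp2, ds$data, cfg)
  expect_true(bag_equal(r0$results$OccurAgg, r1$results$OccurAgg))
  expect_lt(r1$stats$shuffled_tuples, r0$stats$shuffled_tuples)

  # inapplicable pattern: plan returned unchanged
  flat <- nrc_parse("S := sumBy[k; v](for x in A union { k := x.k, v := x.v })")
  cf <- compile_standard(flat, mini_schemas())
  expect_identical(format(push_partial_aggregates(cf$plans$S$plan)),
                   format(plan_index(cf$plans$S$plan)))
})

test_that("random programs compile to plans equivalent to the interpreter", {
  msch <- mini_schemas()
  for (seed in 1:15) {
    p <- random_program(seed)
    inp <- mini_inputs(seed + 200)
    ref <- eval_reference(p, inp)$P
    std <- run_standard(p, msch, inp)$results$P
    expect_true(bag_equal(ref, std), label = paste("program", seed))
  }
})

test_that("dense ids never leak into user-visible output", {
  sch <- omics_schemas()
  ds <- generate_dataset(gen_config(n_samples = 10, seed = 61))
  res <- run_standard(program_suite("OccurrProj")$OccurrProj, sch,
                      ds$data)$results$OccurrProj
  expect_setequal(names(res[[1]]), c("sid", "candidates"))
})
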