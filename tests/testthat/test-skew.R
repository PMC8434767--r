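make_pbag <- function(keys, n_partitions = 4, extra = NULL) {
  tbl <- tibble::tibble(key = keys, x = seq_along(keys))
  if (!is.null(extra)) for (nm in names(extra)) tbl[[nm]] <- extra[[nm]]
  round_robin_partition(tbl, cluster_config(n_partitions))
}

key_names <- function(ks) paste0("s:", ks)

test_that("full detection applies the threshold to exact global shares", {
  # one key holding 60 of 85 tuples is heavy at the 2.5% default
  pb <- make_pbag(c(rep("big", 60), paste0("k", 1:25)))
  rep_ <- detect_heavy_keys(pb, "key", skew_config("full"))
  expect_true(key_names("big") %in% rep_$heavy_keys)
  expect_equal(rep_$tuples_inspected, 85L)

  # 100 keys x 10 tuples each: every share is 1%, below 2.5%
  pb2 <- make_pbag(rep(paste0("k", 1:100), each = 10))
  rep2 <- detect_heavy_keys(pb2, "key", skew_config("full"))
  expect_length(rep2$heavy_keys, 0)

  # a share exactly at the threshold counts as heavy
  pb3 <- make_pbag(c(rep("a", 1), rep("b", 39)))
  rep3 <- detect_heavy_keys(pb3, "key", skew_config("full"))
  expect_true(key_names("a") %in% rep3$heavy_keys)  # 1/40 = 2.5%

  expect_length(detect_heavy_keys(make_pbag(character(0)), "key",
                                  skew_config("full"))$heavy_keys, 0)
})

test_that("full detection equals the exact frequency oracle on random fixtures", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(50:200, 1)
    a <- runif(1, 0.5, 2)
    keys <- paste0("k", sample.int(30, n, replace = TRUE,
                                   prob = (1:30)^(-a)))
    pb <- make_pbag(keys, n_partitions = sample(2:6, 1))
    rep_ <- detect_heavy_keys(pb, "key", skew_config("full"))
    tab <- table(keys) / n
    oracle <- key_names(names(tab)[as.numeric(tab) >= 0.025])
    expect_setequal(rep_$heavy_keys, oracle)
  }
})

test_that("slice inspects only each partition's leading range", {
  # key Z only appears after position 1000 in every partition: slice misses
  # it, full finds it
  part <- c(rep("a", 1000), rep("Z", 500))
  pb <- partitioned_bag(lapply(1:3, function(i)
    tibble::tibble(key = part, x = seq_along(part))), "none")
  sl <- detect_heavy_keys(pb, "key", skew_config("slice", slice_size = 1000))
  fu <- detect_heavy_keys(pb, "key", skew_config("full"))
  expect_false(key_names("Z") %in% sl$heavy_keys)
  expect_true(key_names("Z") %in% fu$heavy_keys)
  expect_equal(sl$tuples_inspected, 3000L)
})

test_that("partial and sample methods are local and seeded respectively", {
  part_big <- tibble::tibble(key = c(rep("loc", 50), paste0("k", 1:5)),
                             x = 1:55)
  part_small <- tibble::tibble(key = paste0("q", 1:3000), x = 1:3000)
  pb <- partitioned_bag(list(part_big, part_small), "none")
  # "loc" is heavy within its partition although globally below threshold
  pa <- detect_heavy_keys(pb, "key", skew_config("partial"))
  fu <- detect_heavy_keys(pb, "key", skew_config("full"))
  expect_true(key_names("loc") %in% pa$heavy_keys)
  expect_false(key_names("loc") %in% fu$heavy_keys)

  s1 <- detect_heavy_keys(pb, "key", skew_config("sample", rng_seed = 4))
  s2 <- detect_heavy_keys(pb, "key", skew_config("sample", rng_seed = 4))
  expect_identical(s1$heavy_keys, s2$heavy_keys)
  expect_lt(s1$tuples_inspected, 3055L)
})

test_that("skew-aware joins equal the skew-unaware join with lower max load", {
  set.seed(17)
  n <- 10000
  keys <- paste0("k", sample.int(200, n, replace = TRUE,
                                 prob = (1:200)^(-1.2)))
  left <- tibble::tibble(key = keys, x = seq_len(n))
  right <- tibble::tibble(key = paste0("k", 1:200), y = round(rnorm(200), 3))
  base_cfg <- cluster_config(8)
  lp <- round_robin_partition(left, base_cfg)
  rp <- round_robin_partition(right, base_cfg)
  st0 <- new_exec_stats()
  r0 <- shuffle_join(lp, rp, "key", base_cfg, st0)
  expected <- tbl_to_bag(pbag_collect(r0))
  for (m in c("full", "partial", "sample", "slice")) {
    cfg <- cluster_config(8, skew = skew_config(m, slice_size = 200))
    st <- new_exec_stats()
    r <- skew_aware_join(lp, rp, "key", cfg, st)
    expect_true(bag_equal(tbl_to_bag(pbag_collect(r)), expected),
                label = m)
    if (m == "full")
      expect_lt(st$max_partition_load, st0$max_partition_load)
  }

  # no heavy keys: identical result and stats to the skew-unaware join
  uk <- tibble::tibble(key = paste0("u", 1:400), x = 1:400)
  up <- round_robin_partition(uk, base_cfg)
  stA <- new_exec_stats(); stB <- new_exec_stats()
  rA <- shuffle_join(up, rp, "key", base_cfg, stA)
  rB <- skew_aware_join(up, rp, "key",
                        cluster_config(8, skew = skew_config("full")), stB)
  expect_true(bag_equal(tbl_to_bag(pbag_collect(rA)),
                        tbl_to_bag(pbag_collect(rB))))
  expect_equal(stA$shuffled_tuples, stB$shuffled_tuples)
  expect_equal(stA$broadcast_tuples, stB$broadcast_tuples)

  # a single heavy key: nothing on the left moves, the matching right
  # tuples are broadcast everywhere
  one <- tibble::tibble(key = rep("hot", 100), x = 1:100)
  op <- round_robin_partition(one, base_cfg)
  match_r <- tibble::tibble(key = "hot", y = 1)
  mp <- round_robin_partition(match_r, base_cfg)
  st1 <- new_exec_stats()
  r1 <- skew_aware_join(op, mp, "key",
                        cluster_config(8, skew = skew_config("full")), st1)
  expect_equal(st1$shuffled_tuples, 0)
  expect_equal(st1$broadcast_tuples, 1 * 8)
  expect_equal(sum(vapply(r1$partitions, nrow, integer(1))), 100L)
})

test_that("skew-aware grouping leaves heavy groups distributed in place", {
  set.seed(23)
  keys <- c(rep("dom", 900), paste0("k", sample.int(50, 100,
                                                    replace = TRUE)))
  tbl <- tibble::tibble(key = keys, x = seq_along(keys))
  cfg0 <- cluster_config(4)
  pb <- round_robin_partition(tbl, cfg0)
  cfg <- cluster_config(4, skew = skew_config("full"))
  st <- new_exec_stats()
  g <- skew_aware_group(pb, "key", cfg, st)
  expect_true(key_names("dom") %in% g$heavy_keys)
  # the dominant group's tuples stayed on their origin partitions
  origin <- vapply(pb$partitions, function(df) sum(df$key == "dom"),
                   integer(1))
  staying <- vapply(g$heavy$partitions, function(df) sum(df$key == "dom"),
                    integer(1))
  expect_equal(staying, origin)
  # max load during grouping never exceeds the input partition load
  input_load <- max(vapply(pb$partitions, nrow, integer(1)))
  heavy_load <- max(vapply(g$heavy$partitions, nrow, integer(1)))
  expect_lte(heavy_load, input_load)

  # the assembled logical result equals skew-unaware grouping
  assembled <- sg_assemble(g)
  ref <- tapply(tbl$x, tbl$key, function(v) sort(v))
  expect_equal(nrow(assembled), length(ref))
  got <- stats::setNames(lapply(assembled$.group, function(grp)
    sort(vapply(grp, function(t) t$x, numeric(1)))),
    sub("^s:", "", assembled$key))
  for (k in names(ref))
    expect_equal(got[[k]], as.numeric(ref[[k]]), label = k)

  # aggregation over heavy groups equals reference sums
  sums <- sg_sumby(g, "x")
  ref_sums <- tapply(tbl$x, tbl$key, sum)
  got_sums <- stats::setNames(sums$x, sub("^s:", "", sums$key))
  expect_equal(as.numeric(got_sums[names(ref_sums)]),
               as.numeric(ref_sums))

  # uniform keys: identical to skew-unaware grouping
  u <- tibble::tibble(key = paste0("u", 1:100), x = 1:100)
  gu <- skew_aware_group(round_robin_partition(u, cfg0), "key", cfg)
  expect_length(gu$heavy_keys, 0)
  expect_equal(nrow(sg_assemble(gu)), 100L)
})
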