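# shared fixtures: a miniature nested schema pair, tiny hand inputs, and a
# seeded random-program generator used by the property tests

mini_schemas <- function() {
  s <- nt_scalar
  list(
    A = nt_bag(nt_tuple(list(
      k = s("string"), v = s("real"),
      items = nt_bag(nt_tuple(list(g = s("string"), w = s("real"))))))),
    B = nt_bag(nt_tuple(list(k = s("string"), g = s("string"),
                             u = s("real")))))
}

mini_inputs <- function(seed = 1, n_a = 12, n_b = 10, p_empty = 0.3) {
  set.seed(seed)
  ks <- paste0("k", 1:4)
  gs <- paste0("g", 1:3)
  A <- lapply(seq_len(n_a), function(i) {
    n_items <- if (runif(1) < p_empty) 0L else sample(1:3, 1)
    list(k = sample(ks, 1), v = round(runif(1), 2),
         items = lapply(seq_len(n_items), function(j)
           list(g = sample(gs, 1), w = round(runif(1), 2))))
  })
  B <- lapply(seq_len(n_b), function(i)
    list(k = sample(ks, 1), g = sample(gs, 1), u = round(runif(1), 2)))
  list(A = A, B = B)
}

# random small programs over the mini schemas, spanning scans, nested
# iteration, equi-joins, filters, dedup, sumBy and groupBy
random_program <- function(seed) {
  set.seed(seed)
  shape <- sample(1:6, 1)
  src <- switch(shape,
    "P := for x in A union { k := x.k, items := for y in x.items union { g := y.g, w := y.w } }",
    "P := for x in A union
       { k := x.k, v := x.v,
         joined := for y in x.items union
           for b in B union
             if (b.k == x.k && b.g == y.g) then
               { g := y.g, s := y.w * b.u } }",
    "P := for x in A union
       { k := x.k,
         sums := sumBy[g; s](
           for y in x.items union
             for b in B union
               if (b.k == x.k && b.g == y.g) then
                 { g := y.g, s := y.w * b.u } ) }",
    "P := sumBy[k; v](for x in A union { k := x.k, v := x.v })",
    "P := dedup(for b in B union { k := b.k, g := b.g })",
    "P := groupBy[k -> grp](for b in B union { k := b.k, g := b.g, u := b.u })")
  nrc_parse(src)
}

# run a program through all three routes and return the three results of
# its final assignment
three_routes <- function(program, schemas, inputs,
                         config = cluster_config(n_partitions = 3)) {
  nm <- utils::tail(vapply(program$assignments, `[[`, character(1), "name"),
                    1)
  list(reference = eval_reference(program, inputs)[[nm]],
       standard = run_standard(program, schemas, inputs, config)$results[[nm]],
       shredded = run_shredded(program, schemas, inputs)$results[[nm]])
}

expect_three_way_equal <- function(program, schemas, inputs, ...) {
  r <- three_routes(program, schemas, inputs, ...)
  expect_true(bag_equal(r$reference, r$standard))
  expect_true(bag_equal(r$reference, r$shredded))
  invisible(r)
}
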