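test_that("typechecking infers nested output types and rejects errors", {
  sch <- omics_schemas()
  suite <- program_suite()

  # projection preserves the nested structure with only the kept attributes
  ty <- typecheck(suite$OccurrProj, sch)$OccurrProj
  expect_true(type_equal(ty, nt_bag(nt_tuple(list(
    sid = nt_scalar("string"),
    candidates = nt_bag(nt_tuple(list(gene = nt_scalar("string"),
                                      impact = nt_scalar("real")))))))))

  # the tumor-grouped program's three-level output type
  ty <- typecheck(suite$TGHybridScores, sch)$TGHybridScores
  expect_true(type_equal(ty, nt_bag(nt_tuple(list(
    tumorsite = nt_scalar("string"),
    samples = nt_bag(nt_tuple(list(
      sid = nt_scalar("string"),
      scores = nt_bag(nt_tuple(list(gene = nt_scalar("string"),
                                    score = nt_scalar("real"))))))))))))

  # sumBy over input with a bag-typed attribute is rejected
  bad <- nrc_parse("P := sumBy[sid; start](for o in Occurrences union
    { sid := o.sid, start := o.start, candidates := for c in o.candidates union
      { gene := c.gene } })")
  expect_error(typecheck(bad, sch), "flat input")

  expect_error(typecheck(nrc_parse("P := for x in NoSuch union { a := x.a }"),
                         sch), "unknown input")
  expect_error(typecheck(nrc_parse("P := for s in Samples union { a := s.nope }"),
                         sch), "attribute not found")
  expect_error(typecheck(nrc_parse(
    "P := for s in Samples union if (s.sid == 1) then { a := s.sid }"), sch),
    "type mismatch")
})

test_that("reference evaluation matches hand-computed nested semantics", {
  sch <- omics_schemas()
  p <- program_suite("OccurAgg")$OccurAgg
  occ <- list(list(sid = "s1", contig = "chr1", start = 1L, end = 1L,
                   reference = "A", alternate = "T", mutationId = "m1",
                   candidates = list(
                     list(gene = "g1", impact = 2.0, sift = 0.5, poly = 0.5,
                          consequences = list()),
                     list(gene = "g1", impact = 1.0, sift = 0.5, poly = 0.5,
                          consequences = list()))))
  cn <- list(list(sid = "s1", gene = "g1", cnum = 3L))
  res <- eval_reference(p, list(Occurrences = occ, CopyNumber = cn))$OccurAgg
  # score = (2.0 + 1.0) * 3
  expect_true(bag_equal(res, list(list(sid = "s1", scores = list(
    list(gene = "g1", score = 9.0))))))

  # all-empty inputs give empty bags at every level
  res0 <- eval_reference(p, list(Occurrences = list(),
                                 CopyNumber = list()))$OccurAgg
  expect_identical(res0, list())

  # dedup removes duplicates by deep equality
  pd <- nrc_parse("D := dedup(for s in Samples union { t := s.tumorsite })")
  smp <- list(list(sid = "a", tumorsite = "brain", aliquot = "a-1"),
              list(sid = "b", tumorsite = "brain", aliquot = "b-1"),
              list(sid = "c", tumorsite = "lung", aliquot = "c-1"))
  res <- eval_reference(pd, list(Samples = smp))$D
  expect_true(bag_equal(res, list(list(t = "brain"), list(t = "lung"))))

  # division by zero is an error
  pz <- nrc_parse("Z := for b in B union { r := b.u / 0 }")
  expect_error(eval_reference(pz, mini_inputs(1)), "division by zero")
})

test_that("bag equality is multiset equality, insensitive to order", {
  a <- list(list(x = 1, ys = list(list(z = "p"), list(z = "q"))),
            list(x = 2, ys = list()))
  perm <- list(a[[2]], list(x = 1, ys = list(list(z = "q"), list(z = "p"))))
  expect_true(bag_equal(a, perm))
  # multiplicity matters
  dup <- c(a, list(a[[2]]))
  expect_false(bag_equal(a, dup))
  # differing scalar
  b <- a; b[[1]]$x <- 3
  expect_false(bag_equal(a, b))
  # tiny numeric noise from reordering sums compares equal
  expect_true(bag_equal(list(list(x = 0.1 + 0.2)), list(list(x = 0.3))))
})

test_that("evaluation is insensitive to input bag order", {
  sch <- mini_schemas()
  inp <- mini_inputs(5)
  p <- random_program(3)
  r1 <- eval_reference(p, inp)$P
  set.seed(9)
  inp2 <- list(A = sample(inp$A), B = sample(inp$B))
  r2 <- eval_reference(p, inp2)$P
  expect_true(bag_equal(r1, r2))
})

test_that("grouping then re-flattening returns the original flat bag", {
  inp <- mini_inputs(7)
  g <- nrc_parse("G := groupBy[k -> grp](for b in B union
    { k := b.k, g := b.g, u := b.u })")
  fl <- nrc_parse("G := groupBy[k -> grp](for b in B union
    { k := b.k, g := b.g, u := b.u })
    F := for x in G union for y in x.grp union
      { k := x.k, g := y.g, u := y.u }")
  flat <- eval_reference(fl, inp)$F
  orig <- eval_reference(
    nrc_parse("O := for b in B union { k := b.k, g := b.g, u := b.u }"),
    inp)$O
  expect_true(bag_equal(flat, orig))
})

test_that("well-typed random programs evaluate without errors", {
  sch <- mini_schemas()
  for (seed in 1:15) {
    p <- random_program(seed)
    expect_no_error(typecheck(p, sch))
    inp <- mini_inputs(seed + 100)
    expect_no_error(eval_reference(p, inp))
  }
})
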