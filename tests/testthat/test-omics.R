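test_that("the suite ships all seventeen programs with the printed types", {
  suite <- program_suite()
  expect_length(suite, 17)
  sch <- omics_schemas()
  tys <- lapply(suite, typecheck, input_schemas = sch)

  # sample-grouped hybrid scores: [ { sid, scores: [ { gene, score } ] } ]
  expect_true(type_equal(tys$SGHybridScores$SGHybridScores,
    nt_bag(nt_tuple(list(sid = nt_scalar("string"),
      scores = nt_bag(nt_tuple(list(gene = nt_scalar("string"),
                                    score = nt_scalar("real")))))))))
  # connectivity is a flat gene/score bag
  expect_true(type_equal(tys$Connectivity$Connectivity,
    nt_bag(nt_tuple(list(gene = nt_scalar("string"),
                         score = nt_scalar("real"))))))
  # the clinical grouping retains candidates and consequences under
  # mutations
  og <- tys$OccurGrouped$OccurGrouped
  mut <- og$elem$fields$mutations$elem
  expect_true("candidates" %in% names(mut$fields))
  expect_true("consequences" %in%
                names(mut$fields$candidates$elem$fields))
  # gene burden output nests per-sample burdens under each gene
  gb <- tys$GeneBurden$GeneBurden
  expect_true(type_equal(gb, nt_bag(nt_tuple(list(
    gene = nt_scalar("string"),
    burdens = nt_bag(nt_tuple(list(sid = nt_scalar("string"),
                                   burden = nt_scalar("real")))))))))
})

test_that("gene burden sums genotype calls over position-associated variants", {
  genes <- list(list(gene = "G1", contig = "chr1", start = 100L, end = 200L,
                     protein = "p1"))
  variants <- list(list(contig = "chr1", start = 150L, reference = "A",
                        alternate = "T",
                        genotypes = list(list(sid = "a", call = 2L),
                                         list(sid = "b", call = 0L))))
  r <- gene_burden(variants, genes)
  expect_true(bag_equal(r, list(list(gene = "G1", burdens = list(
    list(sid = "a", burden = 2), list(sid = "b", burden = 0))))))

  # a variant off the gene contributes nothing (empty burdens bag)
  far <- list(list(contig = "chr1", start = 250L, reference = "A",
                   alternate = "T",
                   genotypes = list(list(sid = "a", call = 1L))))
  r2 <- gene_burden(far, genes)
  expect_true(bag_equal(r2, list(list(gene = "G1", burdens = list()))))

  # a 100 bp flanking region re-includes it
  r3 <- gene_burden(far, genes, score_params(flanking_bp = 100L))
  expect_true(bag_equal(r3, list(list(gene = "G1", burdens = list(
    list(sid = "a", burden = 1))))))
})

test_that("pathway burden sums impact, or raw counts in count mode", {
  occ <- list(list(sid = "s1", contig = "chr1", start = 1L, end = 1L,
                   reference = "A", alternate = "T", mutationId = "m1",
                   candidates = list(
                     list(gene = "g1", impact = 0.5, sift = 0, poly = 0,
                          consequences = list()),
                     list(gene = "g2", impact = 0.3, sift = 0, poly = 0,
                          consequences = list()))),
              list(sid = "s2", contig = "chr1", start = 2L, end = 2L,
                   reference = "A", alternate = "T", mutationId = "m2",
                   candidates = list()))
  pw <- list(list(pathway = "P", genes = list(list(gene = "g1"),
                                              list(gene = "g2"))))
  r <- pathway_burden(occ, pw)
  expect_true(bag_equal(r, list(list(pathway = "P", burdens = list(
    list(sid = "s1", burden = 0.8))))))
  r2 <- pathway_burden(occ, pw, mode = "count")
  expect_true(bag_equal(r2, list(list(pathway = "P", burdens = list(
    list(sid = "s1", burden = 2))))))
})

test_that("pathway burden in count mode is additive over member genes", {
  ds <- generate_dataset(gen_config(n_samples = 15, seed = 131))
  pw <- ds$data$Pathways[[1]]
  member_genes <- vapply(pw$genes, function(g) g$gene, character(1))
  whole <- pathway_burden(ds$data$Occurrences, list(pw), mode = "count")
  # per-gene burden from singleton pathways
  singles <- lapply(member_genes, function(g)
    pathway_burden(ds$data$Occurrences,
                   list(list(pathway = g, genes = list(list(gene = g)))),
                   mode = "count"))
  per_sid <- list()
  for (s in singles) {
    if (!length(s)) next
    for (b in s[[1]]$burdens) {
      prev <- if (is.null(per_sid[[b$sid]])) 0 else per_sid[[b$sid]]
      per_sid[[b$sid]] <- prev + b$burden
    }
  }
  got <- list()
  for (b in whole[[1]]$burdens) got[[b$sid]] <- b$burden
  expect_equal(got[order(names(got))], per_sid[order(names(per_sid))])
})

test_that("burden features form a labeled sample-by-pathway matrix", {
  pmb <- list(list(pathway = "P1", burdens = list(
                list(sid = "a", burden = 2), list(sid = "b", burden = 1))),
              list(pathway = "P2", burdens = list(
                list(sid = "a", burden = 5))),
              list(pathway = "P3", burdens = list()))
  samples <- list(list(sid = "a", tumorsite = "lung", aliquot = "a-1"),
                  list(sid = "b", tumorsite = "brain", aliquot = "b-1"))
  m <- burden_features(pmb, samples)
  expect_equal(dim(m), c(2L, 2L + 3L))
  expect_equal(m$P2, c(5, 0))   # absent burden filled with 0
  expect_equal(m$tumorsite, c("lung", "brain"))

  # unknown samples are dropped with a warning
  pmb2 <- c(pmb, list(list(pathway = "P1", burdens = list(
    list(sid = "zz", burden = 9)))))
  expect_warning(burden_features(pmb2, samples), "zz")

  # matrix round-trips through the TSV writer/reader
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(as.data.frame(m), back)
})

test_that("the driver pipeline follows its closed-form on a one-gene system", {
  # single sample, one gene with hybrid score h = impact * soimpact * cnum,
  # a self-edge of distance d, and expression f:
  # connectivity = (h * d + h) * f
  h <- 0.8 * 0.9 * 3; d <- 0.5; f <- 2.0
  data <- list(
    Samples = list(list(sid = "s1", tumorsite = "lung", aliquot = "q1")),
    Occurrences = list(list(sid = "s1", contig = "chr1", start = 10L,
                            end = 10L, reference = "A", alternate = "T",
                            mutationId = "m1",
                            candidates = list(list(gene = "G", impact = 0.8,
                              sift = 0, poly = 0,
                              consequences = list(list(conseq = "sg")))))),
    CopyNumber = list(list(sid = "s1", gene = "G", cnum = 3L)),
    SOImpact = list(list(conseq = "sg", score = 0.9)),
    GeneMap = list(list(gene = "G", contig = "chr1", start = 1L, end = 100L,
                        protein = "pG")),
    Network = list(list(nodeProtein = "pG", edgeProtein = "pG",
                        distance = d)),
    GeneExpression = list(list(aliquot = "q1", gene = "G", fpkm = f)))
  out <- driver_pipeline(data, route = "reference")
  expect_equal(out$connectivity$gene, "G")
  expect_equal(out$connectivity$score, (h * d + h) * f, tolerance = 1e-9)

  # empty network: the effect score reduces to the node-only hybrid term
  data2 <- data
  data2$Network <- list()
  out2 <- driver_pipeline(data2, route = "reference")
  expect_equal(out2$connectivity$score, h * f, tolerance = 1e-9)

  # raising the gene's expression never lowers its connectivity
  data3 <- data
  data3$GeneExpression[[1]]$fpkm <- f * 10
  out3 <- driver_pipeline(data3, route = "reference")
  expect_gt(out3$connectivity$score, out$connectivity$score)
})

test_that("samples without an aliquot mapping are excluded with a warning", {
  ds <- generate_dataset(gen_config(n_samples = 8, seed = 141))
  ds$data$Samples[[1]]$aliquot <- NA
  expect_warning(driver_pipeline(ds$data, route = "reference"),
                 "without an aliquot")
})

test_that("accuracy from confusion counts", {
  expect_equal(accuracy_from_counts(444, 1049), 42.32)
  expect_equal(accuracy_from_counts(2744, 3498), 78.44)
  expect_equal(accuracy_from_counts(0, 10), 0)
  expect_error(accuracy_from_counts(5, 0), "positive")
  expect_error(accuracy_from_counts(11, 10), "correct")
})
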