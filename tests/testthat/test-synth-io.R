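test_that("generation is deterministic and honors its structural knobs", {
  cf <- gen_config(n_samples = 10, p_empty_candidates = 0.3, seed = 7)
  d1 <- generate_dataset(cf)
  d2 <- generate_dataset(cf)
  expect_identical(d1, d2)
  validate_dataset(d1)

  # p_empty_candidates = 1 empties every candidates bag
  all_empty <- generate_dataset(gen_config(n_samples = 10,
                                           p_empty_candidates = 1, seed = 7))
  expect_true(all(vapply(all_empty$data$Occurrences, function(o)
    length(o$candidates) == 0, logical(1))))

  # a Zipf exponent of 1.5 pushes the dominant tumor site far past the
  # 2.5% heavy-key threshold
  sk <- generate_dataset(gen_preset("skewed", seed = 7))
  shares <- table(vapply(sk$data$Samples, function(s) s$tumorsite,
                         character(1))) / length(sk$data$Samples)
  expect_gt(max(shares), 0.025)

  # sharing rate reuses annotations across samples
  sh <- generate_dataset(gen_preset("sharing", seed = 7))
  expect_lt(length(sh$data$Annotations), length(sh$data$Mutations))

  expect_error(gen_config(mutations_per_sample = 0,
                          annotation_sharing_rate = 0.5), "sharing")
})

test_that("VCF encoding maps genotypes to 0/1/2 allele dosages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1|1\t0/0",
    "chr2\t200\t.\tG\tC,A\t.\tPASS\t.\tGT\t1/2\t2/2\t./."),
    path)
  expect_warning(v <- read_variants_vcf(path), "missing GT")
  # heterozygous is 1, phased homozygous alternate is 2
  calls1 <- vapply(v[[1]]$genotypes, function(g) g$call, integer(1))
  expect_equal(calls1, c(1L, 2L, 0L))
  # the multi-allelic record splits into one record per alternate allele,
  # counting that allele's copies
  expect_length(v, 3)
  expect_equal(v[[2]]$alternate, "C")
  expect_equal(vapply(v[[2]]$genotypes, function(g) g$call, integer(1)),
               c(1L, 0L, 0L))
  expect_equal(v[[3]]$alternate, "A")
  expect_equal(vapply(v[[3]]$genotypes, function(g) g$call, integer(1)),
               c(1L, 2L, 0L))
  expect_error(read_variants_vcf(
    withr::local_tempfile(lines = "chr1\t1", fileext = ".vcf")),
    "malformed")
})

test_that("generated datasets round-trip through their native formats", {
  ds <- generate_dataset(gen_config(n_samples = 8, seed = 17))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  for (nm in names(ds$data))
    expect_true(bag_equal(ds$data[[nm]], back$data[[nm]]), label = nm)

  # GMT: name, description, then member genes
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("P1\tdesc\tg1\tg2", gmt)
  pw <- read_gmt(gmt)
  expect_true(bag_equal(pw, list(list(pathway = "P1",
                                      genes = list(list(gene = "g1"),
                                                   list(gene = "g2"))))))
})
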