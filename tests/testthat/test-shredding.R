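test_that("type shredding emits one flat relation per collection level", {
  sch <- omics_schemas()
  ss <- shred_type(sch$Occurrences, "Occurrences")
  expect_length(ss$relations, 3)
  expect_setequal(names(ss$relations),
                  c("Occurrences_top", "Occurrences_candidates",
                    "Occurrences_candidates_consequences"))
  # the top relation's candidates attribute is a label referencing the
  # candidates dictionary; the dictionaries carry a label key field
  top <- ss$relations$Occurrences_top
  expect_true(is_label_type(top$fields$candidates))
  expect_null(top$label_field)
  cand <- ss$relations$Occurrences_candidates
  expect_equal(cand$label_field, "label")

  # a flat type shreds to a single relation without labels
  flat <- shred_type(sch$Samples, "Samples")
  expect_length(flat$relations, 1)
  expect_equal(names(flat$relations), "Samples")

  # the tumor-grouped output type has three levels
  ty <- typecheck(program_suite("TGHybridScores")$TGHybridScores,
                  sch)$TGHybridScores
  expect_length(shred_type(ty, "TGHybridScores")$relations, 3)

  expect_error(shred_type(nt_tuple(list(a = nt_scalar("int")))))
})

test_that("value shredding round-trips, keeps empty bags, shares dictionaries", {
  sch <- mini_schemas()
  ss <- shred_type(sch$A, "A")
  v <- list(
    list(k = "k1", v = 1.0, items = list(list(g = "x", w = 0.1),
                                         list(g = "y", w = 0.2))),
    list(k = "k2", v = 2.0, items = list()),
    list(k = "k3", v = 3.0, items = list(list(g = "x", w = 0.1),
                                         list(g = "y", w = 0.2))))
  sv <- shred_value(v, ss)
  # labels per parent; the empty bag is an empty dictionary entry, not dropped
  expect_length(sv$dicts$A_items, 3)
  expect_true(any(vapply(sv$dicts$A_items, length, integer(1)) == 0))
  expect_true(bag_equal(unshred_value(sv), v))

  # sharing-aware: identical inner bags collapse to one entry
  svs <- shred_value(v, ss, sharing = TRUE)
  expect_length(svs$dicts$A_items, 2)
  expect_true(bag_equal(unshred_value(svs), v))

  # three-level round trip on generated occurrences
  osch <- omics_schemas()
  ds <- generate_dataset(gen_config(n_samples = 15, seed = 71))
  oss <- shred_type(osch$Occurrences, "Occurrences")
  osv <- shred_value(ds$data$Occurrences, oss)
  expect_true(bag_equal(unshred_value(osv), ds$data$Occurrences))

  # a dangling label is a hard integrity error
  broken <- sv
  broken$top[[1]]$items <- "L<A_items>#999"
  expect_error(unshred_value(broken), "dangling label")
})

test_that("program shredding emits one flat component per output level", {
  sch <- omics_schemas()
  suite <- program_suite()
  sp <- shred_program(suite$TGHybridScores, sch)
  expect_equal(sp$components$TGHybridScores,
               c("TGHybridScores_top", "TGHybridScores_samples",
                 "TGHybridScores_samples_scores"))
  # the flat-in/flat-out assignment shreds to a single identity-like program
  expect_equal(sp$components$TumorSites, "TumorSites_top")
  # every component is flat-typed (labels are scalars)
  for (a in sp$flat_program$assignments) {
    ty <- sp$schemas[[a$name]]
    expect_true(is_flat_tuple(ty$elem), label = a$name)
  }
  # two output levels for the projection program
  sp2 <- shred_program(suite$OccurrProj, sch)
  expect_length(sp2$components$OccurrProj, 2)
})

test_that("shredded evaluation is localized and label contexts are minimal", {
  sch <- omics_schemas()
  sp <- shred_program(program_suite("TGHybridScores")$TGHybridScores, sch)
  # the scores component reassociates top and candidates relations only:
  # it never reads the consequences dictionary it does not reference
  reads <- component_reads <- sp$flat_program$assignments
  scores_reads <- nrcshred:::input_refs(
    sp$flat_program$assignments[[which(vapply(reads, `[[`, character(1),
      "name") == "TGHybridScores_samples_scores")]]$expr)
  expect_true("Occurrences_top" %in% scores_reads)
  expect_true("Occurrences_candidates" %in% scores_reads)
  expect_false("Occurrences_candidates_consequences" %in% scores_reads)

  # the samples-level label carries only the tumorsite binding and the
  # scores-level label only the sid binding
  src <- nrc_print(sp$flat_program)
  expect_match(src, 'mklabel\\("TGHybridScores_samples", tumorsite :=')
  expect_match(src, 'mklabel\\("TGHybridScores_samples_scores", sid :=')

  ds <- generate_dataset(gen_config(n_samples = 20, seed = 81))
  run <- eval_shredded(sp, ds$data)
  expect_false("Occurrences_candidates_consequences" %in%
                 run$access_log$TGHybridScores_samples_scores)

  # widening a label context beyond the computed binding set changes
  # nothing in the unshredded output
  widened <- sp
  wp <- widened$flat_program
  add_binding <- function(e) {
    if (!inherits(e, "nrc_expr")) return(e)
    if (e$kind == "newlabel" &&
        e$level == "TGHybridScores_samples_scores") {
      e$bindings$tumorsite <- nrc_project(nrc_var("s"), "tumorsite")
    }
    for (f in setdiff(names(e), c("kind", "uid"))) {
      if (inherits(e[[f]], "nrc_expr")) e[[f]] <- add_binding(e[[f]])
      else if (is.list(e[[f]])) e[[f]] <- lapply(e[[f]], add_binding)
    }
    e
  }
  # widen in both the component head and its dom so labels stay consistent
  for (i in seq_along(wp$assignments)) {
    nm <- wp$assignments[[i]]$name
    if (nm %in% c("TGHybridScores_samples",
                  "TGHybridScores_samples_scores_dom"))
      wp$assignments[[i]]$expr <- add_binding(wp$assignments[[i]]$expr)
  }
  widened$flat_program <- wp
  run_w <- eval_shredded(widened, ds$data)
  expect_true(bag_equal(unshred_value(run$values$TGHybridScores),
                        unshred_value(run_w$values$TGHybridScores)))
})

test_that("shredded results equal the reference on shipped and random programs", {
  sch <- omics_schemas()
  ds <- generate_dataset(gen_config(n_samples = 20, seed = 91))
  for (nm in c("TGHybridScores", "OccurGrouped", "BuildOccur")) {
    p <- program_suite(nm)[[1]]
    ref <- eval_reference(p, ds$data)[[nm]]
    shr <- run_shredded(p, sch, ds$data)$results[[nm]]
    expect_true(bag_equal(ref, shr), label = nm)
  }
  msch <- mini_schemas()
  for (seed in 1:10) {
    p <- random_program(seed)
    inp <- mini_inputs(seed + 300)
    expect_true(bag_equal(eval_reference(p, inp)$P,
                          run_shredded(p, msch, inp)$results$P),
                label = paste("program", seed))
  }
})

test_that("sharing keeps dictionary tuples at or below the flattened size", {
  sch <- omics_schemas()
  p <- program_suite("BuildOccur")$BuildOccur
  ds <- generate_dataset(gen_preset("sharing", seed = 13))
  sp <- shred_program(p, sch)
  sv <- eval_shredded(sp, ds$data)$values$BuildOccur
  flat <- eval_reference(p, ds$data)$BuildOccur
  flat_cands <- sum(vapply(flat, function(o) length(o$candidates),
                           integer(1)))
  dict_cands <- sum(vapply(sv$dicts$BuildOccur_candidates, length,
                           integer(1)))
  ann_cands <- sum(vapply(ds$data$Annotations, function(a)
    length(a$candidates), integer(1)))
  expect_lt(dict_cands, flat_cands)
  # the candidates dictionary coincides with the unique annotations input
  expect_equal(dict_cands, ann_cands)
})
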