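#' Synthetic multi-omics data generation
#'
#' Generates every input dataset the analysis programs consume, with
#' controllable statistical structure: nested mutation annotations with an
#' empty-candidates probability (the empty inner bags that defeat naive
#' flattening), Zipf-skewed tumor-site assignment (the grouping-key skew
#' that overloads partitions), annotation sharing across samples (the same
#' mutation observed in several samples reuses one annotation), and 0/1/2
#' genotype calls for the VCF-backed variants. All referential links are
#' valid by construction and checkable with [validate_dataset()]. The same
#' configuration and seed always produce identical data.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes in the gene map.
#' @param n_pathways number of gene-set pathways.
#' @param mutations_per_sample mean of the Poisson number of somatic
#'   mutations per sample.
#' @param candidates_range integer range (min, max) of the candidates-bag
#'   size for non-empty annotations.
#' @param p_empty_candidates probability that a mutation's candidates bag is
#'   empty.
#' @param tumorsite_zipf_exponent Zipf exponent of tumor-site assignment
#'   (0 = uniform; larger = one dominant site).
#' @param pathway_zipf_exponent Zipf exponent of pathway sizes (0 = equal
#'   sizes; larger = one dominant pathway).
#' @param annotation_sharing_rate probability that a new mutation event
#'   reuses an existing shared mutation (same mutationId and annotation)
#'   instead of creating a fresh one.
#' @param genes_per_sample number of genes with copy-number calls per
#'   sample.
#' @param n_variants number of VCF variant records.
#' @param seed RNG seed.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_samples = 50L, n_genes = 25L, n_pathways = 10L,
                       mutations_per_sample = 2, candidates_range = c(1L, 3L),
                       p_empty_candidates = 0.3,
                       tumorsite_zipf_exponent = 1.0,
                       pathway_zipf_exponent = 1.0,
                       annotation_sharing_rate = 0,
                       genes_per_sample = 10L, n_variants = 30L, seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1, p_empty_candidates >= 0,
            p_empty_candidates <= 1, annotation_sharing_rate >= 0,
            annotation_sharing_rate <= 1)
  if (annotation_sharing_rate > 0 && mutations_per_sample == 0)
    stop("annotation sharing requires mutations_per_sample > 0",
         call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 mutations_per_sample = mutations_per_sample,
                 candidates_range = as.integer(candidates_range),
                 p_empty_candidates = p_empty_candidates,
                 tumorsite_zipf_exponent = tumorsite_zipf_exponent,
                 pathway_zipf_exponent = pathway_zipf_exponent,
                 annotation_sharing_rate = annotation_sharing_rate,
                 genes_per_sample = as.integer(min(genes_per_sample,
                                                   n_genes)),
                 n_variants = as.integer(n_variants),
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' Preset generator configurations
#'
#' `tiny` is the equivalence-suite fixture: 50 samples, 30% empty candidate
#' bags, mild skew, no sharing. `skewed` raises the tumor-site Zipf
#' exponent to 1.5 over 200 samples, so the dominant site exceeds the 2.5%
#' heavy-key threshold by a wide margin. `sharing` sets the annotation
#' sharing rate to 0.5 over 60 samples, for the shared-annotation
#' dictionary experiment.
#'
#' @param preset one of `"tiny"`, `"skewed"`, `"sharing"`.
#' @param seed RNG seed.
#' @export
gen_preset <- function(preset = c("tiny", "skewed", "sharing"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = gen_config(seed = seed),
    skewed = gen_config(n_samples = 200L, tumorsite_zipf_exponent = 1.5,
                        seed = seed),
    sharing = gen_config(n_samples = 60L, annotation_sharing_rate = 0.5,
                         p_empty_candidates = 0.2, seed = seed))
}

TUMOR_SITES <- c("breast", "cns", "colon", "endometrial", "headneck",
                 "kidney", "lung", "ovary", "stomach")

SO_TERMS <- c(missense_variant = 0.7, stop_gained = 0.9,
              frameshift_variant = 0.9, synonymous_variant = 0.1,
              splice_region_variant = 0.6, intron_variant = 0.2,
              upstream_gene_variant = 0.3, inframe_deletion = 0.5)

rzipf <- function(n, k, a) {
  if (a <= 0) return(sample.int(k, n, replace = TRUE))
  sample.int(k, n, replace = TRUE, prob = (seq_len(k))^(-a))
}

#' Generate a synthetic multi-omics dataset
#'
#' @param config a [gen_config()] or [gen_preset()].
#' @return list with `data` (named list of bag values: Samples, CopyNumber,
#'   Occurrences, Variants, GeneMap, Network, GeneExpression, Pathways,
#'   SOImpact, Mutations, Annotations), `schemas` ([omics_schemas()]) and
#'   `config`.
#' @export
generate_dataset <- function(config = gen_config()) {
  cf <- config
  with_seed(cf$seed, {
    params <- score_params()
    sids <- sprintf("s%04d", seq_len(cf$n_samples))
    sites <- TUMOR_SITES[pmin(length(TUMOR_SITES),
                              rzipf(cf$n_samples, length(TUMOR_SITES),
                                    cf$tumorsite_zipf_exponent))]
    samples <- lapply(seq_len(cf$n_samples), function(i)
      list(sid = sids[i], tumorsite = sites[i],
           aliquot = paste0(sids[i], "-aq1")))

    genes <- sprintf("g%04d", seq_len(cf$n_genes))
    contigs <- paste0("chr", 1:5)
    gene_contig <- sample(contigs, cf$n_genes, replace = TRUE)
    gene_start <- sample.int(900000L, cf$n_genes)
    gene_end <- gene_start + sample(500:5000, cf$n_genes, replace = TRUE)
    proteins <- sprintf("p%04d", seq_len(cf$n_genes))
    genemap <- lapply(seq_len(cf$n_genes), function(i)
      list(gene = genes[i], contig = gene_contig[i],
           start = gene_start[i], end = gene_end[i],
           protein = proteins[i]))

    soimpact <- lapply(names(SO_TERMS), function(tm)
      list(conseq = tm, score = unname(SO_TERMS[[tm]])))

    # shared mutation pool: new events either mint a mutation+annotation or
    # reuse one already observed in another sample
    pool <- list()
    new_annotation <- function() {
      n_c <- if (stats::runif(1) < cf$p_empty_candidates) 0L else
        sample(seq(cf$candidates_range[1], cf$candidates_range[2]), 1)
      cands <- lapply(seq_len(n_c), function(j) {
        lvl <- sample(names(params$impact_level_scores), 1,
                      prob = c(0.15, 0.3, 0.3, 0.25))
        n_q <- sample(1:2, 1)
        list(gene = genes[sample.int(cf$n_genes, 1)],
             impact = unname(params$impact_level_scores[[lvl]]),
             sift = round(stats::runif(1), 2),
             poly = round(stats::runif(1), 2),
             consequences = lapply(
               sample(names(SO_TERMS), n_q),
               function(tm) list(conseq = tm)))
      })
      cands
    }
    mutations <- list(); annotations <- list(); occurrences <- list()
    mut_n <- 0L
    for (i in seq_len(cf$n_samples)) {
      m <- stats::rpois(1, cf$mutations_per_sample)
      for (j in seq_len(m)) {
        reuse <- length(pool) > 0 &&
          stats::runif(1) < cf$annotation_sharing_rate
        if (reuse) {
          entry <- pool[[sample.int(length(pool), 1)]]
        } else {
          mut_n <- mut_n + 1L
          mid <- sprintf("m%05d", mut_n)
          ct <- sample(contigs, 1)
          pos <- sample.int(1000000L, 1)
          ref <- sample(c("A", "C", "G", "T"), 1)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
          entry <- list(mutationId = mid, contig = ct, start = pos,
                        end = pos, reference = ref, alternate = alt,
                        candidates = new_annotation())
          pool[[length(pool) + 1L]] <- entry
          annotations[[length(annotations) + 1L]] <-
            list(mutationId = mid, candidates = entry$candidates)
        }
        mutations[[length(mutations) + 1L]] <-
          list(sid = sids[i], contig = entry$contig, start = entry$start,
               end = entry$end, reference = entry$reference,
               alternate = entry$alternate, mutationId = entry$mutationId)
        occurrences[[length(occurrences) + 1L]] <-
          list(sid = sids[i], contig = entry$contig, start = entry$start,
               end = entry$end, reference = entry$reference,
               alternate = entry$alternate, mutationId = entry$mutationId,
               candidates = entry$candidates)
      }
    }

    copynumber <- list()
    for (i in seq_len(cf$n_samples)) {
      gs <- sample.int(cf$n_genes, cf$genes_per_sample)
      for (g in gs)
        copynumber[[length(copynumber) + 1L]] <-
          list(sid = sids[i], gene = genes[g],
               cnum = sample(0:4, 1, prob = c(0.1, 0.2, 0.4, 0.2, 0.1)))
    }

    expression <- list()
    for (i in seq_len(cf$n_samples)) {
      gs <- sample.int(cf$n_genes, cf$genes_per_sample)
      for (g in gs)
        expression[[length(expression) + 1L]] <-
          list(aliquot = paste0(sids[i], "-aq1"), gene = genes[g],
               fpkm = round(stats::rlnorm(1, meanlog = 1, sdlog = 0.6), 2))
    }

    n_edges <- 2L * cf$n_genes
    network <- lapply(seq_len(n_edges), function(i)
      list(nodeProtein = proteins[sample.int(cf$n_genes, 1)],
           edgeProtein = proteins[sample.int(cf$n_genes, 1)],
           distance = round(stats::runif(1, 0.1, 1), 2)))

    wt <- (seq_len(cf$n_pathways))^(-cf$pathway_zipf_exponent)
    sizes <- pmax(2L, round(2 + 8 * wt / wt[1]))
    pathways <- lapply(seq_len(cf$n_pathways), function(i) {
      gs <- sample.int(cf$n_genes, min(sizes[i], cf$n_genes))
      list(pathway = sprintf("P%03d", i),
           genes = lapply(gs, function(g) list(gene = genes[g])))
    })

    variants <- lapply(seq_len(cf$n_variants), function(i) {
      on_gene <- stats::runif(1) < 0.7
      if (on_gene) {
        g <- sample.int(cf$n_genes, 1)
        ct <- gene_contig[g]
        pos <- sample(gene_start[g]:gene_end[g], 1)
      } else {
        ct <- sample(contigs, 1)
        pos <- sample.int(1000000L, 1)
      }
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      list(contig = ct, start = pos, reference = ref, alternate = alt,
           genotypes = lapply(sids, function(sid)
             list(sid = sid,
                  call = sample(0:2, 1, prob = c(0.6, 0.3, 0.1)))))
    })

    list(data = list(Samples = samples, CopyNumber = copynumber,
                     Occurrences = occurrences, Variants = variants,
                     GeneMap = genemap, Network = network,
                     GeneExpression = expression, Pathways = pathways,
                     SOImpact = soimpact, Mutations = mutations,
                     Annotations = annotations),
         schemas = omics_schemas(), config = cf)
  })
}

#' Plant a dominant driver-gene signal
#'
#' Modifies a generated dataset so one gene carries a jointly extreme
#' signal: every sample gains one occurrence with a HIGH-impact,
#' top-consequence candidate for the gene, the gene's copy number is set to
#' the maximum in every sample, its expression to a large FPKM in every
#' aliquot, and its protein receives a strong self-edge. Under the driver
#' pipeline this gene should rank first in connectivity.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param gene the gene to plant (must exist in the gene map).
#' @return the modified dataset.
#' @export
plant_driver_signal <- function(ds, gene = "g0001") {
  data <- ds$data
  gm <- NULL
  for (g in data$GeneMap) if (g$gene == gene) gm <- g
  if (is.null(gm)) stop("gene not in GeneMap: ", gene, call. = FALSE)
  top_conseq <- names(SO_TERMS)[which.max(SO_TERMS)]
  n0 <- length(data$Occurrences)
  for (i in seq_along(data$Samples)) {
    s <- data$Samples[[i]]
    data$Occurrences[[n0 + i]] <- list(
      sid = s$sid, contig = gm$contig, start = gm$start, end = gm$start,
      reference = "A", alternate = "T",
      mutationId = sprintf("mP%04d", i),
      candidates = list(list(gene = gene, impact = 0.8, sift = 0.99,
                             poly = 0.99,
                             consequences = list(
                               list(conseq = top_conseq)))))
  }
  data$CopyNumber <- Filter(function(x) x$gene != gene, data$CopyNumber)
  data$GeneExpression <- Filter(function(x) x$gene != gene,
                                data$GeneExpression)
  nc <- length(data$CopyNumber); ne <- length(data$GeneExpression)
  for (i in seq_along(data$Samples)) {
    s <- data$Samples[[i]]
    data$CopyNumber[[nc + i]] <- list(sid = s$sid, gene = gene, cnum = 6L)
    data$GeneExpression[[ne + i]] <- list(aliquot = s$aliquot, gene = gene,
                                          fpkm = 60)
  }
  data$Network[[length(data$Network) + 1L]] <-
    list(nodeProtein = gm$protein, edgeProtein = gm$protein, distance = 1)
  ds$data <- data
  ds
}

#' Validate referential integrity of a dataset
#'
#' Checks every cross-dataset link: occurrence/copy-number/expression
#' samples exist, candidate and pathway genes are in the gene map,
#' consequence terms are scored, network proteins are mapped, genotype
#' calls cover exactly the sample set, and every mutation's annotation
#' exists.
#'
#' @param ds a dataset from [generate_dataset()].
#' @return invisibly `TRUE`; problems raise an error.
#' @export
validate_dataset <- function(ds) {
  d <- ds$data
  sids <- vapply(d$Samples, function(x) x$sid, character(1))
  aliquots <- vapply(d$Samples, function(x) x$aliquot, character(1))
  genes <- vapply(d$GeneMap, function(x) x$gene, character(1))
  prots <- vapply(d$GeneMap, function(x) x$protein, character(1))
  terms <- vapply(d$SOImpact, function(x) x$conseq, character(1))
  mids <- vapply(d$Annotations, function(x) x$mutationId, character(1))
  fail <- function(...) stop("referential integrity: ", ..., call. = FALSE)
  for (o in d$Occurrences) {
    if (!o$sid %in% sids) fail("occurrence sid ", o$sid)
    for (c_ in o$candidates) {
      if (!c_$gene %in% genes) fail("candidate gene ", c_$gene)
      for (q in c_$consequences)
        if (!q$conseq %in% terms) fail("conseq ", q$conseq)
    }
  }
  for (x in d$CopyNumber) {
    if (!x$sid %in% sids) fail("copy-number sid ", x$sid)
    if (!x$gene %in% genes) fail("copy-number gene ", x$gene)
  }
  for (x in d$GeneExpression) {
    if (!x$aliquot %in% aliquots) fail("expression aliquot ", x$aliquot)
    if (!x$gene %in% genes) fail("expression gene ", x$gene)
    if (x$fpkm < 0) fail("negative fpkm")
  }
  for (x in d$Network) {
    if (!x$nodeProtein %in% prots || !x$edgeProtein %in% prots)
      fail("network protein")
    if (x$distance < 0) fail("negative network distance")
  }
  for (p in d$Pathways)
    for (g in p$genes)
      if (!g$gene %in% genes) fail("pathway gene ", g$gene)
  for (g in d$GeneMap)
    if (g$start > g$end) fail("gene interval start > end")
  for (v in d$Variants) {
    vs <- vapply(v$genotypes, function(x) x$sid, character(1))
    if (!setequal(vs, sids)) fail("variant genotype sample set")
    for (gt in v$genotypes)
      if (!gt$call %in% 0:2) fail("genotype call outside 0/1/2")
  }
  for (m in d$Mutations)
    if (!m$mutationId %in% mids) fail("mutation without annotation: ",
                                      m$mutationId)
  invisible(TRUE)
}
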