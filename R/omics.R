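#' Multi-omics input schemas
#'
#' The standard input types of the shipped analysis programs. `Samples` maps
#' sample ids to tumor site and sequencing aliquot; `CopyNumber` carries
#' per-sample gene copy numbers; `Occurrences` holds annotated somatic
#' mutations with a nested `candidates` collection (candidate gene, numeric
#' impact score, SIFT and PolyPhen scores) and a further-nested
#' `consequences` collection of sequence-ontology terms; `Variants` mirrors
#' one VCF record per tuple with per-sample genotype calls (0 homozygous
#' reference, 1 heterozygous, 2 homozygous alternate); `GeneMap` maps genes
#' to genomic intervals and proteins; `Network` is a protein-protein edge
#' list with distances; `GeneExpression` carries FPKM values per aliquot;
#' `Pathways` holds gene sets; `SOImpact` scores consequence terms;
#' `Mutations`/`Annotations` split Occurrences into somatic mutations and
#' shared VEP annotations keyed by mutationId. Qualitative VEP impact levels
#' (HIGH/MODERATE/LOW/MODIFIER) are encoded as numeric scores at ingest (see
#' [score_params()]).
#'
#' Also includes the materialized stage outputs of the driver-gene pipeline
#' (`HybridScores`, `HybridNetworks`, `EffectScores`, `ConnectScores`) and
#' `PathwayBurden`, so downstream programs can be typechecked and run
#' standalone against materialized inputs.
#'
#' @return named list of bag types.
#' @export
omics_schemas <- function() {
  s <- nt_scalar
  candidates_t <- nt_bag(nt_tuple(list(
    gene = s("string"), impact = s("real"), sift = s("real"),
    poly = s("real"),
    consequences = nt_bag(nt_tuple(list(conseq = s("string")))))))
  scores_t <- nt_bag(nt_tuple(list(gene = s("string"), score = s("real"))))
  list(
    Samples = nt_bag(nt_tuple(list(sid = s("string"),
                                   tumorsite = s("string"),
                                   aliquot = s("string")))),
    CopyNumber = nt_bag(nt_tuple(list(sid = s("string"), gene = s("string"),
                                      cnum = s("int")))),
    Occurrences = nt_bag(nt_tuple(list(
      sid = s("string"), contig = s("string"), start = s("int"),
      end = s("int"), reference = s("string"), alternate = s("string"),
      mutationId = s("string"), candidates = candidates_t))),
    Variants = nt_bag(nt_tuple(list(
      contig = s("string"), start = s("int"), reference = s("string"),
      alternate = s("string"),
      genotypes = nt_bag(nt_tuple(list(sid = s("string"),
                                       call = s("int"))))))),
    GeneMap = nt_bag(nt_tuple(list(gene = s("string"), contig = s("string"),
                                   start = s("int"), end = s("int"),
                                   protein = s("string")))),
    Network = nt_bag(nt_tuple(list(nodeProtein = s("string"),
                                   edgeProtein = s("string"),
                                   distance = s("real")))),
    GeneExpression = nt_bag(nt_tuple(list(aliquot = s("string"),
                                          gene = s("string"),
                                          fpkm = s("real")))),
    Pathways = nt_bag(nt_tuple(list(
      pathway = s("string"),
      genes = nt_bag(nt_tuple(list(gene = s("string"))))))),
    SOImpact = nt_bag(nt_tuple(list(conseq = s("string"),
                                    score = s("real")))),
    Mutations = nt_bag(nt_tuple(list(
      sid = s("string"), contig = s("string"), start = s("int"),
      end = s("int"), reference = s("string"), alternate = s("string"),
      mutationId = s("string")))),
    Annotations = nt_bag(nt_tuple(list(mutationId = s("string"),
                                       candidates = candidates_t))),
    # materialized pipeline stages
    HybridScores = nt_bag(nt_tuple(list(sid = s("string"),
                                        aliquot = s("string"),
                                        scores = scores_t))),
    HybridNetworks = nt_bag(nt_tuple(list(
      sid = s("string"), aliquot = s("string"),
      nodes = nt_bag(nt_tuple(list(nodeProtein = s("string"),
                                   score = s("real"))))))),
    EffectScores = nt_bag(nt_tuple(list(sid = s("string"),
                                        aliquot = s("string"),
                                        scores = scores_t))),
    ConnectScores = nt_bag(nt_tuple(list(sid = s("string"),
                                         aliquot = s("string"),
                                         scores = scores_t))),
    PathwayBurden = nt_bag(nt_tuple(list(
      pathway = s("string"),
      burdens = nt_bag(nt_tuple(list(sid = s("string"),
                                     burden = s("real")))))))
  )
}

#' Scoring parameters
#'
#' Numeric encodings used by the analysis programs. `impact_level_scores`
#' maps the qualitative VEP impact levels to the numeric scores the
#' generator emits into `Occurrences.candidates.impact` (package defaults,
#' configurable, in `[0, 1]`). `flanking_bp` widens the gene interval used
#' to associate variants to genes, symmetrically on both sides (0 means a
#' variant must lie on the gene).
#'
#' @param impact_level_scores named numeric vector over
#'   HIGH/MODERATE/LOW/MODIFIER, each in `[0, 1]`.
#' @param flanking_bp nonnegative flanking region in base pairs.
#' @export
score_params <- function(impact_level_scores = c(HIGH = 0.8, MODERATE = 0.5,
                                                 LOW = 0.3, MODIFIER = 0.15),
                         flanking_bp = 0L) {
  stopifnot(all(impact_level_scores >= 0), all(impact_level_scores <= 1),
            flanking_bp >= 0)
  list(impact_level_scores = impact_level_scores,
       flanking_bp = as.integer(flanking_bp))
}

#' The shipped analysis programs
#'
#' Parses and returns the analysis programs shipped with the package, as
#' ASTs: the running-example family (OccurrProj, OccurCNV, OccurAgg,
#' SGHybridScores, TGHybridScores), the mutational-burden programs
#' (GeneBurden, PathwayBurden, BurdenFeatures), the five driver-gene
#' pipeline stages (HybridScores, HybridNetworks, EffectScores,
#' ConnectScores, Connectivity), the clinical exploration programs
#' (OccurGrouped, OccurCNVJoin, OccurCNVAgg) and the annotation-sharing
#' construction BuildOccur. Every program typechecks against
#' [omics_schemas()].
#'
#' @param names optional subset of program names.
#' @return named list of [nrc_program()]s; a program's last assignment
#'   carries its name (TGHybridScores also contains its TumorSites
#'   assignment).
#' @export
program_suite <- function(names = NULL) {
  dir <- system.file("nrc", package = "nrcshred")
  files <- list.files(dir, pattern = "\\.nrc$", full.names = TRUE)
  progs <- list()
  for (f in files) {
    nm <- sub("\\.nrc$", "", basename(f))
    progs[[nm]] <- nrc_parse(paste(readLines(f), collapse = "\n"))
  }
  ord <- c("OccurrProj", "OccurCNV", "OccurAgg", "SGHybridScores",
           "TGHybridScores", "GeneBurden", "PathwayBurden",
           "BurdenFeatures", "HybridScores", "HybridNetworks",
           "EffectScores", "ConnectScores", "Connectivity", "OccurGrouped",
           "OccurCNVJoin", "OccurCNVAgg", "BuildOccur")
  progs <- progs[intersect(ord, names(progs))]
  if (!is.null(names)) progs <- progs[names]
  progs
}

#' Program source text
#'
#' @param name a program name from [program_suite()].
#' @return the program's surface-syntax source as a single string.
#' @export
program_source <- function(name) {
  f <- system.file("nrc", paste0(name, ".nrc"), package = "nrcshred")
  if (f == "") stop("no such shipped program: ", name, call. = FALSE)
  paste(readLines(f), collapse = "\n")
}

# run one shipped program (with its upstream assignments inlined by the
# caller via `inputs`) through the requested route
run_program <- function(program, inputs,
                        route = c("reference", "standard", "shredded"),
                        config = cluster_config(),
                        schemas = omics_schemas()) {
  route <- match.arg(route)
  switch(route,
    reference = eval_reference(program, inputs),
    standard = run_standard(program, schemas, inputs, config)$results,
    shredded = run_shredded(program, schemas, inputs)$results)
}
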