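#' Gene mutational burden
#'
#' Per gene, the sum of genotype calls (allele dosage) of every sample over
#' the variants associated with the gene. A variant is associated when it
#' lies within the gene's mapped interval, optionally widened by a symmetric
#' flanking region; coordinates are 1-based and inclusive on both ends. A
#' gene with no associated variants has an empty burdens bag.
#'
#' @param variants Variants bag value (see [omics_schemas()]).
#' @param genes GeneMap bag value.
#' @param params a [score_params()]; `flanking_bp` widens the association
#'   interval.
#' @param route execution route (reference interpreter, standard compiled
#'   plan, or shredded).
#' @return bag value of `{gene, burdens: [{sid, burden}]}`.
#' @export
gene_burden <- function(variants, genes, params = score_params(),
                        route = "reference") {
  program <- gene_burden_program(params$flanking_bp)
  run_program(program, list(Variants = variants, GeneMap = genes),
              route = route)$GeneBurden
}

gene_burden_program <- function(flanking_bp = 0L) {
  if (flanking_bp == 0L)
    return(program_suite("GeneBurden")$GeneBurden)
  src <- program_source("GeneBurden")
  src <- sub("g.start <= v.start && v.start <= g.end",
             sprintf("(g.start - %d) <= v.start && v.start <= (g.end + %d)",
                     flanking_bp, flanking_bp),
             src, fixed = TRUE)
  nrc_parse(src)
}

#' Pathway mutational burden
#'
#' Per pathway, the per-sample sum of candidate impact scores over the
#' member genes of the pathway (impact is used rather than allele counts,
#' since wide candidate assignment would overestimate count-based burden).
#' `mode = "count"` switches to raw counts — each candidate contributes 1 —
#' the variant used to build classification features. Candidate genes
#' absent from every pathway simply contribute nothing.
#'
#' @param occurrences Occurrences bag value.
#' @param pathways Pathways bag value.
#' @param mode `"impact"` (sum impact scores) or `"count"` (raw counts).
#' @inheritParams gene_burden
#' @return bag value of `{pathway, burdens: [{sid, burden}]}`.
#' @export
pathway_burden <- function(occurrences, pathways,
                           mode = c("impact", "count"),
                           route = "reference") {
  mode <- match.arg(mode)
  src <- program_source("PathwayBurden")
  if (mode == "count")
    src <- sub("burden := c.impact", "burden := 1", src, fixed = TRUE)
  program <- nrc_parse(src)
  run_program(program, list(Occurrences = occurrences,
                            Pathways = pathways),
              route = route)$PathwayBurden
}

#' Labeled burden feature matrix
#'
#' Turns pathway-burden output into a feature matrix for tumor-of-origin
#' classification: one row per sample, one numeric column per pathway
#' (missing burdens filled with 0), plus the sample's tumor-site label. Row
#' and column order are deterministic (sample id, pathway name). Samples
#' absent from `samples` are dropped with a warning.
#'
#' @param pmb_output PathwayBurden bag value.
#' @param samples Samples bag value.
#' @return a tibble: `sid`, `tumorsite`, then one column per pathway.
#' @export
burden_features <- function(pmb_output, samples) {
  long <- list()
  for (p in pmb_output) {
    for (b in p$burdens) {
      long[[length(long) + 1L]] <- list(pathway = p$pathway, sid = b$sid,
                                        burden = as.numeric(b$burden))
    }
  }
  smap <- stats::setNames(
    vapply(samples, function(s) s$tumorsite, character(1)),
    vapply(samples, function(s) s$sid, character(1)))
  pathways <- sort(unique(vapply(pmb_output, function(p) p$pathway,
                                 character(1))))
  sids <- sort(names(smap))
  mat <- matrix(0, nrow = length(sids), ncol = length(pathways),
                dimnames = list(sids, pathways))
  dropped <- character(0)
  for (e in long) {
    if (!e$sid %in% names(smap) || is.na(smap[[e$sid]])) {
      dropped <- c(dropped, e$sid)
      next
    }
    mat[e$sid, e$pathway] <- mat[e$sid, e$pathway] + e$burden
  }
  if (length(dropped))
    warning("dropped burdens for sample(s) missing from Samples: ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  out <- tibble::tibble(sid = sids, tumorsite = unname(smap[sids]))
  for (p in pathways) out[[p]] <- unname(mat[, p])
  out
}

#' Cancer driver-gene pipeline
#'
#' Runs the five-stage driver-gene analysis as a pipeline of materialized
#' programs: HybridScores (mutation impact x consequence score x copy
#' number per gene and sample), HybridNetworks (edge-weighted propagation
#' to protein nodes), EffectScores (node score plus own hybrid score),
#' ConnectScores (times expression FPKM), and Connectivity (summed across
#' samples). The genes with the highest connectivity are candidate drivers.
#'
#' @param data named list with Occurrences, CopyNumber, Samples, Network,
#'   GeneMap, GeneExpression and SOImpact bag values.
#' @param route execution route; the default runs the compiled standard
#'   plans on the partitioned runtime.
#' @param config a [cluster_config()] (standard route only).
#' @return list with all five stage outputs (`HybridScores`,
#'   `HybridNetworks`, `EffectScores`, `ConnectScores`, `Connectivity` as
#'   bag values), and `connectivity`: a tibble of genes sorted by
#'   descending connectivity score. Samples lacking an aliquot mapping are
#'   excluded with a warning.
#' @export
driver_pipeline <- function(data, route = "standard",
                            config = cluster_config()) {
  missing_aliquot <- vapply(data$Samples, function(s)
    is.null(s$aliquot) || is.na(s$aliquot), logical(1))
  if (any(missing_aliquot)) {
    warning("excluding ", sum(missing_aliquot),
            " sample(s) without an aliquot mapping", call. = FALSE)
    data$Samples <- data$Samples[!missing_aliquot]
  }
  stages <- c("HybridScores", "HybridNetworks", "EffectScores",
              "ConnectScores", "Connectivity")
  progs <- program_suite(stages)
  combined <- nrc_program(do.call(c, lapply(progs, function(p)
    p$assignments)))
  res <- run_program(combined, data, route = route, config = config)
  conn <- res$Connectivity
  tbl <- tibble::tibble(
    gene = vapply(conn, function(x) x$gene, character(1)),
    score = vapply(conn, function(x) as.numeric(x$score), numeric(1)))
  tbl <- tbl[order(-tbl$score, tbl$gene), ]
  c(res[stages], list(connectivity = tbl))
}

#' Accuracy from confusion counts
#'
#' Overall classification accuracy as a percentage, from the number of
#' correctly predicted labels and the number of evaluated samples, reported
#' to two decimals (truncated, the convention used when accuracy
#' percentages are quoted from a confusion matrix).
#'
#' @param correct number of correct predictions (`0 <= correct <= total`).
#' @param total number of evaluated samples (`> 0`).
#' @return percentage in `[0, 100]`, rounded to 2 decimals.
#' @export
accuracy_from_counts <- function(correct, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (correct < 0 || correct > total)
    stop("correct must lie in [0, total]", call. = FALSE)
  trunc(100 * correct / total * 100) / 100
}
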