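#' Reading and writing the standard formats
#'
#' Flat relations are exchanged as TSV; nested collections as JSON lines
#' (one top-level object per line); variants as minimal VCF v4.2 (CHROM POS
#' ID REF ALT QUAL FILTER INFO FORMAT plus one genotype column per sample,
#' GT field only); pathways as GMT. Genotypes map 0/0 to call 0, 0/1 or 1/0
#' to 1 and 1/1 to 2; phased separators (`|`) are treated as unphased;
#' multi-allelic records are split into one record per alternate allele; a
#' missing GT is read as call 0 with a warning. Writing then reading any of
#' these is the identity on the supported fields.
#'
#' @name omics-io
NULL

coerce_scalar <- function(v, t) {
  switch(t$kind, string = as.character(v), int = as.integer(v),
         real = as.numeric(v), bool = as.logical(v))
}

coerce_tuple <- function(tup, elem_type) {
  out <- list()
  for (f in names(elem_type$fields)) {
    ft <- elem_type$fields[[f]]
    v <- tup[[f]]
    if (is.null(v)) stop("missing field in record: ", f, call. = FALSE)
    out[[f]] <- if (is_bag_type(ft))
      lapply(v, coerce_tuple, elem_type = ft$elem)
    else coerce_scalar(v, ft)
  }
  out
}

#' @rdname omics-io
#' @param bag flat bag value.
#' @param path file path.
#' @export
write_tsv_bag <- function(bag, path) {
  df <- as.data.frame(lapply(stats::setNames(nm = names(bag[[1]])),
                             function(f) vapply(bag, function(tup)
                               as.character(tup[[f]]), character(1))),
                      stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname omics-io
#' @param type bag type of the relation.
#' @export
read_tsv_bag <- function(path, type) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i)
    coerce_tuple(as.list(df[i, , drop = FALSE]), type$elem))
}

#' @rdname omics-io
#' @export
write_jsonl <- function(bag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tup in bag)
    writeLines(jsonlite::toJSON(tup, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname omics-io
#' @export
read_jsonl <- function(path, type) {
  lines <- readLines(path)
  lapply(seq_along(lines), function(i) {
    tup <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop("malformed JSONL record at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    coerce_tuple(tup, type$elem)
  })
}

#' @rdname omics-io
#' @param variants Variants bag value.
#' @export
write_variants_vcf <- function(variants, path) {
  sids <- if (length(variants))
    vapply(variants[[1]]$genotypes, function(g) g$sid, character(1))
  else character(0)
  gt_of <- function(call) switch(as.character(call),
                                 "0" = "0/0", "1" = "0/1", "2" = "1/1")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sids),
                     collapse = "\t")), con)
  for (v in variants) {
    calls <- vapply(v$genotypes, function(g) gt_of(g$call), character(1))
    writeLines(paste(c(v$contig, v$start, ".", v$reference, v$alternate,
                       ".", "PASS", ".", "GT", calls), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname omics-io
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM"))
    stop("malformed VCF: missing #CHROM header line", call. = FALSE)
  header <- strsplit(sub("^#", "", body[1]), "\t", fixed = TRUE)[[1]]
  sids <- header[-(1:9)]
  out <- list()
  warned <- FALSE
  for (ln in seq_along(body)[-1]) {
    f <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 + length(sids))
      stop("malformed VCF record at line ", ln, call. = FALSE)
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    gts <- vapply(f[-(1:9)], function(cell) {
      if (is.na(gt_idx)) return(NA_character_)
      strsplit(cell, ":", fixed = TRUE)[[1]][gt_idx]
    }, character(1), USE.NAMES = FALSE)
    # one record per alternate allele; call counts that allele's copies
    for (ai in seq_along(alts)) {
      genotypes <- lapply(seq_along(sids), function(si) {
        gt <- gts[si]
        call <- if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
          if (!warned) {
            warning("missing GT treated as call 0 (first at line ", ln,
                    ")", call. = FALSE)
            warned <<- TRUE
          }
          0L
        } else {
          alleles <- strsplit(gt, "[/|]")[[1]]
          sum(alleles == as.character(ai))
        }
        list(sid = sids[si], call = as.integer(call))
      })
      out[[length(out) + 1L]] <- list(contig = f[1],
                                      start = as.integer(f[2]),
                                      reference = f[4], alternate = alts[ai],
                                      genotypes = genotypes)
    }
  }
  out
}

#' @rdname omics-io
#' @param pathways Pathways bag value.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$pathway, "synthetic gene set",
            vapply(p$genes, function(g) g$gene, character(1))),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname omics-io
#' @export
read_gmt <- function(path) {
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    stats::setNames(lapply(lines, function(f) f[-(1:2)]),
                    vapply(lines, `[[`, character(1), 1))
  }
  lapply(names(sets), function(nm)
    list(pathway = nm,
         genes = lapply(unname(sets[[nm]]), function(g) list(gene = g))))
}

#' Write / read a complete dataset directory
#'
#' Materializes a generated dataset in its native formats — flat tables as
#' TSV, Occurrences and Annotations as JSONL, Variants as VCF, Pathways as
#' GMT — alongside a JSON manifest recording the files and the generator
#' configuration. [read_dataset()] restores the dataset from the manifest.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param dir target directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- ds$data
  files <- list(
    Samples = "samples.tsv", CopyNumber = "copynumber.tsv",
    GeneMap = "genemap.tsv", Network = "network.tsv",
    GeneExpression = "expression.tsv", SOImpact = "soimpact.tsv",
    Mutations = "mutations.tsv", Occurrences = "occurrences.jsonl",
    Annotations = "annotations.jsonl", Variants = "variants.vcf",
    Pathways = "pathways.gmt")
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    switch(files[[nm]] |> tools::file_ext(),
      tsv = write_tsv_bag(d[[nm]], path),
      jsonl = write_jsonl(d[[nm]], path),
      vcf = write_variants_vcf(d[[nm]], path),
      gmt = write_gmt(d[[nm]], path))
  }
  manifest <- list(files = files, config = unclass(ds$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  schemas <- omics_schemas()
  data <- list()
  for (nm in names(manifest$files)) {
    path <- file.path(dir, manifest$files[[nm]])
    data[[nm]] <- switch(tools::file_ext(path),
      tsv = read_tsv_bag(path, schemas[[nm]]),
      jsonl = read_jsonl(path, schemas[[nm]]),
      vcf = read_variants_vcf(path),
      gmt = read_gmt(path))
  }
  cfg <- manifest$config
  list(data = data, schemas = schemas,
       config = do.call(gen_config, cfg[setdiff(names(cfg), character(0))]))
}
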