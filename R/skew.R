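#' Skew-resilient processing
#'
#' Key-based shuffles send all tuples with the same key to one partition, so
#' a dominant key (a tumor site with far more samples than the rest, a
#' pathway containing most mutated genes) overloads a single partition.
#' "Heavy keys" are keys whose tuples make up at least a configured fraction
#' of the data; they are detected by one of four strategies and then handled
#' by a broadcast-based execution that leaves their tuples in place.
#'
#' * `full` — exact frequencies over all values in all partitions;
#' * `partial` — a key is heavy if it reaches the threshold locally within
#'   any partition (local denominators, no global pass);
#' * `sample` — frequencies from a seeded random subsample (default 10%) of
#'   each partition;
#' * `slice` — frequencies from the first `slice_size` (default 1,000)
#'   tuples of each partition.
#'
#' All methods categorize a key as heavy when its share of the inspected
#' tuples is at least `heavy_threshold` (default 2.5%); every other key is
#' light. Shares are tuple-count fractions, and a key exactly at the
#' threshold counts as heavy.
#'
#' @name skew
NULL

#' Skew-handling configuration
#'
#' @param method one of `"none"`, `"full"`, `"partial"`, `"sample"`,
#'   `"slice"`.
#' @param heavy_threshold fraction of total tuples at or above which a key is
#'   heavy (default 0.025).
#' @param sample_fraction per-partition sampling fraction for the `sample`
#'   method (default 0.10).
#' @param slice_size number of leading tuples inspected per partition by the
#'   `slice` method (default 1000).
#' @param rng_seed seed for the `sample` method's subsampling.
#' @export
skew_config <- function(method = c("none", "full", "partial", "sample",
                                   "slice"),
                        heavy_threshold = 0.025, sample_fraction = 0.10,
                        slice_size = 1000L, rng_seed = 1L) {
  method <- match.arg(method)
  stopifnot(heavy_threshold > 0, heavy_threshold <= 1,
            sample_fraction > 0, sample_fraction <= 1, slice_size >= 1)
  structure(list(method = method, heavy_threshold = heavy_threshold,
                 sample_fraction = sample_fraction,
                 slice_size = as.integer(slice_size),
                 rng_seed = as.integer(rng_seed)),
            class = "nrc_skew_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Detect heavy keys
#'
#' @param pbag a [partitioned_bag()].
#' @param key_attrs character vector of key attributes.
#' @param cfg a [skew_config()]; `method = "none"` yields an empty report.
#' @return a heavy-key report: the method, a tibble of inspected keys with
#'   estimated frequency fractions and a heavy flag, and the number of tuples
#'   inspected. Keys not reported heavy are light (the two classes partition
#'   the key space).
#' @export
detect_heavy_keys <- function(pbag, key_attrs, cfg = skew_config("full")) {
  keyed <- lapply(pbag$partitions, function(df) {
    if (!nrow(df)) character(0) else row_key_strings(df, key_attrs)
  })
  total_keys <- unlist(keyed)
  report <- function(tab, inspected, denom = "global") {
    if (!length(tab)) {
      return(structure(list(method = cfg$method,
                            keys = tibble::tibble(key = character(0),
                                                  estimated_fraction = numeric(0),
                                                  heavy = logical(0)),
                            heavy_keys = character(0),
                            tuples_inspected = inspected),
                       class = "nrc_heavy_report"))
    }
    keys <- tibble::tibble(key = names(tab),
                           estimated_fraction = as.numeric(tab),
                           heavy = as.numeric(tab) >= cfg$heavy_threshold)
    structure(list(method = cfg$method, keys = keys,
                   heavy_keys = keys$key[keys$heavy],
                   tuples_inspected = inspected),
              class = "nrc_heavy_report")
  }
  if (cfg$method %in% c("none") || !length(total_keys))
    return(report(numeric(0), 0L))
  switch(cfg$method,
    full = {
      tab <- table(total_keys) / length(total_keys)
      report(tab, length(total_keys))
    },
    partial = {
      # local frequencies against each partition's own size
      fracs <- list()
      for (ks in keyed) {
        if (!length(ks)) next
        tab <- table(ks) / length(ks)
        for (k in names(tab))
          fracs[[k]] <- max(fracs[[k]] %||% 0, tab[[k]])
      }
      report(unlist(fracs), length(total_keys))
    },
    sample = {
      sampled <- with_seed(cfg$rng_seed, lapply(keyed, function(ks) {
        if (!length(ks)) return(character(0))
        m <- max(1L, round(cfg$sample_fraction * length(ks)))
        ks[sample.int(length(ks), m)]
      }))
      s <- unlist(sampled)
      tab <- table(s) / length(s)
      report(tab, length(s))
    },
    slice = {
      sliced <- lapply(keyed, function(ks)
        ks[seq_len(min(length(ks), cfg$slice_size))])
      s <- unlist(sliced)
      tab <- table(s) / length(s)
      report(tab, length(s))
    })
}

#' @export
print.nrc_heavy_report <- function(x, ...) {
  cat("heavy-key report (", x$method, "): ", length(x$heavy_keys),
      " heavy key(s), ", x$tuples_inspected, " tuples inspected\n", sep = "")
  invisible(x)
}

# split a pbag's partitions into heavy / light row subsets by key membership
split_by_heavy <- function(pbag, key_attrs, heavy_keys) {
  heavy_parts <- list(); light_parts <- list()
  for (i in seq_along(pbag$partitions)) {
    df <- pbag$partitions[[i]]
    if (!nrow(df)) { heavy_parts[[i]] <- df; light_parts[[i]] <- df; next }
    is_h <- row_key_strings(df, key_attrs) %in% heavy_keys
    heavy_parts[[i]] <- df[is_h, , drop = FALSE]
    light_parts[[i]] <- df[!is_h, , drop = FALSE]
  }
  list(heavy = partitioned_bag(heavy_parts, pbag$guarantee),
       light = partitioned_bag(light_parts, pbag$guarantee))
}

# core of the skew-aware join, shared with the plan executor: light keys take
# the ordinary shuffle join; heavy-key left tuples stay in place and the
# matching right tuples are broadcast so computation proceeds locally
skew_join_pbags <- function(left, right, left_keys, right_keys, join_fn, by,
                            config, stats, keep = NULL) {
  rep_ <- detect_heavy_keys(left, left_keys, config$skew)
  hk <- rep_$heavy_keys
  if (!length(hk)) {
    ls <- if (pbag_size(left)) shuffle_by_key(left, left_keys, config, stats)
          else left
    rs <- if (pbag_size(right)) shuffle_by_key(right, right_keys, config,
                                               stats) else right
    parts <- lapply(seq_along(ls$partitions), function(i)
      join_fn(ls$partitions[[i]], rs$partitions[[i]], by = by,
              na_matches = "never", relationship = "many-to-many",
              keep = keep))
    return(partitioned_bag(parts, left_keys))
  }
  lsplit <- split_by_heavy(left, left_keys, hk)
  rsplit <- split_by_heavy(right, right_keys, hk)
  ls <- if (pbag_size(lsplit$light)) shuffle_by_key(lsplit$light, left_keys,
                                                    config, stats)
        else lsplit$light
  rs <- if (pbag_size(rsplit$light)) shuffle_by_key(rsplit$light, right_keys,
                                                    config, stats)
        else rsplit$light
  rheavy <- pbag_collect(rsplit$heavy)
  bc <- broadcast(rheavy, config, stats)
  parts <- lapply(seq_along(ls$partitions), function(i) {
    light_join <- join_fn(ls$partitions[[i]], rs$partitions[[i]], by = by,
                          na_matches = "never",
                          relationship = "many-to-many", keep = keep)
    heavy_join <- join_fn(lsplit$heavy$partitions[[i]], bc$tbl, by = by,
                          na_matches = "never",
                          relationship = "many-to-many", keep = keep)
    dplyr::bind_rows(light_join, heavy_join)
  })
  partitioned_bag(parts, "none")
}

#' Skew-aware equi-join
#'
#' Joins two partitioned bags on shared key attributes. Light keys follow the
#' skew-unaware shuffle-join strategy; tuples of heavy keys (detected on the
#' left input with the configured method) are not moved — the matching right
#' tuples are broadcast to every partition and those joins proceed locally.
#' The union of both results equals the skew-unaware join.
#'
#' @param left,right [partitioned_bag()]s with the key attributes in their
#'   schemas (same names on both sides).
#' @param keys character vector of shared key attributes.
#' @param config a [cluster_config()]; `config$skew` selects the detection
#'   method.
#' @param stats optional stats accumulator.
#' @return a [partitioned_bag()] of the joined rows.
#' @export
skew_aware_join <- function(left, right, keys, config,
                            stats = new_exec_stats()) {
  by <- stats::setNames(keys, keys)
  res <- skew_join_pbags(left, right, keys, keys, dplyr::inner_join, by,
                         config, stats)
  record_op_load(stats, "skew_aware_join", res, config)
  res
}

#' Skew-unaware equi-join (baseline)
#'
#' @inheritParams skew_aware_join
#' @export
shuffle_join <- function(left, right, keys, config,
                         stats = new_exec_stats()) {
  ls <- if (pbag_size(left)) shuffle_by_key(left, keys, config, stats)
        else left
  rs <- if (pbag_size(right)) shuffle_by_key(right, keys, config, stats)
        else right
  parts <- lapply(seq_along(ls$partitions), function(i)
    dplyr::inner_join(ls$partitions[[i]], rs$partitions[[i]],
                      by = stats::setNames(keys, keys),
                      na_matches = "never", relationship = "many-to-many"))
  res <- partitioned_bag(parts, keys)
  record_op_load(stats, "shuffle_join", res, config)
  res
}

#' Skew-aware grouping
#'
#' Groups a flat partitioned bag by key attributes. Light keys are grouped
#' via the ordinary key shuffle; tuples of heavy keys remain on their origin
#' partitions (no single-partition group is materialized — the group exists
#' as a distributed bag, the way shredded dictionaries keep inner collections
#' distributed). [sg_assemble()] materializes the logical result for
#' comparison; [sg_sumby()] aggregates heavy groups from per-partition
#' partials without assembling them.
#'
#' @param pbag a flat [partitioned_bag()].
#' @param keys grouping attributes.
#' @param config a [cluster_config()].
#' @param stats optional stats accumulator.
#' @export
skew_aware_group <- function(pbag, keys, config, stats = new_exec_stats()) {
  rep_ <- detect_heavy_keys(pbag, keys, config$skew)
  hk <- rep_$heavy_keys
  sp <- split_by_heavy(pbag, keys, hk)
  light <- if (pbag_size(sp$light))
    shuffle_by_key(sp$light, keys, config, stats) else sp$light
  payload <- setdiff(names(pbag$partitions[[1]]), keys)
  light_grouped <- map_parts(light, function(df) {
    group_partition(df, list(prefix = keys,
                             payload = stats::setNames(as.list(payload),
                                                       payload),
                             out_col = ".group", valid_cols = character(0)))
  }, guarantee = keys)
  res <- structure(list(keys = keys, payload = payload,
                        light = light_grouped, heavy = sp$heavy,
                        heavy_keys = hk, report = rep_),
                   class = "nrc_skew_group")
  record_op_load(stats, "skew_aware_group(light)", light_grouped, config)
  record_op_load(stats, "skew_aware_group(heavy,stationary)", sp$heavy,
                 config)
  res
}

#' @rdname skew_aware_group
#' @param x a skew-aware grouping result.
#' @export
sg_assemble <- function(x) {
  light <- pbag_collect(x$light)
  heavy <- pbag_collect(x$heavy)
  if (nrow(heavy)) {
    hg <- group_partition(heavy, list(prefix = x$keys,
                                      payload = stats::setNames(
                                        as.list(x$payload), x$payload),
                                      out_col = ".group",
                                      valid_cols = character(0)))
    light <- dplyr::bind_rows(light, hg)
  }
  light
}

#' @rdname skew_aware_group
#' @param value_cols numeric payload attributes to sum per group.
#' @export
sg_sumby <- function(x, value_cols) {
  light <- pbag_collect(x$light)
  out <- light[, x$keys, drop = FALSE]
  for (v in value_cols)
    out[[v]] <- vapply(light$.group, function(g)
      sum(vapply(g, function(tup) as.numeric(tup[[v]]), numeric(1))),
      numeric(1))
  # heavy groups: per-partition partial sums, then a (tiny) final combine
  partials <- lapply(x$heavy$partitions, function(df) {
    if (!nrow(df)) return(NULL)
    sumby_partition(df, list(prefix = character(0), keys = x$keys,
                             values = value_cols, out = value_cols))
  })
  partials <- dplyr::bind_rows(partials)
  if (nrow(partials)) {
    final <- sumby_partition(partials, list(prefix = character(0),
                                            keys = x$keys,
                                            values = value_cols,
                                            out = value_cols))
    out <- dplyr::bind_rows(out, final)
  }
  out
}
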