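#' Simulated partitioned runtime
#'
#' Executes plans over an explicit partition model. A [partitioned_bag()] is
#' an ordered list of flat relations (tibbles), one per partition, with an
#' optional co-residency guarantee: `"none"` after round-robin placement,
#' `key(attrs)` after a key shuffle (all tuples sharing key values reside in
#' one partition), or label-based for shredded dictionary relations. "Load"
#' is measured in tuple counts, counting tuples nested inside bag columns
#' (they travel with their parents); partitions are evaluated sequentially —
#' the contract is placement and volume fidelity, not wall-clock parallelism.
#'
#' @name runtime
NULL

#' Cluster configuration
#'
#' @param n_partitions number of partitions (>= 1).
#' @param hash_seed integer seed of the deterministic hash partitioner;
#'   identical configuration and inputs give identical placement.
#' @param skew a [skew_config()]; method `"none"` disables heavy-key
#'   handling.
#' @param partition_cap optional per-partition tuple cap; exceeding it raises
#'   a simulated memory-pressure error (the spill/crash failure mode of
#'   overloaded workers).
#' @export
cluster_config <- function(n_partitions = 4L, hash_seed = 1L,
                           skew = skew_config(), partition_cap = NULL) {
  stopifnot(n_partitions >= 1)
  structure(list(n_partitions = as.integer(n_partitions),
                 hash_seed = as.integer(hash_seed),
                 skew = skew, partition_cap = partition_cap),
            class = "nrc_cluster_config")
}

#' @rdname runtime
#' @param partitions list of tibbles.
#' @param guarantee `"none"`, or a character vector of key attributes whose
#'   values are co-resident.
#' @export
partitioned_bag <- function(partitions, guarantee = "none") {
  structure(list(partitions = partitions, guarantee = guarantee),
            class = "nrc_pbag")
}

#' @export
print.nrc_pbag <- function(x, ...) {
  sizes <- vapply(x$partitions, nrow, integer(1))
  cat("<partitioned bag>", length(sizes), "partitions, sizes:",
      paste(sizes, collapse = ","), "\n")
  invisible(x)
}

#' Collect a partitioned bag into one tibble
#' @param pbag a [partitioned_bag()].
#' @export
pbag_collect <- function(pbag) dplyr::bind_rows(pbag$partitions)

pbag_size <- function(pbag) sum(vapply(pbag$partitions, nrow, integer(1)))

# deep tuple count of one relation: rows plus tuples nested in bag columns
tbl_deep_count <- function(df) {
  n <- nrow(df)
  for (col in df) {
    if (is.list(col)) n <- n + sum(vapply(col, function(cell) {
      if (is.list(cell)) deep_tuple_count(cell) else 0L
    }, integer(1)))
  }
  n
}

#' Round-robin placement
#'
#' Deals tuples to partitions in round-robin order (partition sizes differ by
#' at most one); nested attributes stay with their parents. The result has no
#' partitioning guarantee.
#'
#' @param tbl a tibble.
#' @param config a [cluster_config()].
#' @export
round_robin_partition <- function(tbl, config) {
  k <- config$n_partitions
  n <- nrow(tbl)
  idx <- if (n) ((seq_len(n) - 1L) %% k) + 1L else integer(0)
  parts <- lapply(seq_len(k), function(i) tbl[idx == i, , drop = FALSE])
  partitioned_bag(parts, "none")
}

# ---- deterministic hash partitioner ---------------------------------------

# canonical string form of a column (injective per scalar kind, NA -> marker)
canon_col <- function(v) {
  if (is.list(v)) return(vapply(v, canon_value, character(1)))
  out <- if (is.character(v)) paste0("s:", v)
         else if (is.logical(v)) paste0("b:", ifelse(v, "T", "F"))
         else paste0("n:", sprintf("%.8g", as.numeric(v)))
  out[is.na(v)] <- "#null"
  out
}

row_key_strings <- function(df, key_attrs) {
  missing <- setdiff(key_attrs, names(df))
  if (length(missing))
    stop("missing key attribute: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cols <- lapply(key_attrs, function(k) canon_col(df[[k]]))
  if (!length(cols)) return(rep("", nrow(df)))
  do.call(paste, c(cols, sep = "\x1f"))
}

# seeded 31-polynomial string hash mod 2^31-1; deterministic across platforms
hash_strings <- function(s, seed) {
  M <- 2147483647
  vapply(s, function(x) {
    h <- (as.numeric(seed) + 11) %% M
    for (b in utf8ToInt(x)) h <- (h * 31 + b) %% M
    h
  }, numeric(1), USE.NAMES = FALSE)
}

hash_partition_of <- function(keys, config) {
  as.integer(hash_strings(keys, config$hash_seed) %% config$n_partitions) + 1L
}

#' Execution statistics accumulator
#'
#' Tracks shuffled and broadcast tuple counts, per-operator per-partition
#' loads, and the maximum partition load seen.
#'
#' @export
new_exec_stats <- function() {
  e <- new.env(parent = emptyenv())
  e$shuffled_tuples <- 0
  e$broadcast_tuples <- 0
  e$max_partition_load <- 0
  e$ops <- list()
  class(e) <- "nrc_exec_stats"
  e
}

#' @export
print.nrc_exec_stats <- function(x, ...) {
  cat("shuffled_tuples:    ", x$shuffled_tuples, "\n")
  cat("broadcast_tuples:   ", x$broadcast_tuples, "\n")
  cat("max_partition_load: ", x$max_partition_load, "\n")
  invisible(x)
}

#' Summarize execution statistics as a tibble
#' @param stats an object from [new_exec_stats()].
#' @export
stats_tbl <- function(stats) {
  tibble::tibble(
    shuffled_tuples = stats$shuffled_tuples,
    broadcast_tuples = stats$broadcast_tuples,
    max_partition_load = stats$max_partition_load)
}

record_op_load <- function(stats, op_label, pbag, config) {
  loads <- vapply(pbag$partitions, tbl_deep_count, integer(1))
  stats$ops[[length(stats$ops) + 1L]] <-
    list(op = op_label, loads = loads)
  stats$max_partition_load <- max(stats$max_partition_load, loads)
  if (!is.null(config$partition_cap) &&
      any(loads > config$partition_cap))
    stop("partition tuple cap exceeded (", max(loads), " > ",
         config$partition_cap, "): simulated memory spill", call. = FALSE)
  invisible(stats)
}

#' Shuffle a partitioned bag by key
#'
#' Moves tuples so that all tuples sharing values of `key_attrs` co-reside in
#' the partition chosen by the seeded hash partitioner, establishing a
#' key-based partitioning guarantee. Tuples already on their target partition
#' are not counted as shuffled.
#'
#' @param pbag a [partitioned_bag()].
#' @param key_attrs character vector of key attributes.
#' @param config a [cluster_config()].
#' @param stats optional stats accumulator to charge the move to.
#' @export
shuffle_by_key <- function(pbag, key_attrs, config, stats = NULL) {
  k <- config$n_partitions
  moved <- 0
  buckets <- vector("list", k)
  for (pi in seq_along(pbag$partitions)) {
    df <- pbag$partitions[[pi]]
    if (!nrow(df)) next
    tgt <- hash_partition_of(row_key_strings(df, key_attrs), config)
    for (ti in unique(tgt)) {
      piece <- df[tgt == ti, , drop = FALSE]
      if (ti != pi) moved <- moved + tbl_deep_count(piece)
      buckets[[ti]] <- c(buckets[[ti]], list(piece))
    }
  }
  proto <- pbag$partitions[[1]][0, , drop = FALSE]
  parts <- lapply(buckets, function(b)
    if (is.null(b)) proto else dplyr::bind_rows(b))
  if (!is.null(stats)) stats$shuffled_tuples <- stats$shuffled_tuples + moved
  partitioned_bag(parts, key_attrs)
}

#' Broadcast a relation to every partition
#'
#' Duplicates a (small) relation on each partition so joins against it
#' proceed without moving the large side. Charges `nrow * n_partitions`
#' broadcast tuples.
#'
#' @param tbl a tibble.
#' @param config a [cluster_config()].
#' @param stats optional stats accumulator.
#' @return the replicated handle (the tibble itself plus a broadcast flag).
#' @export
broadcast <- function(tbl, config, stats = NULL) {
  if (!is.null(stats))
    stats$broadcast_tuples <- stats$broadcast_tuples +
      tbl_deep_count(tbl) * config$n_partitions
  structure(list(tbl = tbl), class = "nrc_broadcast")
}
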