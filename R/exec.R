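#' Plan execution engine
#'
#' Evaluates a plan DAG over partitioned relations, threading an execution
#' statistics accumulator through every shuffle and broadcast. Partition
#' placement is deterministic given the inputs and the cluster
#' configuration's hash seed.
#'
#' @name plan-exec
NULL

exec_plan <- function(plan, inputs, config, stats = new_exec_stats()) {
  cache <- new.env(parent = emptyenv())
  run <- function(p) {
    key <- as.character(p$id)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- exec_op(p, run, inputs, config, stats)
    record_op_load(stats, plan_describe(p), res, config)
    assign(key, res, envir = cache)
    res
  }
  run(plan)
}

map_parts <- function(pbag, f, guarantee = pbag$guarantee) {
  partitioned_bag(lapply(pbag$partitions, f), guarantee)
}

exec_op <- function(p, run, inputs, config, stats) {
  switch(p$op,
    scan = {
      tbl <- inputs[[p$name]]
      if (is.null(tbl)) stop("no input relation: ", p$name, call. = FALSE)
      round_robin_partition(tbl, config)
    },

    select = {
      child <- run(p$inputs[[1]])
      map_parts(child, function(df) {
        if (!nrow(df)) return(df)
        keep <- ev_col(p$pred, df)
        df[!is.na(keep) & keep, , drop = FALSE]
      })
    },

    project = {
      child <- run(p$inputs[[1]])
      map_parts(child, function(df) {
        cols <- lapply(p$exprs, ev_col, df = df)
        tibble::as_tibble(cols, .name_repair = "minimal")
      }, guarantee = "none")
    },

    addid = {
      child <- run(p$inputs[[1]])
      sizes <- vapply(child$partitions, nrow, integer(1))
      offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
      parts <- lapply(seq_along(child$partitions), function(i) {
        df <- child$partitions[[i]]
        df[[p$col]] <- offsets[i] + seq_len(nrow(df))
        df
      })
      partitioned_bag(parts, child$guarantee)
    },

    flatten = {
      child <- run(p$inputs[[1]])
      # dense child ids across partitions, deterministic in partition order
      counts <- vapply(child$partitions, function(df) {
        if (!nrow(df)) return(0L)
        sum(vapply(df[[p$bag_col]], function(cell)
          if (is.list(cell)) length(cell) else 0L, integer(1)))
      }, integer(1))
      offsets <- cumsum(c(0L, counts))[seq_along(counts)]
      parts <- lapply(seq_along(child$partitions), function(i) {
        flatten_partition(child$partitions[[i]], p, offsets[i])
      })
      partitioned_bag(parts, child$guarantee)
    },

    join = {
      left <- run(p$inputs[[1]])
      right <- run(p$inputs[[2]])
      exec_join(left, right, p, config, stats)
    },

    sumby = {
      child <- run(p$inputs[[1]])
      gb <- c(p$prefix, p$keys)
      # local partial aggregation (combiner) before the shuffle
      partial <- map_parts(child, function(df) sumby_partition(df, p),
                           guarantee = "none")
      if (isTRUE(p$local)) return(partial)
      shuffle_keys <- if (length(gb)) gb else p$keys
      shuffled <- if (pbag_size(partial) == 0) partial
        else shuffle_by_key(partial, shuffle_keys, config, stats)
      pfinal <- p
      pfinal$values <- p$out  # partials already carry the output names
      map_parts(shuffled, function(df) sumby_partition(df, pfinal),
                guarantee = shuffle_keys)
    },

    group = {
      child <- run(p$inputs[[1]])
      shuffled <- if (length(p$prefix) && pbag_size(child) > 0)
        shuffle_by_key(child, p$prefix, config, stats) else child
      map_parts(shuffled, function(df) group_partition(df, p),
                guarantee = p$prefix)
    },

    attach = {
      parent <- run(p$inputs[[1]])
      grouped <- run(p$inputs[[2]])
      pl <- if (pbag_size(parent)) shuffle_by_key(parent, p$by, config, stats)
            else parent
      gl <- if (pbag_size(grouped)) shuffle_by_key(grouped, p$by, config,
                                                   stats) else grouped
      parts <- lapply(seq_along(pl$partitions), function(i) {
        attach_partition(pl$partitions[[i]], gl$partitions[[i]], p)
      })
      partitioned_bag(parts, p$by)
    },

    distinct = {
      child <- run(p$inputs[[1]])
      keyed <- map_parts(child, function(df) {
        df[[".dk"]] <- row_key_strings(df, p$cols)
        df
      })
      shuffled <- if (pbag_size(keyed)) shuffle_by_key(keyed, ".dk", config,
                                                       stats) else keyed
      map_parts(shuffled, function(df) {
        df <- df[!duplicated(df[[".dk"]]), , drop = FALSE]
        df[[".dk"]] <- NULL
        df
      }, guarantee = "none")
    },

    union = {
      a <- run(p$inputs[[1]])
      b <- run(p$inputs[[2]])
      parts <- lapply(seq_along(a$partitions), function(i)
        dplyr::bind_rows(a$partitions[[i]], b$partitions[[i]]))
      partitioned_bag(parts, "none")
    },

    stop("unknown plan operator: ", p$op)
  )
}

# one output row per child element; parents with empty (or null) bags emit a
# single row with null children when the flatten is outer
flatten_partition <- function(df, p, id_offset) {
  fields <- p$fields
  fnames <- names(fields)
  out_base <- df[, setdiff(names(df), p$bag_col), drop = FALSE]
  if (!nrow(df)) {
    for (f in fnames) out_base[[fields[[f]]$col]] <-
      empty_col(fields[[f]]$type)
    out_base[[p$id_col]] <- integer(0)
    return(out_base)
  }
  bags <- df[[p$bag_col]]
  lens <- vapply(bags, function(cell)
    if (is.list(cell)) length(cell) else 0L, integer(1))
  rep_counts <- if (p$outer) pmax(1L, lens) else lens
  idx <- rep(seq_len(nrow(df)), rep_counts)
  out <- out_base[idx, , drop = FALSE]
  # element position within the concatenated bags; 0 marks a padding row
  elem_pos <- unlist(lapply(seq_along(bags), function(i) {
    if (lens[i] == 0L) { if (p$outer) 0L else integer(0) }
    else seq_len(lens[i])
  }))
  all_elems <- unlist(lapply(bags, function(cell)
    if (is.list(cell)) cell else list()), recursive = FALSE)
  pick <- cumsum(ifelse(elem_pos == 0L, 0L, 1L))
  for (f in fnames) {
    ft <- fields[[f]]$type
    colname <- fields[[f]]$col
    if (is_bag_type(ft)) {
      out[[colname]] <- lapply(seq_along(elem_pos), function(j) {
        if (elem_pos[j] == 0L) NA else all_elems[[pick[j]]][[f]]
      })
    } else {
      caster <- switch(ft$kind, string = as.character, int = as.integer,
                       real = as.numeric, bool = as.logical)
      out[[colname]] <- vapply(seq_along(elem_pos), function(j) {
        if (elem_pos[j] == 0L) caster(NA) else caster(all_elems[[pick[j]]][[f]])
      }, caster(NA))
    }
  }
  nvalid <- sum(elem_pos > 0L)
  ids <- rep(NA_integer_, length(elem_pos))
  ids[elem_pos > 0L] <- id_offset + seq_len(nvalid)
  out[[p$id_col]] <- ids
  out
}

exec_join <- function(left, right, p, config, stats) {
  if (!length(p$left_keys)) {
    # cartesian association: replicate the right side everywhere
    rtbl <- pbag_collect(right)
    bc <- broadcast(rtbl, config, stats)
    return(map_parts(left, function(df) dplyr::cross_join(df, bc$tbl),
                     guarantee = left$guarantee))
  }
  join_fn <- if (p$kind == "inner") dplyr::inner_join else dplyr::left_join
  by <- stats::setNames(p$right_keys, p$left_keys)
  if (config$skew$method != "none") {
    return(skew_join_pbags(left, right, p$left_keys, p$right_keys,
                           join_fn, by, config, stats, keep = TRUE))
  }
  ls <- if (identical(left$guarantee, p$left_keys)) left
        else if (pbag_size(left)) shuffle_by_key(left, p$left_keys, config,
                                                 stats) else left
  rs <- if (identical(right$guarantee, p$right_keys)) right
        else if (pbag_size(right)) shuffle_by_key(right, p$right_keys, config,
                                                  stats) else right
  parts <- lapply(seq_along(ls$partitions), function(i)
    join_fn(ls$partitions[[i]], rs$partitions[[i]], by = by,
            na_matches = "never", relationship = "many-to-many",
            keep = TRUE))
  partitioned_bag(parts, p$left_keys)
}

sumby_partition <- function(df, p) {
  gb <- c(p$prefix, p$keys)
  if (!nrow(df)) {
    out <- df[, c(gb, p$values), drop = FALSE]
    names(out) <- c(gb, p$out)
    return(out)
  }
  valid <- rep(TRUE, nrow(df))
  for (k in p$keys) valid <- valid & !is.na(df[[k]])
  if (length(gb) == 0) {
    sums <- lapply(p$values, function(v) sum(df[[v]][valid], na.rm = TRUE))
    out <- tibble::as_tibble(stats::setNames(sums, p$out))
    return(out)
  }
  df <- df[valid, , drop = FALSE]
  if (!nrow(df)) {
    out <- df[, c(gb, p$values), drop = FALSE]
    names(out) <- c(gb, p$out)
    return(out)
  }
  key <- row_key_strings(df, gb)
  first <- !duplicated(key)
  out <- df[first, gb, drop = FALSE]
  grp <- match(key, key[first])
  for (j in seq_along(p$values)) {
    v <- df[[p$values[j]]]
    v[is.na(v)] <- 0
    out[[p$out[j]]] <- as.numeric(rowsum(v, grp)[, 1])
  }
  out
}

group_partition <- function(df, p) {
  payload_fields <- names(p$payload)
  if (!nrow(df)) {
    out <- df[, p$prefix, drop = FALSE]
    out[[p$out_col]] <- list()
    return(out)
  }
  valid <- rep(TRUE, nrow(df))
  for (vc in p$valid_cols) valid <- valid & !is.na(df[[vc]])
  key <- row_key_strings(df, p$prefix)
  first <- !duplicated(key)
  out <- df[first, p$prefix, drop = FALSE]
  grp_of <- match(key, key[first])
  cells <- vector("list", sum(first))
  for (g in seq_along(cells)) cells[[g]] <- list()
  vrows <- which(valid)
  if (length(vrows)) {
    payload_cols <- lapply(payload_fields, function(f) df[[p$payload[[f]]]])
    names(payload_cols) <- payload_fields
    tuples <- lapply(vrows, function(i) {
      tup <- lapply(payload_cols, function(col)
        if (is.list(col)) col[[i]] else col[[i]])
      tup
    })
    for (j in seq_along(vrows)) {
      g <- grp_of[vrows[j]]
      cells[[g]][[length(cells[[g]]) + 1L]] <- tuples[[j]]
    }
  }
  out[[p$out_col]] <- cells
  out
}

attach_partition <- function(parent, grouped, p) {
  join_fn <- if (p$inner) dplyr::inner_join else dplyr::left_join
  out <- join_fn(parent, grouped, by = p$by, na_matches = "never",
                 relationship = "many-to-many")
  col <- out[[p$bag_col]]
  if (is.null(col)) {
    out[[p$bag_col]] <- rep(list(list()), nrow(out))
  } else {
    out[[p$bag_col]] <- lapply(col, function(cell)
      if (is.null(cell) || (!is.list(cell) && is.na(cell))) list() else cell)
  }
  out
}
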