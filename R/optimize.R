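#' Plan optimizations
#'
#' Two result-preserving rewrites over compiled plans.
#'
#' [push_projections()] walks the operator DAG computing, for every edge,
#' the set of columns actually used downstream (including, for bag columns,
#' which element fields are used), and prunes every scan's projection to
#' that set — nested attributes are pruned inside their list columns, so a
#' scan of a nested source retains only the subfields the program touches.
#'
#' [push_partial_aggregates()] rewrites a keyed sum whose summand is a
#' product with one factor per side of an inner equi-join: the sum
#' distributes over the join (within each join-key group the pairs form a
#' cross product, so the sum of products factorizes), letting the left
#' factor be pre-aggregated per (group keys, join keys) before the join.
#' This shrinks the relation entering the join's shuffle. The rewrite is a
#' no-op when the pattern does not apply.
#'
#' Both functions return a plan that yields [bag_equal()] results to the
#' input plan.
#'
#' @param plan an indexed plan (as found in `nrc_compiled$plans[[i]]$plan`).
#' @name plan-optimize
NULL

req_merge <- function(a, b) {
  for (nm in names(b)) {
    if (isTRUE(a[[nm]]) || isTRUE(b[[nm]])) a[[nm]] <- TRUE
    else if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else a[[nm]] <- req_merge(a[[nm]], b[[nm]])
  }
  a
}

req_all <- function(cols) stats::setNames(rep(list(TRUE), length(cols)), cols)

# columns referenced by a column expression, as a requirement set
cx_req <- function(e) {
  switch(e$kind,
    colref = req_all(e$name),
    const = list(),
    arith = , cmp = , bool = req_merge(cx_req(e$lhs), cx_req(e$rhs)),
    labelkey = Reduce(req_merge, lapply(e$bindings, cx_req), list()),
    isnotnull = cx_req(e$expr),
    prunebag = stats::setNames(list(e$fields), e$col),
    list())
}

#' @rdname plan-optimize
#' @export
push_projections <- function(plan) {
  out <- pp_walk(plan, req_all(plan$out_cols %||% character(0)))
  plan_index(out)
}

pp_walk <- function(p, req) {
  switch(p$op,
    scan = p,
    project = {
      child <- p$inputs[[1]]
      used <- intersect(names(p$exprs), names(req))
      creq <- list()
      for (nm in used) {
        e <- p$exprs[[nm]]
        if (e$kind == "colref") {
          # a straight column copy inherits the (possibly nested) requirement
          creq <- req_merge(creq, stats::setNames(list(req[[nm]] %||% TRUE),
                                                  e$name))
        } else {
          creq <- req_merge(creq, cx_req(e))
        }
      }
      if (child$op == "scan") {
        # prune the scan's projection to what is needed, slicing bag columns
        exprs <- list()
        for (nm in used) {
          e <- p$exprs[[nm]]
          r <- req[[nm]]
          if (e$kind == "colref" && !isTRUE(r))
            exprs[[nm]] <- list(kind = "prunebag", col = e$name, fields = r)
          else exprs[[nm]] <- e
        }
        p$exprs <- exprs
        p$out_cols <- names(exprs)
        p
      } else {
        p$inputs[[1]] <- pp_walk(child, creq)
        p$exprs <- p$exprs[used]
        p$out_cols <- used
        p
      }
    },
    select = {
      creq <- req_merge(req, cx_req(p$pred))
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], creq)
      p
    },
    addid = {
      creq <- req[setdiff(names(req), p$col)]
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], creq)
      p
    },
    flatten = {
      fcols <- vapply(p$fields, function(f) f$col, character(1))
      nested <- list()
      for (f in names(p$fields)) {
        r <- req[[p$fields[[f]]$col]]
        if (!is.null(r)) nested[[f]] <- r
      }
      creq <- req[setdiff(names(req), c(fcols, p$id_col))]
      creq[[p$bag_col]] <- if (length(nested)) nested else TRUE
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], creq)
      # drop pruned fields from the flatten itself
      if (length(nested)) p$fields <- p$fields[names(nested)]
      p
    },
    join = {
      lcols <- p$inputs[[1]]$out_cols; rcols <- p$inputs[[2]]$out_cols
      lreq <- req_merge(req[intersect(names(req), lcols)],
                        req_all(p$left_keys))
      rreq <- req_merge(req[intersect(names(req), rcols)],
                        req_all(p$right_keys))
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], lreq)
      p$inputs[[2]] <- pp_walk(p$inputs[[2]], rreq)
      p
    },
    sumby = {
      creq <- req_all(c(p$prefix, p$keys, p$values))
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], creq)
      p
    },
    group = {
      creq <- req_all(c(p$prefix, unlist(p$payload), p$valid_cols))
      nested <- req[[p$out_col]]
      if (!isTRUE(nested) && !is.null(nested)) {
        for (f in names(nested))
          if (!is.null(p$payload[[f]]))
            creq[[p$payload[[f]]]] <- nested[[f]]
      }
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], creq)
      p
    },
    attach = {
      preq <- req_merge(req[setdiff(names(req), p$bag_col)],
                        req_all(p$by))
      greq <- req_all(p$by)
      greq[[p$bag_col]] <- req[[p$bag_col]] %||% TRUE
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], preq)
      p$inputs[[2]] <- pp_walk(p$inputs[[2]], greq)
      p
    },
    distinct = {
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], req_all(p$cols))
      p
    },
    union = {
      p$inputs[[1]] <- pp_walk(p$inputs[[1]], req)
      p$inputs[[2]] <- pp_walk(p$inputs[[2]], req)
      p
    },
    { p$inputs <- lapply(p$inputs, pp_walk,
                         req = req_all(unlist(lapply(p$inputs, function(ch)
                           ch$out_cols)))); p }
  )
}

#' @rdname plan-optimize
#' @export
push_partial_aggregates <- function(plan) {
  plan_index(ppa_walk(plan))
}

ppa_walk <- function(p) {
  p$inputs <- lapply(p$inputs, ppa_walk)
  if (p$op != "sumby" || length(p$values) != 1) return(p)
  proj <- p$inputs[[1]]
  if (proj$op != "project") return(p)
  jn <- proj$inputs[[1]]
  if (jn$op != "join" || jn$kind != "inner" || !length(jn$left_keys))
    return(p)
  L <- jn$inputs[[1]]; R <- jn$inputs[[2]]
  lcols <- L$out_cols; rcols <- R$out_cols
  # the summand must be a product with one plain-column factor per side
  ve <- proj$exprs[[p$values]]
  if (is.null(ve) || ve$kind != "arith" || ve$op != "*" ||
      ve$lhs$kind != "colref" || ve$rhs$kind != "colref") return(p)
  fac <- c(ve$lhs$name, ve$rhs$name)
  a <- fac[fac %in% lcols]; b <- fac[fac %in% rcols]
  if (length(a) != 1 || length(b) != 1) return(p)
  # group keys must trace through the projection to left-side columns
  trace <- function(col) {
    e <- proj$exprs[[col]]
    if (!is.null(e) && e$kind == "colref") e$name else col
  }
  gb <- c(p$prefix, p$keys)
  src <- vapply(gb, trace, character(1))
  if (!all(src %in% lcols)) return(p)
  keys_pre <- unique(c(src, jn$left_keys))
  pre <- p_sumby(L, prefix = character(0), keys = keys_pre,
                 values = a, out = a, local = TRUE)
  pre$out_cols <- c(keys_pre, a)
  jn2 <- p_join(pre, R, left_keys = jn$left_keys,
                right_keys = jn$right_keys, kind = "inner")
  jn2$out_cols <- c(pre$out_cols, rcols)
  exprs <- stats::setNames(lapply(src, cx_col), gb)
  exprs[[p$values]] <- cx_bin("arith", "*", cx_col(a), cx_col(b))
  proj2 <- p_project(jn2, exprs)
  proj2$out_cols <- names(exprs)
  p$inputs[[1]] <- proj2
  p
}
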