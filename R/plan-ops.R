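#' Dataflow plan IR
#'
#' Compiled programs are DAGs of flat operators over relations (tibbles):
#' `scan`, `select`, `project`, `addid` (dense unique ids), `flatten`
#' (outer-flatten of a bag attribute: one output row per child element, with
#' a single NULL-padded row for parents whose bag is empty), `join`
#' (inner/left_outer), `sumby` (keyed sums with a preserved parent prefix),
#' `group` (nests payload columns into a bag column per key prefix; NULL
#' child rows regroup to empty bags), `attach` (left-outer reattachment of a
#' grouped child onto its parent by the maintained id prefix), `distinct`,
#' and `union`. Every operator's schema is flat except for bag columns
#' produced by `group`/`attach` and bag columns carried through from nested
#' scans.
#'
#' Plans print as indented text and serialize to JSON via [plan_to_json()].
#'
#' @name plan-ir
NULL

plan_node <- function(op, inputs = list(), ...) {
  structure(list(op = op, inputs = inputs, ...), class = "nrc_plan")
}

p_scan     <- function(name) plan_node("scan", name = name)
p_select   <- function(child, pred) plan_node("select", list(child), pred = pred)
p_project  <- function(child, exprs) plan_node("project", list(child),
                                               exprs = exprs)
p_addid    <- function(child, col) plan_node("addid", list(child), col = col)
p_flatten  <- function(child, bag_col, var, fields, id_col, outer = TRUE)
  plan_node("flatten", list(child), bag_col = bag_col, var = var,
            fields = fields, id_col = id_col, outer = outer)
p_join     <- function(left, right, left_keys, right_keys,
                       kind = c("inner", "left_outer"))
  plan_node("join", list(left, right), left_keys = left_keys,
            right_keys = right_keys, kind = match.arg(kind))
p_sumby    <- function(child, prefix, keys, values, out, local = FALSE)
  plan_node("sumby", list(child), prefix = prefix, keys = keys,
            values = values, out = out, local = local)
p_group    <- function(child, prefix, payload, out_col, valid_cols)
  plan_node("group", list(child), prefix = prefix, payload = payload,
            out_col = out_col, valid_cols = valid_cols)
p_attach   <- function(parent, grouped, by, bag_col, inner = FALSE)
  plan_node("attach", list(parent, grouped), by = by, bag_col = bag_col,
            inner = inner)
p_distinct <- function(child, cols) plan_node("distinct", list(child),
                                              cols = cols)
p_union    <- function(a, b) plan_node("union", list(a, b))

# assign dense node ids (post-order) for execution caching and printing
plan_index <- function(plan) {
  n <- 0L
  walk <- function(p) {
    p$inputs <- lapply(p$inputs, walk)
    n <<- n + 1L
    p$id <- n
    p
  }
  walk(plan)
}

# ---- printing --------------------------------------------------------------

fmt_colexpr <- function(e) {
  switch(e$kind,
    colref = e$name,
    const = as.character(e$value),
    arith = , cmp = , bool = paste0("(", fmt_colexpr(e$lhs), " ", e$op, " ",
                                    fmt_colexpr(e$rhs), ")"),
    labelkey = paste0("mklabel<", e$level, ">(",
                      paste(names(e$bindings), collapse = ","), ")"),
    isnotnull = paste0("notnull(", fmt_colexpr(e$expr), ")"),
    prunebag = paste0(e$col, "{", paste(names(e$fields), collapse = ","),
                      "}"),
    "?")
}

plan_describe <- function(p) {
  switch(p$op,
    scan = paste0("Scan(", p$name, ")"),
    select = paste0("Select(", fmt_colexpr(p$pred), ")"),
    project = paste0("Project(", paste0(names(p$exprs), collapse = ", "), ")"),
    addid = paste0("AddId(", p$col, ")"),
    flatten = paste0(if (p$outer) "OuterFlatten(" else "Flatten(",
                     p$bag_col, " -> ", p$var, ")"),
    join = paste0("Join[", p$kind, "](",
                  paste(p$left_keys, p$right_keys, sep = "=",
                        collapse = ", "), ")"),
    sumby = paste0(if (isTRUE(p$local)) "LocalSumByKey(prefix=[" else
                     "SumByKey(prefix=[", paste(p$prefix, collapse = ","),
                   "], keys=[", paste(p$keys, collapse = ","),
                   "], values=[", paste(p$values, collapse = ","), "])"),
    group = paste0("GroupByKey(prefix=[", paste(p$prefix, collapse = ","),
                   "] -> ", p$out_col, ")"),
    attach = paste0(if (p$inner) "AttachInner(" else "AttachOuter(",
                    p$bag_col, " by [", paste(p$by, collapse = ","), "])"),
    distinct = "Distinct",
    union = "Union",
    p$op)
}

#' @export
format.nrc_plan <- function(x, indent = 0L, ...) {
  head <- paste0(strrep("  ", indent), plan_describe(x), "\n")
  paste0(head, paste0(vapply(x$inputs, format, character(1),
                             indent = indent + 1L), collapse = ""))
}

#' @export
print.nrc_plan <- function(x, ...) {
  cat(format(x))
  invisible(x)
}

#' Serialize a plan to JSON
#'
#' @param plan a compiled plan.
#' @return a JSON string describing the operator DAG.
#' @export
plan_to_json <- function(plan) {
  to_list <- function(p) {
    out <- list(op = p$op, desc = plan_describe(p))
    for (f in setdiff(names(p), c("op", "inputs", "pred", "exprs",
                                  "payload", "fields")))
      out[[f]] <- p[[f]]
    if (!is.null(p$fields)) out$fields <- names(p$fields)
    out$inputs <- lapply(p$inputs, to_list)
    out
  }
  jsonlite::toJSON(to_list(plan), auto_unbox = TRUE, null = "null")
}

# all operators of a given type in a plan (preorder)
plan_ops <- function(plan, op = NULL) {
  acc <- list()
  walk <- function(p) {
    if (is.null(op) || p$op == op) acc[[length(acc) + 1L]] <<- p
    for (ch in p$inputs) walk(ch)
  }
  walk(plan)
  acc
}

# ---- column expressions ----------------------------------------------------

cx_col   <- function(name) list(kind = "colref", name = name)
cx_const <- function(value) list(kind = "const", value = value)
cx_bin   <- function(kind, op, lhs, rhs) list(kind = kind, op = op,
                                              lhs = lhs, rhs = rhs)
cx_label <- function(level, bindings) list(kind = "labelkey", level = level,
                                           bindings = bindings)
cx_notnull <- function(e) list(kind = "isnotnull", expr = e)

# vectorized evaluation of a column expression over a tibble
ev_col <- function(e, df) {
  n <- nrow(df)
  switch(e$kind,
    colref = {
      v <- df[[e$name]]
      if (is.null(v)) stop("plan references unknown column: ", e$name,
                           call. = FALSE)
      v
    },
    const = rep(e$value, n),
    arith = {
      l <- ev_col(e$lhs, df); r <- ev_col(e$rhs, df)
      if (e$op == "/" && any(!is.na(r) & r == 0))
        stop("division by zero", call. = FALSE)
      switch(e$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r)
    },
    cmp = {
      l <- ev_col(e$lhs, df); r <- ev_col(e$rhs, df)
      switch(e$op, "==" = l == r, "!=" = l != r, "<" = l < r,
             "<=" = l <= r, ">" = l > r, ">=" = l >= r)
    },
    bool = {
      l <- ev_col(e$lhs, df); r <- ev_col(e$rhs, df)
      if (e$op == "&&") l & r else l | r
    },
    labelkey = {
      parts <- lapply(names(e$bindings), function(b) {
        v <- ev_col(e$bindings[[b]], df)
        paste0(b, "=", vapply(v, canon_scalar, character(1)))
      })
      body <- if (length(parts)) do.call(paste, c(parts, sep = "|")) else
        rep("", n)
      paste0("L<", e$level, ">", body)
    },
    isnotnull = !is.na(ev_col(e$expr, df)),
    prunebag = lapply(df[[e$col]], prune_cell, spec = e$fields),
    stop("unknown column expression kind: ", e$kind)
  )
}

# keep only the required element fields of a bag cell, recursively
prune_cell <- function(cell, spec) {
  if (!is.list(cell)) return(cell)  # null padding
  lapply(cell, function(tup) {
    keep <- intersect(names(spec), names(tup))
    tup <- tup[keep]
    for (f in keep)
      if (!isTRUE(spec[[f]])) tup[[f]] <- prune_cell(tup[[f]], spec[[f]])
    tup
  })
}

# translate a scalar AST expression into a column expression, given a map
# from comprehension variable -> (field -> column name)
ast_to_colexpr <- function(e, varcols) {
  switch(e$kind,
    project = {
      if (e$expr$kind != "var")
        stop("unsupported projection in compiled expression", call. = FALSE)
      cols <- varcols[[e$expr$name]]
      if (is.null(cols) || is.null(cols[[e$attr]]))
        stop("no column for ", e$expr$name, ".", e$attr, call. = FALSE)
      cx_col(cols[[e$attr]])
    },
    const = cx_const(e$value),
    arith = cx_bin("arith", e$op, ast_to_colexpr(e$lhs, varcols),
                   ast_to_colexpr(e$rhs, varcols)),
    cmp = cx_bin("cmp", e$op, ast_to_colexpr(e$lhs, varcols),
                 ast_to_colexpr(e$rhs, varcols)),
    bool = cx_bin("bool", e$op, ast_to_colexpr(e$lhs, varcols),
                  ast_to_colexpr(e$rhs, varcols)),
    newlabel = cx_label(e$level, lapply(e$bindings, ast_to_colexpr,
                                        varcols = varcols)),
    stop("expression kind not compilable to a column: ", e$kind)
  )
}
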