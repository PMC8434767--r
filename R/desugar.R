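#' Desugar groupBy into dedup + nested comprehension
#'
#' `groupBy[k -> g](e)` is convenience syntax for building a deduplicated bag
#' of keys and then, per key, collecting the non-key parts of the matching
#' tuples:
#'
#' ```
#' for k in dedup(for x in e union { k1 := x.k1, ... }) union
#'   { k1 := k.k1, ...,
#'     g := for x in e union
#'       if (x.k1 == k.k1 && ...) then { rest1 := x.rest1, ... } }
#' ```
#'
#' Evaluating either form yields [bag_equal()] results. The rewrite needs the
#' element type of `e` (to enumerate the non-key attributes), so the program
#' must typecheck against the supplied schemas.
#'
#' @param program an [nrc_program()].
#' @param input_schemas named list of input bag types.
#' @return the program with every `groupBy` node rewritten.
#' @export
desugar_groupby <- function(program, input_schemas) {
  typecheck(program, input_schemas)  # reject ill-typed input up front
  known <- input_schemas
  assignments <- list()
  for (a in program$assignments) {
    expr2 <- desugar_expr(a$expr, env = list(), schemas = known)
    known[[a$name]] <- type_of(expr2, env = list(), schemas = known)
    assignments[[length(assignments) + 1L]] <- list(name = a$name,
                                                    expr = expr2)
  }
  nrc_program(assignments)
}

desugar_expr <- function(e, env, schemas) {
  rec <- function(x, env2 = env) desugar_expr(x, env2, schemas)
  switch(e$kind,
    input = , var = , const = , labeldomain = e,
    project = { e$expr <- rec(e$expr); e },
    tuple = { e$fields <- lapply(e$fields, rec); e },
    sng = , dedup = , sumby = { e$expr <- rec(e$expr); e },
    "for" = {
      e$source <- rec(e$source)
      st <- type_of(e$source, env, schemas)
      env[[e$var]] <- st$elem
      e$body <- rec(e$body, env)
      e
    },
    "if" = { e$cond <- rec(e$cond); e$then <- rec(e$then); e },
    cmp = , bool = , arith = , union = {
      e$lhs <- rec(e$lhs); e$rhs <- rec(e$rhs); e
    },
    newlabel = { e$bindings <- lapply(e$bindings, rec); e },
    groupby = {
      inner <- rec(e$expr)
      t <- type_of(inner, env, schemas)
      rest <- setdiff(names(t$elem$fields), e$keys)
      kv <- "g_k__"; xv <- "g_x__"
      key_tuple <- nrc_tuple(stats::setNames(
        lapply(e$keys, function(k) nrc_project(nrc_var(xv), k)), e$keys))
      key_src <- nrc_dedup(nrc_for(xv, inner, nrc_sng(key_tuple)))
      cond <- Reduce(function(acc, k) {
        c_ <- nrc_cmp("==", nrc_project(nrc_var(xv), k),
                      nrc_project(nrc_var(kv), k))
        if (is.null(acc)) c_ else nrc_bool("&&", acc, c_)
      }, e$keys, accumulate = FALSE, init = NULL)
      rest_tuple <- nrc_tuple(stats::setNames(
        lapply(rest, function(r) nrc_project(nrc_var(xv), r)), rest))
      group_expr <- nrc_for(xv, inner, nrc_if(cond, nrc_sng(rest_tuple)))
      head_fields <- stats::setNames(
        lapply(e$keys, function(k) nrc_project(nrc_var(kv), k)), e$keys)
      head_fields[[e$group_attr]] <- group_expr
      nrc_for(kv, key_src, nrc_sng(nrc_tuple(head_fields)))
    },
    stop("unknown node kind: ", e$kind)
  )
}
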