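#' Expression AST
#'
#' Constructors for the expression language: comprehensions (`for ... in
#' ... union`), tuple construction, projection, conditionals restricted to bag
#' positions, arithmetic, comparison and boolean predicates, `dedup`,
#' `groupBy`, `sumBy`, and bag union. Two extra node kinds (`nrc_new_label`,
#' `nrc_label_domain`) appear only in shredded component programs, where
#' nested collections are replaced by label surrogates.
#'
#' @name nrc-ast
NULL

node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "nrc_expr")
}

#' @rdname nrc-ast
#' @param name input or variable name.
#' @export
nrc_input <- function(name) node("input", name = name)

#' @rdname nrc-ast
#' @export
nrc_var <- function(name) node("var", name = name)

#' @rdname nrc-ast
#' @param expr,attr project attribute `attr` out of tuple-valued `expr`.
#' @export
nrc_project <- function(expr, attr) node("project", expr = expr, attr = attr)

#' @rdname nrc-ast
#' @param fields named list of expressions.
#' @export
nrc_tuple <- function(fields) {
  stopifnot(!is.null(names(fields)), !anyDuplicated(names(fields)))
  node("tuple", fields = fields)
}

#' @rdname nrc-ast
#' @export
nrc_sng <- function(expr) node("sng", expr = expr)

#' @rdname nrc-ast
#' @param var bound variable name; `source` a bag-typed expression; `body` a
#'   bag-typed expression evaluated once per source element (bag union of the
#'   results).
#' @export
nrc_for <- function(var, source, body)
  node("for", var = var, source = source, body = body)

#' @rdname nrc-ast
#' @param cond boolean expression; `then` a bag expression. A false condition
#'   contributes the empty bag (conditionals are only allowed in bag
#'   positions).
#' @export
nrc_if <- function(cond, then) node("if", cond = cond, then = then)

#' @rdname nrc-ast
#' @param op comparison (`==`, `!=`, `<`, `<=`, `>`, `>=`), boolean
#'   (`&&`, `||`) or arithmetic (`+`, `-`, `*`, `/`) operator.
#' @param lhs,rhs operand expressions.
#' @export
nrc_cmp <- function(op, lhs, rhs) {
  op <- match.arg(op, c("==", "!=", "<", "<=", ">", ">="))
  node("cmp", op = op, lhs = lhs, rhs = rhs)
}

#' @rdname nrc-ast
#' @export
nrc_bool <- function(op, lhs, rhs) {
  op <- match.arg(op, c("&&", "||"))
  node("bool", op = op, lhs = lhs, rhs = rhs)
}

#' @rdname nrc-ast
#' @export
nrc_arith <- function(op, lhs, rhs) {
  op <- match.arg(op, c("+", "-", "*", "/"))
  node("arith", op = op, lhs = lhs, rhs = rhs)
}

#' @rdname nrc-ast
#' @export
nrc_dedup <- function(expr) node("dedup", expr = expr)

#' @rdname nrc-ast
#' @param keys character vector of key attributes.
#' @param group_attr name of the output attribute holding each group's bag.
#' @export
nrc_groupby <- function(keys, group_attr, expr)
  node("groupby", keys = keys, group_attr = group_attr, expr = expr)

#' @rdname nrc-ast
#' @param values character vector of summed attributes. The input expression
#'   must be flat (no bag-typed attributes).
#' @export
nrc_sumby <- function(keys, values, expr)
  node("sumby", keys = keys, values = values, expr = expr)

#' @rdname nrc-ast
#' @param value scalar constant; `kind` its scalar kind (inferred when
#'   missing).
#' @export
nrc_const <- function(value, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (is.character(value)) "string"
            else if (is.logical(value)) "bool"
            else if (is.numeric(value) && value == round(value) &&
                     is.integer(value)) "int"
            else "real"
  }
  node("const", value = value, ckind = kind)
}

#' @rdname nrc-ast
#' @export
nrc_union <- function(lhs, rhs) node("union", lhs = lhs, rhs = rhs)

# ---- shredded-program-only nodes ------------------------------------------

#' @rdname nrc-ast
#' @param level label level identifier.
#' @param bindings named list of scalar expressions: the minimal context the
#'   label carries downstream.
#' @export
nrc_new_label <- function(level, bindings)
  node("newlabel", level = level, bindings = bindings)

#' @rdname nrc-ast
#' @export
nrc_label_domain <- function(level) node("labeldomain", level = level)

# ---- programs --------------------------------------------------------------

#' Programs: ordered named assignments
#'
#' A program is an ordered list of `name := expr` assignments; later
#' assignments may reference earlier names as materialized inputs. Names must
#' be unique and references must not precede definitions (enforced by
#' [typecheck()]).
#'
#' @param assignments list of `list(name =, expr =)` entries.
#' @export
nrc_program <- function(assignments) {
  nms <- vapply(assignments, function(a) a$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate assignment names", call. = FALSE)
  structure(list(assignments = assignments), class = "nrc_program")
}

#' @export
print.nrc_program <- function(x, ...) {
  cat(nrc_print(x))
  invisible(x)
}

program_names <- function(p) vapply(p$assignments, `[[`, character(1), "name")

# ---- AST utilities ---------------------------------------------------------

# free variables of an expression (variables not bound by an enclosing `for`)
free_vars <- function(e, bound = character(0)) {
  switch(e$kind,
    input = , const = , labeldomain = character(0),
    var = if (e$name %in% bound) character(0) else e$name,
    project = free_vars(e$expr, bound),
    tuple = unique(unlist(lapply(e$fields, free_vars, bound = bound))),
    sng = , dedup = , groupby = , sumby = free_vars(e$expr, bound),
    "for" = unique(c(free_vars(e$source, bound),
                     free_vars(e$body, c(bound, e$var)))),
    "if" = unique(c(free_vars(e$cond, bound), free_vars(e$then, bound))),
    cmp = , bool = , arith = , union = unique(c(
      free_vars(e$lhs, bound), free_vars(e$rhs, bound))),
    newlabel = unique(unlist(lapply(e$bindings, free_vars, bound = bound))),
    stop("unknown node kind: ", e$kind)
  ) %||% character(0)
}

# input names referenced anywhere in an expression
input_refs <- function(e) {
  acc <- character(0)
  walk <- function(e) {
    if (!inherits(e, "nrc_expr")) return(invisible())
    if (e$kind == "input") acc <<- c(acc, e$name)
    for (f in e[setdiff(names(e), "kind")]) {
      if (inherits(f, "nrc_expr")) walk(f)
      else if (is.list(f)) for (g in f) if (inherits(g, "nrc_expr")) walk(g)
    }
  }
  walk(e)
  unique(acc)
}

# projections rooted at a given variable, e.g. var "s" -> c("sid", "tumorsite")
var_projections <- function(e, var) {
  acc <- character(0)
  walk <- function(e) {
    if (!inherits(e, "nrc_expr")) return(invisible())
    if (e$kind == "project" && e$expr$kind == "var" && e$expr$name == var) {
      acc <<- c(acc, e$attr)
      return(invisible())
    }
    for (f in e[setdiff(names(e), "kind")]) {
      if (inherits(f, "nrc_expr")) walk(f)
      else if (is.list(f)) for (g in f) if (inherits(g, "nrc_expr")) walk(g)
    }
  }
  walk(e)
  unique(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
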