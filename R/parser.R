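#' Surface syntax
#'
#' A concrete textual syntax for programs, mirroring the comprehension style
#' of the language:
#'
#' ```
#' OccurrProj := for o in Occurrences union
#'   { sid := o.sid,
#'     candidates := for c in o.candidates union
#'       { gene := c.gene, impact := c.impact } }
#' ```
#'
#' Grammar sketch (see `inst/GRAMMAR.md` for the full EBNF):
#' * `name := expr` top-level assignment;
#' * `for v in e union e` comprehension; `if (pred) then e` conditional
#'   (bag positions only); `e ++ e` bag union;
#' * `{ a := e, ... }` tuple constructor (a singleton bag where a bag is
#'   expected);
#' * `dedup(e)`, `groupBy[k1, k2 -> attr](e)`, `sumBy[k1; v1](e)`;
#' * predicates with `== != < <= > >=`, `&&`, `||`; arithmetic `+ - * /`;
#' * paths `v.attr`, string literals in double quotes, numbers (`2` is an
#'   int, `2.0` a real), `true`/`false`.
#'
#' `mklabel("level", a := e, ...)` and `labels("level")` occur only in
#' printed shredded component programs.
#'
#' @param text program source text.
#' @return [nrc_parse()] returns an [nrc_program()].
#' @name surface-syntax
NULL

KEYWORDS <- c("for", "in", "union", "if", "then", "dedup", "groupBy",
              "sumBy", "true", "false", "mklabel", "labels")

nrc_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  two <- c(":=", "->", "++", "==", "!=", "<=", ">=", "&&", "||")
  one <- c("(", ")", "{", "}", "[", "]", ",", ";", ".", "<", ">",
           "+", "-", "*", "/")
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L
    while (i <= nchar(s)) {
      rest <- substr(s, i, nchar(s))
      if (grepl("^\\s", rest)) { i <- i + 1L; next }
      if (grepl("^#", rest)) break  # comment to end of line
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      if (length(m)) {
        toks[[length(toks) + 1L]] <- list(
          type = if (m %in% KEYWORDS) m else "IDENT",
          value = m, line = ln, col = i)
        i <- i + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?", rest))
      if (length(m)) {
        toks[[length(toks) + 1L]] <- list(type = "NUMBER", value = m,
                                          line = ln, col = i)
        i <- i + nchar(m); next
      }
      if (substr(rest, 1, 1) == '"') {
        m <- regmatches(rest, regexpr('^"[^"]*"', rest))
        if (!length(m))
          stop(sprintf("unterminated string at line %d, col %d", ln, i),
               call. = FALSE)
        toks[[length(toks) + 1L]] <- list(
          type = "STRING", value = substr(m, 2, nchar(m) - 1),
          line = ln, col = i)
        i <- i + nchar(m); next
      }
      hit <- two[startsWith(rest, two)]
      if (length(hit)) {
        toks[[length(toks) + 1L]] <- list(type = hit[1], value = hit[1],
                                          line = ln, col = i)
        i <- i + 2L; next
      }
      hit <- one[startsWith(rest, one)]
      if (length(hit)) {
        toks[[length(toks) + 1L]] <- list(type = hit[1], value = hit[1],
                                          line = ln, col = i)
        i <- i + 1L; next
      }
      stop(sprintf("unexpected character '%s' at line %d, col %d",
                   substr(rest, 1, 1), ln, i), call. = FALSE)
    }
  }
  toks
}

# parser state: token list + cursor + stack of bound comprehension variables
new_pstate <- function(toks) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks; e$pos <- 1L; e$bound <- character(0)
  e
}

peek <- function(ps, k = 0L) {
  if (ps$pos + k > length(ps$toks)) return(list(type = "EOF", value = "",
                                                line = -1L, col = -1L))
  ps$toks[[ps$pos + k]]
}

advance <- function(ps) { t <- peek(ps); ps$pos <- ps$pos + 1L; t }

expect <- function(ps, type) {
  t <- peek(ps)
  if (t$type != type)
    stop(sprintf("syntax error at line %d, col %d: expected '%s', found '%s'",
                 t$line, t$col, type, t$value), call. = FALSE)
  advance(ps)
}

#' @rdname surface-syntax
#' @export
nrc_parse <- function(text) {
  ps <- new_pstate(nrc_tokenize(text))
  assignments <- list()
  while (peek(ps)$type != "EOF") {
    name <- expect(ps, "IDENT")$value
    expect(ps, ":=")
    expr <- parse_bag(ps)
    assignments[[length(assignments) + 1L]] <- list(name = name, expr = expr)
  }
  if (!length(assignments)) stop("empty program", call. = FALSE)
  nrc_program(assignments)
}

# parse an expression in bag position; a bare tuple is wrapped as a singleton
parse_bag <- function(ps) {
  e <- parse_expr(ps)
  if (e$kind == "tuple") nrc_sng(e) else e
}

# bag position that does not consume `++`: comprehension bodies and
# conditional branches bind tighter than bag union, so
# `for x in X union { t } ++ e` unions the whole comprehension with e
parse_bag_nounion <- function(ps) {
  e <- parse_nonunion(ps)
  if (e$kind == "tuple") nrc_sng(e) else e
}

parse_expr <- function(ps) {
  e <- parse_nonunion(ps)
  while (peek(ps)$type == "++") {
    advance(ps)
    lhs <- if (e$kind == "tuple") nrc_sng(e) else e
    r <- parse_nonunion(ps)
    if (r$kind == "tuple") r <- nrc_sng(r)
    e <- nrc_union(lhs, r)
  }
  e
}

parse_nonunion <- function(ps) {
  t <- peek(ps)
  switch(t$type,
    "for" = {
      advance(ps)
      var <- expect(ps, "IDENT")$value
      expect(ps, "in")
      src <- parse_primary(ps)
      expect(ps, "union")
      ps$bound <- c(ps$bound, var)
      body <- parse_bag_nounion(ps)
      ps$bound <- setdiff(ps$bound, var)
      nrc_for(var, src, body)
    },
    "if" = {
      advance(ps)
      expect(ps, "(")
      cond <- parse_pred(ps)
      expect(ps, ")")
      expect(ps, "then")
      nrc_if(cond, parse_bag_nounion(ps))
    },
    dedup = {
      advance(ps); expect(ps, "(")
      e <- parse_bag(ps); expect(ps, ")")
      nrc_dedup(e)
    },
    groupBy = {
      advance(ps); expect(ps, "[")
      keys <- parse_name_list(ps)
      expect(ps, "->")
      gattr <- expect(ps, "IDENT")$value
      expect(ps, "]"); expect(ps, "(")
      e <- parse_bag(ps); expect(ps, ")")
      nrc_groupby(keys, gattr, e)
    },
    sumBy = {
      advance(ps); expect(ps, "[")
      keys <- parse_name_list(ps)
      expect(ps, ";")
      vals <- parse_name_list(ps)
      expect(ps, "]"); expect(ps, "(")
      e <- parse_bag(ps); expect(ps, ")")
      nrc_sumby(keys, vals, e)
    },
    "{" = parse_tuple(ps),
    labels = {
      advance(ps); expect(ps, "(")
      lev <- expect(ps, "STRING")$value
      expect(ps, ")")
      nrc_label_domain(lev)
    },
    parse_arith(ps)
  )
}

parse_tuple <- function(ps) {
  expect(ps, "{")
  fields <- list()
  if (peek(ps)$type != "}") {
    repeat {
      fname <- expect(ps, "IDENT")$value
      expect(ps, ":=")
      fields[[fname]] <- parse_expr(ps)
      if (peek(ps)$type != ",") break
      advance(ps)
    }
  }
  expect(ps, "}")
  nrc_tuple(fields)
}

parse_name_list <- function(ps) {
  out <- expect(ps, "IDENT")$value
  while (peek(ps)$type == ",") {
    advance(ps)
    out <- c(out, expect(ps, "IDENT")$value)
  }
  out
}

parse_pred <- function(ps) {
  e <- parse_pred_and(ps)
  while (peek(ps)$type == "||") {
    advance(ps)
    e <- nrc_bool("||", e, parse_pred_and(ps))
  }
  e
}

parse_pred_and <- function(ps) {
  e <- parse_pred_atom(ps)
  while (peek(ps)$type == "&&") {
    advance(ps)
    e <- nrc_bool("&&", e, parse_pred_atom(ps))
  }
  e
}

parse_pred_atom <- function(ps) {
  if (peek(ps)$type == "(") {
    # lookahead: parenthesized predicate vs parenthesized arithmetic operand
    save <- ps$pos
    advance(ps)
    inner <- try(parse_pred(ps), silent = TRUE)
    if (!inherits(inner, "try-error") && peek(ps)$type == ")" &&
        inner$kind %in% c("cmp", "bool")) {
      advance(ps)
      return(inner)
    }
    ps$pos <- save
  }
  lhs <- parse_arith(ps)
  t <- peek(ps)
  if (t$type %in% c("==", "!=", "<", "<=", ">", ">=")) {
    advance(ps)
    return(nrc_cmp(t$type, lhs, parse_arith(ps)))
  }
  lhs  # bare boolean expression
}

parse_arith <- function(ps) {
  e <- parse_term(ps)
  while (peek(ps)$type %in% c("+", "-")) {
    op <- advance(ps)$type
    e <- nrc_arith(op, e, parse_term(ps))
  }
  e
}

parse_term <- function(ps) {
  e <- parse_factor(ps)
  while (peek(ps)$type %in% c("*", "/")) {
    op <- advance(ps)$type
    e <- nrc_arith(op, e, parse_factor(ps))
  }
  e
}

parse_factor <- function(ps) {
  t <- peek(ps)
  switch(t$type,
    NUMBER = {
      advance(ps)
      if (grepl(".", t$value, fixed = TRUE))
        nrc_const(as.numeric(t$value), "real")
      else nrc_const(as.integer(t$value), "int")
    },
    STRING = { advance(ps); nrc_const(t$value, "string") },
    true = { advance(ps); nrc_const(TRUE, "bool") },
    false = { advance(ps); nrc_const(FALSE, "bool") },
    mklabel = {
      advance(ps); expect(ps, "(")
      lev <- expect(ps, "STRING")$value
      bindings <- list()
      while (peek(ps)$type == ",") {
        advance(ps)
        bn <- expect(ps, "IDENT")$value
        expect(ps, ":=")
        bindings[[bn]] <- parse_arith(ps)
      }
      expect(ps, ")")
      nrc_new_label(lev, bindings)
    },
    "(" = {
      advance(ps)
      e <- parse_arith(ps)
      expect(ps, ")")
      e
    },
    parse_primary(ps)
  )
}

# identifier with optional projection chain; resolves to var or input
parse_primary <- function(ps) {
  t <- peek(ps)
  if (t$type != "IDENT")
    stop(sprintf("syntax error at line %d, col %d: unexpected '%s'",
                 t$line, t$col, t$value), call. = FALSE)
  advance(ps)
  e <- if (t$value %in% ps$bound) nrc_var(t$value) else nrc_input(t$value)
  while (peek(ps)$type == ".") {
    advance(ps)
    e <- nrc_project(e, expect(ps, "IDENT")$value)
  }
  e
}

# ---- pretty printer --------------------------------------------------------

#' @rdname surface-syntax
#' @param x a program or expression.
#' @export
nrc_print <- function(x) {
  if (inherits(x, "nrc_program")) {
    paste0(vapply(x$assignments, function(a)
      paste0(a$name, " := ", print_expr(a$expr, 1L), "\n"),
      character(1)), collapse = "\n")
  } else {
    print_expr(x, 0L)
  }
}

print_expr <- function(e, depth) {
  ind <- strrep("  ", depth)
  switch(e$kind,
    input = , var = e$name,
    project = paste0(print_expr(e$expr, depth), ".", e$attr),
    const = {
      if (e$ckind == "string") paste0('"', e$value, '"')
      else if (e$ckind == "bool") if (e$value) "true" else "false"
      else if (e$ckind == "int") sprintf("%d", as.integer(e$value))
      else {
        s <- sprintf("%g", e$value)
        if (!grepl("[.e]", s)) s <- paste0(s, ".0")
        s
      }
    },
    tuple = {
      if (!length(e$fields)) return("{ }")
      inner <- vapply(names(e$fields), function(f)
        paste0(f, " := ", print_expr(e$fields[[f]], depth + 1L)),
        character(1))
      paste0("{ ", paste(inner, collapse = paste0(",\n", ind, "  ")), " }")
    },
    sng = print_expr(e$expr, depth),
    "for" = paste0("for ", e$var, " in ", print_expr(e$source, depth),
                   " union\n", ind, "  ", print_expr(e$body, depth + 1L)),
    "if" = paste0("if (", print_expr(e$cond, depth), ") then\n", ind, "  ",
                  print_expr(e$then, depth + 1L)),
    cmp = paste0(print_operand(e$lhs, depth), " ", e$op, " ",
                 print_operand(e$rhs, depth)),
    bool = paste0(print_operand(e$lhs, depth), " ", e$op, " ",
                  print_operand(e$rhs, depth)),
    arith = paste0(print_operand(e$lhs, depth), " ", e$op, " ",
                   print_operand(e$rhs, depth)),
    dedup = paste0("dedup(", print_expr(e$expr, depth), ")"),
    groupby = paste0("groupBy[", paste(e$keys, collapse = ", "), " -> ",
                     e$group_attr, "](\n", ind, "  ",
                     print_expr(e$expr, depth + 1L), " )"),
    sumby = paste0("sumBy[", paste(e$keys, collapse = ", "), "; ",
                   paste(e$values, collapse = ", "), "](\n", ind, "  ",
                   print_expr(e$expr, depth + 1L), " )"),
    union = paste0(print_expr(e$lhs, depth), "\n", ind, "++ ",
                   print_expr(e$rhs, depth)),
    newlabel = paste0('mklabel("', e$level, '"',
                      if (length(e$bindings))
                        paste0(", ", paste(vapply(names(e$bindings),
                          function(b) paste0(b, " := ",
                                             print_expr(e$bindings[[b]], depth)),
                          character(1)), collapse = ", "))
                      else "", ")"),
    labeldomain = paste0('labels("', e$level, '")'),
    stop("cannot print node kind: ", e$kind)
  )
}

# parenthesize nested binary operands so printed text reparses to the same AST
print_operand <- function(e, depth) {
  s <- print_expr(e, depth)
  if (e$kind %in% c("cmp", "bool", "arith")) paste0("(", s, ")") else s
}
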