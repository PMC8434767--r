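#' Reference interpreter
#'
#' Nested, in-memory, non-distributed evaluation of a program: the semantic
#' oracle against which both compilation routes are checked. Comprehensions
#' iterate multisets (bag union of the body's results); a false or unknown
#' condition contributes the empty bag; `dedup` removes duplicates by deep
#' structural equality; `groupBy`/`sumBy` group on exact key equality. Null
#' (`NA`) operands propagate through arithmetic and are excluded from `sumBy`
#' sums; division by zero is an error.
#'
#' Comprehensions whose source is a named input are memoized on the values of
#' their free variables; this is a pure caching layer (bags are values) and
#' does not change semantics.
#'
#' @param program an [nrc_program()].
#' @param inputs named list of bag values.
#' @return named list of bag values, one per assignment.
#' @export
eval_reference <- function(program, inputs) {
  stopifnot(inherits(program, "nrc_program"))
  known <- inputs
  for (a in program$assignments) {
    known[[a$name]] <- eval_nrc(a$expr, env = list(), inputs = known)
  }
  known[program_names(program)]
}

#' Evaluate a single expression
#'
#' @param expr an expression AST.
#' @param env named list of variable bindings.
#' @param inputs named list of input bag values.
#' @param labels optional environment collecting labels created by
#'   `nrc_new_label` nodes (used by the shredded evaluator).
#' @keywords internal
#' @export
eval_nrc <- function(expr, env, inputs, labels = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$inputs <- inputs
  ctx$labels <- labels
  ctx$memo <- new.env(hash = TRUE, parent = emptyenv())
  ctx$fv <- new.env(hash = TRUE, parent = emptyenv())
  ctx$index <- new.env(hash = TRUE, parent = emptyenv())
  expr <- annotate_uids(expr)
  ev(expr, env, ctx)
}

annotate_uids <- function(e) {
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  walk <- function(e) {
    if (!inherits(e, "nrc_expr")) return(e)
    counter$n <- counter$n + 1L
    e$uid <- counter$n
    for (f in setdiff(names(e), c("kind", "uid"))) {
      if (inherits(e[[f]], "nrc_expr")) e[[f]] <- walk(e[[f]])
      else if (is.list(e[[f]])) e[[f]] <- lapply(e[[f]], function(g)
        if (inherits(g, "nrc_expr")) walk(g) else g)
    }
    e
  }
  walk(e)
}

# decompose `for v in Input union if (cond) then rest` into equality
# conjuncts v.attr == rhs (rhs free of v) plus the residual body
split_eq_guard <- function(e) {
  v <- e$var
  conjs <- split_conjuncts(e$body$cond)
  attrs <- character(0); rhs <- list(); residual <- list()
  for (cj in conjs) {
    hit <- NULL
    if (cj$kind == "cmp" && cj$op == "==") {
      sides <- list(cj$lhs, cj$rhs)
      for (i in 1:2) {
        s <- sides[[i]]; o <- sides[[3 - i]]
        if (s$kind == "project" && s$expr$kind == "var" &&
            s$expr$name == v && !(v %in% free_vars(o))) {
          hit <- list(attr = s$attr, rhs = o)
          break
        }
      }
    }
    if (is.null(hit)) residual[[length(residual) + 1L]] <- cj
    else { attrs <- c(attrs, hit$attr); rhs[[length(rhs) + 1L]] <- hit$rhs }
  }
  if (!length(attrs)) return(NULL)
  body <- if (length(residual)) {
    cond <- Reduce(function(a, b) nrc_bool("&&", a, b), residual)
    nrc_if(cond, e$body$then)
  } else e$body$then
  list(attrs = attrs, rhs = rhs, residual = body)
}

input_index <- function(ctx, name, attrs) {
  key <- paste0(name, "\x1e", paste(attrs, collapse = ","))
  idx <- ctx$index[[key]]
  if (is.null(idx)) {
    bag <- ctx$inputs[[name]]
    if (is.null(bag)) stop("unknown input: ", name, call. = FALSE)
    idx <- new.env(hash = TRUE, parent = emptyenv())
    for (tup in bag) {
      k <- paste(vapply(attrs, function(a) canon_scalar(tup[[a]]),
                        character(1)), collapse = "\x1f")
      idx[[k]] <- c(idx[[k]], list(tup))
    }
    ctx$index[[key]] <- idx
  }
  idx
}

node_free_vars <- function(e, ctx) {
  key <- as.character(e$uid)
  fv <- ctx$fv[[key]]
  if (is.null(fv)) {
    fv <- free_vars(e)
    assign(key, fv, envir = ctx$fv)
  }
  fv
}

ev <- function(e, env, ctx) {
  switch(e$kind,
    input = {
      v <- ctx$inputs[[e$name]]
      if (is.null(v)) stop("unknown input: ", e$name, call. = FALSE)
      v
    },
    var = {
      v <- env[[e$name]]
      if (is.null(v)) stop("unbound variable: ", e$name, call. = FALSE)
      v
    },
    project = {
      tup <- ev(e$expr, env, ctx)
      if (length(tup) == 1 && !is.list(tup) && is.na(tup)) return(NA)
      v <- tup[[e$attr]]
      if (is.null(v)) stop("attribute not found: ", e$attr, call. = FALSE)
      v
    },
    tuple = lapply(e$fields, ev, env = env, ctx = ctx),
    sng = list(ev(e$expr, env, ctx)),
    "for" = {
      # fast path: an input-sourced comprehension whose body is guarded by
      # equality conjuncts on the bound variable iterates only the matching
      # tuples, via a hash index built once per (input, attribute set) —
      # multiplicities and semantics are unchanged
      if (e$source$kind == "input" && e$body$kind == "if") {
        eq <- split_eq_guard(e)
        if (!is.null(eq)) {
          idx <- input_index(ctx, e$source$name, eq$attrs)
          keyvals <- vapply(eq$rhs, function(r)
            canon_scalar(ev(r, env, ctx)), character(1))
          tuples <- idx[[paste(keyvals, collapse = "\x1f")]]
          out <- list()
          for (tup in tuples) {
            env[[e$var]] <- tup
            out <- c(out, ev(eq$residual, env, ctx))
          }
          return(out)
        }
      }
      memoize <- e$source$kind == "input"
      if (memoize) {
        fv <- node_free_vars(e, ctx)
        key <- paste0(e$uid, "|", paste(
          vapply(fv, function(v) canon_value(env[[v]]), character(1)),
          collapse = ";"))
        hit <- ctx$memo[[key]]
        if (!is.null(hit)) return(hit$v)
      }
      src <- ev(e$source, env, ctx)
      out <- list()
      for (tup in src) {
        env[[e$var]] <- tup
        out <- c(out, ev(e$body, env, ctx))
      }
      if (memoize) assign(key, list(v = out), envir = ctx$memo)
      out
    },
    "if" = {
      c_ <- ev(e$cond, env, ctx)
      if (isTRUE(c_)) ev(e$then, env, ctx) else list()
    },
    cmp = {
      l <- ev(e$lhs, env, ctx); r <- ev(e$rhs, env, ctx)
      if (is_label_value(l) || is_label_value(r)) {
        eq <- identical(label_key(l), label_key(r))
        return(if (e$op == "==") eq else !eq)
      }
      if (is.na(l) || is.na(r)) return(NA)
      switch(e$op, "==" = l == r, "!=" = l != r, "<" = l < r,
             "<=" = l <= r, ">" = l > r, ">=" = l >= r)
    },
    bool = {
      l <- ev(e$lhs, env, ctx)
      if (e$op == "&&") {
        if (isFALSE(l)) return(FALSE)
        r <- ev(e$rhs, env, ctx)
        if (isFALSE(r)) return(FALSE)
        if (is.na(l) || is.na(r)) return(NA)
        TRUE
      } else {
        if (isTRUE(l)) return(TRUE)
        r <- ev(e$rhs, env, ctx)
        if (isTRUE(r)) return(TRUE)
        if (is.na(l) || is.na(r)) return(NA)
        FALSE
      }
    },
    arith = {
      l <- ev(e$lhs, env, ctx); r <- ev(e$rhs, env, ctx)
      if (is.na(l) || is.na(r)) return(NA)
      if (e$op == "/" && r == 0) stop("division by zero", call. = FALSE)
      switch(e$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r)
    },
    dedup = {
      bag <- ev(e$expr, env, ctx)
      keys <- vapply(bag, canon_value, character(1))
      bag[!duplicated(keys)]
    },
    groupby = {
      bag <- ev(e$expr, env, ctx)
      rest <- if (length(bag)) setdiff(names(bag[[1]]), e$keys) else character(0)
      gk <- vapply(bag, function(tup)
        canon_value(tup[e$keys]), character(1))
      out <- list()
      for (k in unique(gk)) {
        members <- bag[gk == k]
        tup <- members[[1]][e$keys]
        tup[[e$group_attr]] <- lapply(members, function(m) m[rest])
        out <- c(out, list(tup))
      }
      out
    },
    sumby = {
      bag <- ev(e$expr, env, ctx)
      gk <- vapply(bag, function(tup) canon_value(tup[e$keys]), character(1))
      out <- list()
      for (k in unique(gk)) {
        members <- bag[gk == k]
        tup <- members[[1]][e$keys]
        for (v in e$values) {
          vals <- vapply(members, function(m) as.numeric(m[[v]]), numeric(1))
          tup[[v]] <- sum(vals, na.rm = TRUE)
        }
        out <- c(out, list(tup))
      }
      out
    },
    const = e$value,
    union = c(ev(e$lhs, env, ctx), ev(e$rhs, env, ctx)),
    newlabel = {
      bindings <- lapply(e$bindings, ev, env = env, ctx = ctx)
      k <- label_key(label_value(e$level, bindings))
      if (!is.null(ctx$labels)) {
        lev <- as.character(e$level)
        cur <- ctx$labels[[lev]] %||% list()
        if (is.null(cur[[k]])) { cur[[k]] <- bindings; ctx$labels[[lev]] <- cur }
      }
      k
    },
    labeldomain = {
      v <- ctx$inputs[[paste0(".labels.", e$level)]]
      if (is.null(v))
        stop("no label domain for level ", e$level, call. = FALSE)
      v
    },
    stop("unknown node kind: ", e$kind)
  )
}
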