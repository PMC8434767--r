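#' Standard (flattening) compilation
#'
#' Compiles a program to a flat dataflow plan by unnesting. Starting from the
#' outermost level, every comprehension level becomes a stream of flat rows:
#' generators over inputs become scans and equi-joins (equality conjuncts
#' between a new generator and already-bound variables are used as join
#' keys), generators over nested attributes become outer-flattens with
#' NULL-padded rows for empty bags, and residual predicates become selects.
#' Each level is indexed with dense unique ids ([p_addid()]/flatten ids); the
#' maintained id prefix of every level is recorded on the plan's `group` and
#' `attach` operators, which re-nest child rows onto their parents — a
#' left-outer reattachment, so parents whose children all vanish (empty bags,
#' failed predicates) regroup to empty bags rather than disappearing.
#'
#' With `naive = TRUE` the compiler emits the lossy diagnostic variant:
#' inner flatten (no NULL padding) and inner reattachment, which reproduces
#' the classic flattening defect — parents with empty inner collections are
#' lost from the output.
#'
#' @param program an [nrc_program()].
#' @param input_schemas named list of input bag types.
#' @param naive emit the lossy inner-flatten diagnostic variant.
#' @return an `nrc_compiled` object: per-assignment plans plus input/output
#'   schemas.
#' @export
compile_standard <- function(program, input_schemas, naive = FALSE) {
  out_types <- typecheck(program, input_schemas)
  known <- input_schemas
  cs <- new.env(parent = emptyenv())
  cs$counter <- 0L
  plans <- list()
  for (a in program$assignments) {
    plans[[a$name]] <- compile_assignment(a$expr, known, cs, naive)
    known[[a$name]] <- out_types[[a$name]]
  }
  structure(list(plans = plans, input_schemas = input_schemas,
                 out_types = out_types, naive = naive),
            class = "nrc_compiled")
}

#' @export
print.nrc_compiled <- function(x, ...) {
  for (nm in names(x$plans)) {
    cat("== ", nm, " ==\n", sep = "")
    print(x$plans[[nm]]$plan)
  }
  invisible(x)
}

fresh <- function(cs, stem) {
  cs$counter <- cs$counter + 1L
  paste0(stem, "_", cs$counter)
}

with_cols <- function(p, cols) { p$out_cols <- cols; p }

compile_assignment <- function(expr, schemas, cs, naive) {
  ctx <- list(plan = NULL, vars = list(), types = list(),
              rowids = character(0), schemas = schemas, naive = naive)
  st <- c_stream(expr, ctx, cs)
  plan <- st$plan
  if (length(st$validcols)) {
    pred <- Reduce(function(acc, vc) {
      e <- cx_notnull(cx_col(vc))
      if (is.null(acc)) e else cx_bin("bool", "&&", acc, e)
    }, st$validcols, init = NULL)
    plan <- with_cols(p_select(plan, pred), plan$out_cols)
  }
  exprs <- lapply(st$cols, cx_col)
  plan <- with_cols(p_project(plan, exprs), names(st$cols))
  plan <- plan_index(plan)
  list(plan = plan, fields = names(st$cols))
}

# compile a bag expression into a stream of flat rows within a context.
# Returns list(plan, cols = field -> column, rowids, validcols).
c_stream <- function(E, ctx, cs) {
  switch(E$kind,
    "for" = , "if" = c_chain(E, ctx, cs),
    sng = c_chain(E, ctx, cs),
    sumby = {
      inner <- c_stream(E$expr, ctx, cs)
      keycols <- unlist(E$keys |> lapply(function(k) inner$cols[[k]]))
      outcols <- vapply(E$values, function(v) fresh(cs, paste0("agg_", v)),
                        character(1))
      valuecols <- vapply(E$values, function(v) inner$cols[[v]], character(1))
      plan <- p_sumby(inner$plan, prefix = ctx$rowids, keys = keycols,
                      values = valuecols, out = outcols)
      plan <- with_cols(plan, c(ctx$rowids, keycols, outcols))
      cols <- c(stats::setNames(as.list(keycols), E$keys),
                stats::setNames(as.list(outcols), E$values))
      list(plan = plan, cols = cols, rowids = ctx$rowids,
           validcols = character(0))
    },
    groupby = {
      inner <- c_stream(E$expr, ctx, cs)
      plan <- drop_invalid(inner, cs)
      keycols <- vapply(E$keys, function(k) inner$cols[[k]], character(1))
      rest <- setdiff(names(inner$cols), E$keys)
      bagcol <- fresh(cs, paste0("bag_", E$group_attr))
      prefix <- c(ctx$rowids, keycols)
      plan <- p_group(plan, prefix = prefix,
                      payload = inner$cols[rest], out_col = bagcol,
                      valid_cols = character(0))
      plan <- with_cols(plan, c(prefix, bagcol))
      cols <- c(stats::setNames(as.list(keycols), E$keys),
                stats::setNames(list(bagcol), E$group_attr))
      list(plan = plan, cols = cols, rowids = ctx$rowids,
           validcols = character(0))
    },
    dedup = {
      inner <- c_stream(E$expr, ctx, cs)
      plan <- drop_invalid(inner, cs)
      keep <- c(ctx$rowids, unlist(inner$cols))
      plan <- with_cols(p_project(plan, stats::setNames(
        lapply(keep, cx_col), keep)), keep)
      plan <- with_cols(p_distinct(plan, keep), keep)
      list(plan = plan, cols = inner$cols, rowids = ctx$rowids,
           validcols = character(0))
    },
    union = {
      a <- c_stream(E$lhs, ctx, cs)
      b <- c_stream(E$rhs, ctx, cs)
      flds <- names(a$cols)
      common <- vapply(flds, function(f) fresh(cs, paste0("u_", f)),
                       character(1))
      align <- function(st) {
        plan <- drop_invalid(st, cs)
        keep <- stats::setNames(
          lapply(c(ctx$rowids, unlist(st$cols[flds])), cx_col),
          c(ctx$rowids, common))
        with_cols(p_project(plan, keep), c(ctx$rowids, common))
      }
      plan <- with_cols(p_union(align(a), align(b)), c(ctx$rowids, common))
      list(plan = plan, cols = stats::setNames(as.list(common), flds),
           rowids = ctx$rowids, validcols = character(0))
    },
    input = , labeldomain = {
      name <- if (E$kind == "input") E$name else paste0(".labels.", E$level)
      t <- ctx$schemas[[name]]
      if (is.null(t)) stop("unknown input: ", name, call. = FALSE)
      v <- fresh(cs, "x")
      st <- scan_input(name, t, v, cs)
      list(plan = st$plan,
           cols = stats::setNames(as.list(unlist(st$colmap)),
                                  names(st$colmap)),
           rowids = c(ctx$rowids, st$id), validcols = character(0))
    },
    stop("expression not compilable as a stream: ", E$kind)
  )
}

drop_invalid <- function(st, cs) {
  if (!length(st$validcols)) return(st$plan)
  pred <- Reduce(function(acc, vc) {
    e <- cx_notnull(cx_col(vc))
    if (is.null(acc)) e else cx_bin("bool", "&&", acc, e)
  }, st$validcols, init = NULL)
  with_cols(p_select(st$plan, pred), st$plan$out_cols)
}

scan_input <- function(name, t, v, cs) {
  flds <- t$elem$fields
  colmap <- stats::setNames(
    lapply(names(flds), function(f) fresh(cs, paste0(v, "_", f))),
    names(flds))
  scan <- with_cols(p_scan(name), names(flds))
  proj <- with_cols(p_project(scan, stats::setNames(
    lapply(names(flds), cx_col), unlist(colmap))), unlist(colmap))
  id <- fresh(cs, paste0(v, "_id"))
  plan <- with_cols(p_addid(proj, id), c(unlist(colmap), id))
  list(plan = plan, colmap = colmap, id = id, fields = flds)
}

split_conjuncts <- function(pred) {
  if (pred$kind == "bool" && pred$op == "&&")
    c(split_conjuncts(pred$lhs), split_conjuncts(pred$rhs))
  else list(pred)
}

is_simple_proj <- function(e) e$kind == "project" && e$expr$kind == "var"

c_chain <- function(E, ctx, cs) {
  gens <- list()
  filters <- list()
  cur <- E
  repeat {
    if (cur$kind == "for") {
      gens[[length(gens) + 1L]] <- list(var = cur$var, src = cur$source,
                                        after = length(gens))
      cur <- cur$body
    } else if (cur$kind == "if") {
      for (cj in split_conjuncts(cur$cond))
        filters[[length(filters) + 1L]] <- list(pred = cj, placed = FALSE)
      cur <- cur$then
    } else break
  }
  head <- cur

  plan <- ctx$plan
  vars <- ctx$vars
  types <- ctx$types
  bound <- names(vars)
  localids <- character(0)
  validcols <- character(0)

  place_filters <- function() {
    for (i in seq_along(filters)) {
      f <- filters[[i]]
      if (f$placed) next
      if (all(free_vars(f$pred) %in% bound)) {
        pred <- ast_to_colexpr(f$pred, lapply(vars, unlist))
        plan <<- with_cols(p_select(plan, pred), plan$out_cols)
        filters[[i]]$placed <<- TRUE
      }
    }
  }

  for (g in gens) {
    v <- g$var
    src <- g$src
    if (src$kind %in% c("input", "labeldomain")) {
      name <- if (src$kind == "input") src$name
              else paste0(".labels.", src$level)
      t <- ctx$schemas[[name]]
      if (is.null(t)) stop("unknown input: ", name, call. = FALSE)
      sc <- scan_input(name, t, v, cs)
      if (is.null(plan)) {
        plan <- sc$plan
      } else {
        # extract equi-join keys linking the new generator to bound columns
        lk <- character(0); rk <- character(0)
        for (i in seq_along(filters)) {
          f <- filters[[i]]
          if (f$placed || f$pred$kind != "cmp" || f$pred$op != "==") next
          sides <- list(f$pred$lhs, f$pred$rhs)
          if (!all(vapply(sides, is_simple_proj, logical(1)))) next
          sv <- vapply(sides, function(s) s$expr$name, character(1))
          sa <- vapply(sides, function(s) s$attr, character(1))
          new_side <- which(sv == v)
          old_side <- which(sv %in% bound)
          if (length(new_side) == 1 && length(old_side) == 1 &&
              new_side != old_side) {
            lk <- c(lk, vars[[sv[old_side]]][[sa[old_side]]])
            rk <- c(rk, sc$colmap[[sa[new_side]]])
            filters[[i]]$placed <- TRUE
          }
        }
        jn <- p_join(plan, sc$plan, left_keys = lk, right_keys = rk,
                     kind = "inner")
        plan <- with_cols(jn, c(plan$out_cols, sc$plan$out_cols))
      }
      vars[[v]] <- sc$colmap
      types[[v]] <- t$elem
      localids <- c(localids, sc$id)
    } else if (src$kind == "project" && src$expr$kind == "var") {
      pv <- src$expr$name
      bt <- types[[pv]]$fields[[src$attr]]
      if (is.null(bt) || !is_bag_type(bt))
        stop("iteration over non-bag attribute ", pv, ".", src$attr,
             call. = FALSE)
      if (is.null(plan))
        stop("nested iteration without an enclosing stream", call. = FALSE)
      flds <- bt$elem$fields
      colmap <- stats::setNames(
        lapply(names(flds), function(f) fresh(cs, paste0(v, "_", f))),
        names(flds))
      fields <- stats::setNames(lapply(names(flds), function(f)
        list(col = colmap[[f]], type = flds[[f]])), names(flds))
      idc <- fresh(cs, paste0(v, "_id"))
      fl <- p_flatten(plan, bag_col = vars[[pv]][[src$attr]], var = v,
                      fields = fields, id_col = idc, outer = !ctx$naive)
      plan <- with_cols(fl, c(setdiff(plan$out_cols,
                                      vars[[pv]][[src$attr]]),
                              unlist(colmap), idc))
      vars[[v]] <- colmap
      types[[v]] <- bt$elem
      localids <- c(localids, idc)
      validcols <- c(validcols, idc)
    } else {
      stop("unsupported generator source: ", src$kind, call. = FALSE)
    }
    bound <- names(vars)
    place_filters()
  }
  place_filters()
  unplaced <- Filter(function(f) !f$placed, filters)
  if (length(unplaced))
    stop("predicate references unbound variables", call. = FALSE)

  ctx2 <- ctx
  ctx2$plan <- plan
  ctx2$vars <- vars
  ctx2$types <- types
  ctx2$rowids <- c(ctx$rowids, localids)

  if (head$kind == "sng" && head$expr$kind == "tuple") {
    c_tuple_head(head$expr, ctx2, cs, validcols)
  } else {
    st <- c_stream(head, ctx2, cs)
    st$validcols <- unique(c(validcols, st$validcols))
    st
  }
}

c_tuple_head <- function(tup, ctx, cs, validcols) {
  plan <- ctx$plan
  varsmap <- lapply(ctx$vars, unlist)
  scalar_exprs <- list()
  bag_cols <- list()
  env_types <- ctx$types
  for (f in names(tup$fields)) {
    ef <- tup$fields[[f]]
    ft <- type_of(ef, env = env_types, schemas = ctx$schemas)
    if (is_bag_type(ft)) {
      if (ef$kind == "project" && ef$expr$kind == "var") {
        # whole-bag copy: pass the list column through unchanged
        bag_cols[[f]] <- varsmap[[ef$expr$name]][[ef$attr]]
      } else {
        bst <- c_stream(ef, ctx, cs)
        gplan <- bst$plan
        bagcol <- fresh(cs, paste0("bag_", f))
        grouped <- p_group(gplan, prefix = ctx$rowids,
                           payload = bst$cols, out_col = bagcol,
                           valid_cols = bst$validcols)
        grouped <- with_cols(grouped, c(ctx$rowids, bagcol))
        at <- p_attach(plan, grouped, by = ctx$rowids, bag_col = bagcol,
                       inner = ctx$naive)
        plan <- with_cols(at, c(plan$out_cols, bagcol))
        bag_cols[[f]] <- bagcol
      }
    } else {
      col <- fresh(cs, paste0("e_", f))
      scalar_exprs[[col]] <- ast_to_colexpr(ef, varsmap)
      bag_cols[[f]] <- col
    }
  }
  if (length(scalar_exprs)) {
    keep <- stats::setNames(lapply(plan$out_cols, cx_col), plan$out_cols)
    plan <- with_cols(p_project(plan, c(keep, scalar_exprs)),
                      c(plan$out_cols, names(scalar_exprs)))
  }
  list(plan = plan, cols = bag_cols, rowids = ctx$rowids,
       validcols = validcols)
}
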