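#' Shredding: programs
#'
#' Transforms a program over nested collections into a set of flat component
#' programs linked by labels. Each output collection level becomes one flat
#' component: the top component replaces every bag-valued field with a label
#' expression carrying the minimal context bindings the child level needs
#' (the free outer-variable projections of the child expression); each child
#' component iterates the deduplicated domain of those labels and computes
#' the child rows with a `label` key column. Generators over nested input
#' attributes become label-equality joins against the input's dictionary
#' relations, so every component operates on flat relations only — programs
#' over flat input and output shred to the identity.
#'
#' The result is an ordered flat program: per level, a label-domain
#' assignment `<level>_dom` (the deduplicated labels with their context
#' bindings) and the component assignment `<level>` itself. The flat program
#' is evaluable by [eval_reference()] and compilable by [compile_standard()];
#' [eval_shredded()] and [execute_shredded()] wrap this and assemble
#' per-assignment shredded values.
#'
#' @param program an [nrc_program()].
#' @param input_schemas named list of input bag types.
#' @return an `nrc_shredded_program` with `flat_program` (the ordered flat
#'   assignments), `components` (per original assignment, the component
#'   names, one per output collection level; label domains excluded),
#'   `schemas` (flat relation schemas) and `shredded_schemas` (per nested
#'   input and per assignment, the shredded relational schema used to encode
#'   and reconstruct values).
#' @export
shred_program <- function(program, input_schemas) {
  out_types <- typecheck(program, input_schemas)
  program <- desugar_groupby(program, input_schemas)

  schemas <- list()
  shredded_schemas <- list()
  for (nm in names(input_schemas)) {
    t <- input_schemas[[nm]]
    if (is_flat_tuple(t$elem)) {
      schemas[[nm]] <- t
    } else {
      ss <- shred_type(t, nm)
      shredded_schemas[[nm]] <- ss
      for (rel in ss$relations)
        schemas[[rel$name]] <- nt_bag(nt_tuple(rel$fields))
    }
  }

  st <- new.env(parent = emptyenv())
  st$assignments <- list()
  st$schemas <- schemas
  emit <- function(name, expr) {
    st$assignments[[length(st$assignments) + 1L]] <-
      list(name = name, expr = expr)
    st$schemas[[name]] <- type_of(expr, env = list(), schemas = st$schemas)
  }

  components <- list()
  for (a in program$assignments) {
    comp <- shred_assignment(a$name, a$expr, st, emit)
    components[[a$name]] <- comp
    shredded_schemas[[a$name]] <- shred_type(out_types[[a$name]], a$name)
  }

  structure(list(flat_program = nrc_program(st$assignments),
                 components = components,
                 schemas = st$schemas,
                 input_schemas = input_schemas,
                 out_types = out_types,
                 shredded_schemas = shredded_schemas,
                 source = program),
            class = "nrc_shredded_program")
}

#' @export
print.nrc_shredded_program <- function(x, ...) {
  for (nm in names(x$components)) {
    cat("-- ", nm, ": components [",
        paste(x$components[[nm]], collapse = ", "), "]\n", sep = "")
  }
  cat(nrc_print(x$flat_program))
  invisible(x)
}

is_bag_expr <- function(e)
  e$kind %in% c("for", "sumby", "groupby", "dedup", "union", "sng")

shred_assignment <- function(name, expr, st, emit) {
  comp_names <- character(0)
  recurse <- function(expr, env, level) {
    res <- sh_rw(expr, env, level, st)
    emit(level, res$expr)
    comp_names <<- c(comp_names, level)
    for (ch in res$children) {
      dom_name <- paste0(ch$level, "_dom")
      dom_expr <- nrc_dedup(replace_head(res$expr, ch$dom_head))
      emit(dom_name, dom_expr)
      env_child <- stats::setNames(list(ch$dom_elem_type), ch$label_var)
      child_expr <- nrc_for(ch$label_var, nrc_input(dom_name), ch$body)
      recurse(child_expr, env_child, ch$level)
    }
  }
  recurse(expr, list(), paste0(name, "_top"))
  comp_names
}

# replace the terminal singleton head of a for/if chain
replace_head <- function(e, new_head) {
  switch(e$kind,
    "for" = { e$body <- replace_head(e$body, new_head); e },
    "if" = { e$then <- replace_head(e$then, new_head); e },
    sng = new_head,
    stop("cannot replace head of node kind ", e$kind, call. = FALSE)
  )
}

# Rewrite one output level: shredded input access, label-equality joins for
# generators over nested attributes, and cutting of bag-valued head fields.
# Returns list(expr, children).
sh_rw <- function(expr, env, level, st) {
  children <- list()
  prefix <- sub("_top$", "", level)

  rw <- function(e, env) {
    rec <- function(x, env2 = env) rw(x, env2)
    switch(e$kind,
      input = , var = , const = , newlabel = , labeldomain = e,
      project = { e$expr <- rec(e$expr); e },
      cmp = , bool = , arith = {
        e$lhs <- rec(e$lhs); e$rhs <- rec(e$rhs); e
      },
      union = { e$lhs <- rec(e$lhs); e$rhs <- rec(e$rhs); e },
      dedup = , sumby = { e$expr <- rec(e$expr); e },
      "if" = { e$cond <- rec(e$cond); e$then <- rec(e$then); e },
      "for" = {
        src <- e$source
        if (src$kind == "input") {
          top_rel <- paste0(src$name, "_top")
          if (!is.null(st$schemas[[src$name]])) {
            elem <- st$schemas[[src$name]]$elem
          } else if (!is.null(st$schemas[[top_rel]])) {
            e$source <- nrc_input(top_rel)
            elem <- st$schemas[[top_rel]]$elem
          } else stop("unknown input: ", src$name, call. = FALSE)
          env[[e$var]] <- elem
          e$body <- rec(e$body, env)
          e
        } else {
          src2 <- rec(src)
          ty <- type_of(src2, env, st$schemas)
          if (is_label_type(ty)) {
            dict_rel <- ty$level
            dt <- st$schemas[[dict_rel]]
            if (is.null(dt))
              stop("no dictionary relation for level ", dict_rel,
                   call. = FALSE)
            env[[e$var]] <- dt$elem
            body <- rec(e$body, env)
            cond <- nrc_cmp("==", nrc_project(nrc_var(e$var), "label"), src2)
            nrc_for(e$var, nrc_input(dict_rel), nrc_if(cond, body))
          } else if (is_bag_type(ty)) {
            env[[e$var]] <- ty$elem
            e$source <- src2
            e$body <- rec(e$body, env)
            e
          } else stop("iteration over non-collection expression",
                      call. = FALSE)
        }
      },
      sng = {
        if (e$expr$kind != "tuple") { e$expr <- rec(e$expr); return(e) }
        tup <- e$expr
        for (f in names(tup$fields)) {
          fe <- tup$fields[[f]]
          if (is_bag_expr(fe)) {
            lid <- paste0(prefix, "_", f)
            cut <- cut_bag_field(fe, env, lid)
            children[[length(children) + 1L]] <<- cut
            tup$fields[[f]] <- cut$label_expr
          } else {
            tup$fields[[f]] <- rec(fe)
          }
        }
        e$expr <- tup
        e
      },
      groupby = stop("groupBy must be desugared before shredding",
                     call. = FALSE),
      stop("unknown node kind: ", e$kind)
    )
  }

  list(expr = rw(expr, env), children = children)
}

# Cut one bag-valued head field out of its level. The label context is the
# minimal binding set: the free outer-variable projections of the field
# expression. Returns the label expression for the parent head, the dom
# head (label + bindings), the dom element type, and the child body with
# outer projections substituted by label-context projections.
cut_bag_field <- function(B, env, lid) {
  outer_vars <- intersect(free_vars(B), names(env))
  bindings <- list()
  for (v in outer_vars) {
    for (attr in var_projections(B, v)) {
      bname <- attr
      i <- 2L
      while (!is.null(bindings[[bname]]) &&
             !(identical(bindings[[bname]]$var, v) &&
               identical(bindings[[bname]]$attr, attr))) {
        bname <- paste0(attr, "_", i); i <- i + 1L
      }
      ty <- env[[v]]$fields[[attr]]
      if (is.null(ty))
        stop("cannot type binding ", v, ".", attr, call. = FALSE)
      bindings[[bname]] <- list(var = v, attr = attr, type = ty)
    }
  }
  bexprs <- lapply(bindings, function(b) nrc_project(nrc_var(b$var), b$attr))
  label_expr <- nrc_new_label(lid, bexprs)
  dom_head <- nrc_sng(nrc_tuple(c(list(label = label_expr), bexprs)))
  dom_elem <- nt_tuple(c(list(label = nt_label(lid)),
                         lapply(bindings, function(b) b$type)))
  lv <- "lbl_"
  subst <- function(e, bound) {
    switch(e$kind,
      project = {
        if (e$expr$kind == "var" && !(e$expr$name %in% bound) &&
            e$expr$name %in% outer_vars) {
          hit <- NULL
          for (bname in names(bindings)) {
            b <- bindings[[bname]]
            if (identical(b$var, e$expr$name) &&
                identical(b$attr, e$attr)) { hit <- bname; break }
          }
          if (is.null(hit))
            stop("missing binding for ", e$expr$name, ".", e$attr,
                 call. = FALSE)
          nrc_project(nrc_var(lv), hit)
        } else { e$expr <- subst(e$expr, bound); e }
      },
      var = , input = , const = , labeldomain = e,
      tuple = { e$fields <- lapply(e$fields, subst, bound = bound); e },
      sng = , dedup = , sumby = , groupby = {
        e$expr <- subst(e$expr, bound); e
      },
      "for" = {
        e$source <- subst(e$source, bound)
        e$body <- subst(e$body, c(bound, e$var))
        e
      },
      "if" = {
        e$cond <- subst(e$cond, bound)
        e$then <- subst(e$then, bound)
        e
      },
      cmp = , bool = , arith = , union = {
        e$lhs <- subst(e$lhs, bound); e$rhs <- subst(e$rhs, bound); e
      },
      newlabel = {
        e$bindings <- lapply(e$bindings, subst, bound = bound); e
      },
      stop("unknown node kind: ", e$kind))
  }
  body <- add_label_field(subst(B, character(0)),
                          nrc_project(nrc_var(lv), "label"))
  list(level = lid, label_expr = label_expr, dom_head = dom_head,
       dom_elem_type = dom_elem, label_var = lv, body = body)
}

# extend the head tuple(s) of a flat bag expression with a label key field
add_label_field <- function(e, label_proj) {
  switch(e$kind,
    sng = {
      if (e$expr$kind != "tuple")
        stop("cannot label a non-tuple singleton", call. = FALSE)
      e$expr$fields <- c(list(label = label_proj), e$expr$fields)
      e
    },
    "for" = { e$body <- add_label_field(e$body, label_proj); e },
    "if" = { e$then <- add_label_field(e$then, label_proj); e },
    sumby = {
      e$expr <- add_label_field(e$expr, label_proj)
      e$keys <- c("label", e$keys)
      e
    },
    dedup = { e$expr <- add_label_field(e$expr, label_proj); e },
    union = {
      e$lhs <- add_label_field(e$lhs, label_proj)
      e$rhs <- add_label_field(e$rhs, label_proj)
      e
    },
    stop("cannot extend head of node kind ", e$kind, call. = FALSE)
  )
}
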