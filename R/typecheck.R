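#' Typecheck a program
#'
#' Infers the output type of every assignment in a program given the types of
#' its inputs. Rejects unbound variables, unknown attributes, ill-typed
#' predicates and arithmetic, references to assignments before their
#' definition, and `sumBy` applied to input with bag-typed attributes (the
#' aggregate is defined only over flat input).
#'
#' @param program an [nrc_program()].
#' @param input_schemas named list of `nrc_type` bag types, one per input.
#' @return named list of `nrc_type`s, one per assignment, in program order.
#' @export
typecheck <- function(program, input_schemas) {
  stopifnot(inherits(program, "nrc_program"))
  known <- input_schemas
  out <- list()
  for (a in program$assignments) {
    out[[a$name]] <- type_of(a$expr, env = list(), schemas = known)
    known[[a$name]] <- out[[a$name]]
  }
  out
}

type_of <- function(e, env, schemas) {
  tc <- function(e, env) type_of(e, env, schemas)
  switch(e$kind,
    input = {
      t <- schemas[[e$name]]
      if (is.null(t))
        stop("unknown input: ", e$name, call. = FALSE)
      t
    },
    var = {
      t <- env[[e$name]]
      if (is.null(t)) stop("unbound variable: ", e$name, call. = FALSE)
      t
    },
    project = {
      t <- tc(e$expr, env)
      if (!is_tuple_type(t))
        stop("projection .", e$attr, " applied to non-tuple", call. = FALSE)
      ft <- t$fields[[e$attr]]
      if (is.null(ft))
        stop("attribute not found: ", e$attr, call. = FALSE)
      ft
    },
    tuple = nt_tuple(lapply(e$fields, tc, env = env)),
    sng = {
      t <- tc(e$expr, env)
      if (!is_tuple_type(t))
        stop("singleton bag of non-tuple expression", call. = FALSE)
      nt_bag(t)
    },
    "for" = {
      st <- tc(e$source, env)
      if (!is_bag_type(st))
        stop("iteration over non-bag expression (var ", e$var, ")",
             call. = FALSE)
      env[[e$var]] <- st$elem
      bt <- tc(e$body, env)
      if (!is_bag_type(bt))
        stop("comprehension body must be bag-typed", call. = FALSE)
      bt
    },
    "if" = {
      ct <- tc(e$cond, env)
      if (!(is_scalar_type(ct) && ct$kind == "bool"))
        stop("condition must be boolean", call. = FALSE)
      tt <- tc(e$then, env)
      if (!is_bag_type(tt))
        stop("conditional allowed only in bag positions", call. = FALSE)
      tt
    },
    cmp = {
      lt <- tc(e$lhs, env); rt <- tc(e$rhs, env)
      ok <- (is_label_type(lt) && is_label_type(rt) &&
               e$op %in% c("==", "!=")) ||
            (is_scalar_type(lt) && is_scalar_type(rt) &&
               (lt$kind == rt$kind ||
                  (is_numeric_kind(lt) && is_numeric_kind(rt))))
      if (!ok)
        stop("type mismatch in comparison ", e$op, ": ",
             format(lt), " vs ", format(rt), call. = FALSE)
      nt_scalar("bool")
    },
    bool = {
      for (side in list(e$lhs, e$rhs)) {
        t <- tc(side, env)
        if (!(is_scalar_type(t) && t$kind == "bool"))
          stop("boolean operator over non-boolean operand", call. = FALSE)
      }
      nt_scalar("bool")
    },
    arith = {
      lt <- tc(e$lhs, env); rt <- tc(e$rhs, env)
      if (!is_numeric_kind(lt) || !is_numeric_kind(rt))
        stop("arithmetic over non-numeric operands: ",
             format(lt), " ", e$op, " ", format(rt), call. = FALSE)
      if (e$op == "/") nt_scalar("real")
      else nt_scalar(arith_result_kind(lt, rt))
    },
    dedup = {
      t <- tc(e$expr, env)
      if (!is_bag_type(t)) stop("dedup over non-bag", call. = FALSE)
      t
    },
    groupby = {
      t <- tc(e$expr, env)
      if (!is_bag_type(t)) stop("groupBy over non-bag", call. = FALSE)
      flds <- t$elem$fields
      missing <- setdiff(e$keys, names(flds))
      if (length(missing))
        stop("groupBy key not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
      for (k in e$keys)
        if (is_bag_type(flds[[k]]))
          stop("groupBy key must be scalar: ", k, call. = FALSE)
      rest <- setdiff(names(flds), e$keys)
      if (e$group_attr %in% e$keys)
        stop("group attribute collides with a key: ", e$group_attr,
             call. = FALSE)
      nt_bag(nt_tuple(c(flds[e$keys],
                        stats::setNames(list(nt_bag(nt_tuple(flds[rest]))),
                                        e$group_attr))))
    },
    sumby = {
      t <- tc(e$expr, env)
      if (!is_bag_type(t)) stop("sumBy over non-bag", call. = FALSE)
      if (!is_flat_tuple(t$elem))
        stop("sumBy requires flat input (no bag-typed attributes)",
             call. = FALSE)
      flds <- t$elem$fields
      missing <- setdiff(c(e$keys, e$values), names(flds))
      if (length(missing))
        stop("sumBy attribute not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
      for (v in e$values) {
        if (!is_numeric_kind(flds[[v]]))
          stop("sumBy value must be numeric: ", v, call. = FALSE)
        flds[[v]] <- nt_scalar("real")  # sums accumulate as reals
      }
      nt_bag(nt_tuple(flds[c(e$keys, e$values)]))
    },
    const = nt_scalar(e$ckind),
    union = {
      lt <- tc(e$lhs, env); rt <- tc(e$rhs, env)
      if (!is_bag_type(lt) || !type_equal(lt, rt))
        stop("bag union over incompatible types", call. = FALSE)
      lt
    },
    newlabel = {
      for (b in e$bindings) {
        bt <- tc(b, env)
        if (!is_scalar_type(bt) && !is_label_type(bt))
          stop("label context bindings must be scalar", call. = FALSE)
      }
      nt_label(e$level)
    },
    labeldomain = {
      t <- schemas[[paste0(".labels.", e$level)]]
      if (is.null(t))
        stop("no label domain schema for level ", e$level, call. = FALSE)
      t
    },
    stop("unknown node kind: ", e$kind)
  )
}
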