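#' Shredding: types and values
#'
#' The shredded representation encodes a nested bag as a set of flat
#' relations linked by labels, in the manner of a database schema with
#' foreign keys: one relation per collection level, where every bag-typed
#' attribute is replaced by a label field referencing the child level's
#' dictionary. [shred_type()] derives the flat relational schema,
#' [shred_value()] encodes a nested value against it (optionally sharing one
#' dictionary entry between parents with identical inner bags), and
#' [unshred_value()] reconstructs the nested value by dereferencing labels —
#' a dangling label (one that resolves in no dictionary) is an integrity
#' error, never an empty bag.
#'
#' @name shredding
NULL

#' Shred a nested bag type into a flat relational schema
#'
#' @param t a bag type.
#' @param name relation name stem for the top level (e.g. `"Occurrences"`).
#' @return an `nrc_shredded_schema`: a list of flat relations, one per
#'   collection level. The top relation is named `<name>_top` (or `<name>`
#'   when the type is already flat); each nested level `<name>_<attr path>`
#'   carries a `label` key field, and parent relations reference it through
#'   their label-typed attribute.
#' @export
shred_type <- function(t, name = "X") {
  stopifnot(is_bag_type(t))
  relations <- list()
  walk <- function(elem, relname, is_top) {
    fields <- list()
    child_links <- list()
    if (!is_top) fields$label <- nt_label(relname)
    for (f in names(elem$fields)) {
      ft <- elem$fields[[f]]
      if (is_bag_type(ft)) {
        lid <- paste0(sub("_top$", "", relname), "_", f)
        fields[[f]] <- nt_label(lid)
        child_links[[f]] <- lid
      } else {
        fields[[f]] <- ft
      }
    }
    rel <- list(name = relname, fields = fields,
                label_field = if (is_top) NULL else "label",
                child_links = child_links)
    relations[[relname]] <<- rel
    for (f in names(child_links))
      walk(elem$fields[[f]]$elem, child_links[[f]], FALSE)
  }
  top_name <- if (is_flat_tuple(t$elem)) name else paste0(name, "_top")
  walk(t$elem, top_name, TRUE)
  structure(list(name = name, relations = relations,
                 top = top_name, type = t),
            class = "nrc_shredded_schema")
}

#' @export
print.nrc_shredded_schema <- function(x, ...) {
  for (rel in x$relations) {
    cat(rel$name, ": ", format(nt_tuple(rel$fields)), "\n", sep = "")
  }
  invisible(x)
}

#' Shred a nested value
#'
#' @param v a bag value conforming to the schema's nested type.
#' @param schema an `nrc_shredded_schema` from [shred_type()].
#' @param sharing share one dictionary entry between parents whose inner
#'   bags are identical (deep multiset equality); with `sharing = FALSE`
#'   every parent gets its own label.
#' @return an `nrc_shredded_value`: `top` (flat bag, labels as opaque string
#'   keys) and `dicts` (level id -> label -> flat bag; empty inner bags are
#'   kept as empty dictionary entries, never dropped).
#' @export
shred_value <- function(v, schema, sharing = FALSE) {
  dicts <- list()
  counters <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  shred_bag <- function(bag, relname) {
    rel <- schema$relations[[relname]]
    lapply(bag, function(tup) {
      for (f in names(rel$child_links)) {
        lid <- rel$child_links[[f]]
        inner <- tup[[f]]
        key <- NULL
        if (sharing) {
          ck <- paste0(lid, "\x1f", canon_value(inner))
          key <- seen[[ck]]
        }
        if (is.null(key)) {
          n <- (counters[[lid]] %||% 0L) + 1L
          counters[[lid]] <- n
          key <- paste0("L<", lid, ">#", n)
          if (sharing) assign(ck, key, envir = seen)
          d <- dicts[[lid]] %||% list()
          d[[key]] <- shred_bag(inner, lid)
          dicts[[lid]] <<- d
        }
        tup[[f]] <- key
      }
      tup
    })
  }
  top <- shred_bag(v, schema$top)
  structure(list(top = top, dicts = dicts, schema = schema),
            class = "nrc_shredded_value")
}

#' @export
print.nrc_shredded_value <- function(x, ...) {
  cat("<shredded value> top:", length(x$top), "tuples;",
      length(x$dicts), "dictionaries\n")
  for (lid in names(x$dicts)) {
    d <- x$dicts[[lid]]
    cat("  ", lid, ": ", length(d), " labels, ",
        sum(vapply(d, length, integer(1))), " tuples\n", sep = "")
  }
  invisible(x)
}

#' @rdname shred_value
#' @param sv an `nrc_shredded_value`.
#' @export
unshred_value <- function(sv) {
  schema <- sv$schema
  deref <- function(bag, relname) {
    rel <- schema$relations[[relname]]
    lapply(bag, function(tup) {
      for (f in names(rel$child_links)) {
        lid <- rel$child_links[[f]]
        key <- tup[[f]]
        d <- sv$dicts[[lid]] %||% list()
        entry <- d[[key]]
        if (is.null(entry)) {
          if (!key %in% names(d))
            stop("dangling label ", key, " in level ", lid, call. = FALSE)
          entry <- list()
        }
        tup[[f]] <- deref(entry, lid)
      }
      tup
    })
  }
  deref(sv$top, schema$top)
}

# total tuples across all dictionary levels of a shredded value
shredded_dict_tuples <- function(sv, levels = names(sv$dicts)) {
  sum(vapply(levels, function(lid)
    sum(vapply(sv$dicts[[lid]], length, integer(1))), integer(1)))
}

# flatten one dictionary level into a relation with a label column
dict_to_bag <- function(sv, lid) {
  d <- sv$dicts[[lid]] %||% list()
  out <- list()
  for (key in names(d)) {
    for (tup in d[[key]]) {
      out[[length(out) + 1L]] <- c(list(label = key), tup)
    }
  }
  out
}

# all flat relations (as bag values) of a shredded value, named by level
shredded_relations <- function(sv) {
  rels <- stats::setNames(list(sv$top), sv$schema$top)
  for (lid in setdiff(names(sv$schema$relations), sv$schema$top))
    rels[[lid]] <- dict_to_bag(sv, lid)
  rels
}
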