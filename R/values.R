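#' Values
#'
#' Runtime values of the query language. Scalars are length-1 R atomics, the
#' null introduced by flattening is `NA`, tuples are named lists, and bags are
#' unnamed lists of tuples. Bags are multisets: all equality tests in the
#'
#' package are order-insensitive ([bag_equal()]). Labels — surrogate keys for
#' nested collection levels in the shredded representation — are
#' content-addressed: a label is its level plus the tuple of context bindings
#' it carries, so label equality is structural and independent of any interned
#' numbering.
#'
#' @name nrc-values
NULL

#' @rdname nrc-values
#' @param level label level identifier.
#' @param ctx named list of scalar context bindings.
#' @export
label_value <- function(level, ctx) {
  structure(list(level = level, ctx = ctx[order(names(ctx))]),
            class = "nrc_labelv")
}

is_label_value <- function(v) inherits(v, "nrc_labelv")

# stable string key for a label (used as the label column in flat relations)
label_key <- function(l) {
  paste0("L<", l$level, ">",
         paste0(names(l$ctx), "=", vapply(l$ctx, canon_scalar, character(1)),
                collapse = "|"))
}

#' @export
format.nrc_labelv <- function(x, ...) label_key(x)

#' @export
print.nrc_labelv <- function(x, ...) { cat(label_key(x), "\n"); invisible(x) }

is_tuple_value <- function(v) is.list(v) && !is.null(names(v)) &&
  !is_label_value(v)
is_bag_value <- function(v) is.list(v) && is.null(names(v)) &&
  !is_label_value(v)

# ---- canonicalization ------------------------------------------------------

# Scalars are canonicalized with numerics rounded to 8 significant digits so
# that sums accumulated in different orders across execution routes compare
# equal; strings are escaped to keep the encoding injective.
canon_scalar <- function(v) {
  if (length(v) != 1 || (is.list(v) && !is_label_value(v)))
    stop("not a scalar: ", paste(class(v), collapse = "/"), call. = FALSE)
  if (is_label_value(v)) return(label_key(v))
  if (is.na(v)) return("#null")
  if (is.character(v)) return(paste0("s:", encodeString(v, quote = '"')))
  if (is.logical(v)) return(if (v) "b:T" else "b:F")
  if (is.numeric(v)) return(paste0("n:", sprintf("%.8g", v)))
  stop("unsupported scalar class: ", class(v)[1], call. = FALSE)
}

canon_value <- function(v) {
  if (is_label_value(v)) return(label_key(v))
  if (is_bag_value(v)) {
    if (length(v) == 0) return("[]")
    elems <- vapply(v, canon_value, character(1))
    return(paste0("[", paste(sort(elems), collapse = ","), "]"))
  }
  if (is_tuple_value(v)) {
    nms <- sort(names(v))
    return(paste0("{", paste0(nms, "=",
                              vapply(v[nms], canon_value, character(1)),
                              collapse = ","), "}"))
  }
  canon_scalar(v)
}

#' Multiset equality of bags
#'
#' Deep, order-insensitive equality of two bag values: bags are compared as
#' multisets, recursing into nested bags. Numeric scalars are compared after
#' rounding to 8 significant digits, which makes results computed by different
#' execution routes (different summation orders) compare equal. Labels are
#' compared by content (level and context bindings), which is invariant under
#' renaming of any interned surrogates.
#'
#' @param a,b bag values (unnamed lists of tuples).
#' @return `TRUE` or `FALSE`.
#' @export
bag_equal <- function(a, b) {
  if (!is_bag_value(a) || !is_bag_value(b))
    stop("bag_equal expects bag values", call. = FALSE)
  if (length(a) != length(b)) return(FALSE)
  identical(canon_value(a), canon_value(b))
}

# ---- conversion between value bags and tibbles -----------------------------

# Flat relations at runtime are tibbles; bag-typed attributes are list-columns
# whose cells hold value bags (unnamed lists of tuples).

empty_col <- function(t) {
  if (is_bag_type(t)) return(list())
  if (is_label_type(t)) return(character(0))
  switch(t$kind, string = character(0), int = integer(0),
         real = numeric(0), bool = logical(0))
}

#' Convert a bag value to a tibble
#'
#' @param bag unnamed list of tuples.
#' @param elem_type tuple type of the elements (needed to type columns of
#'   empty bags).
#' @return a tibble; bag attributes become list-columns of value bags, label
#'   attributes become character key columns.
#' @export
bag_to_tbl <- function(bag, elem_type) {
  flds <- elem_type$fields
  nms <- names(flds)
  if (length(bag) == 0) {
    cols <- lapply(flds, empty_col)
    names(cols) <- nms
    return(tibble::as_tibble(cols))
  }
  cols <- lapply(nms, function(f) {
    ft <- flds[[f]]
    vals <- lapply(bag, function(tup) tup[[f]])
    if (is_bag_type(ft)) {
      vals
    } else if (is_label_type(ft)) {
      vapply(vals, function(v) {
        if (is_label_value(v)) label_key(v)
        else if (length(v) == 1 && is.na(v)) NA_character_
        else as.character(v)
      }, character(1))
    } else {
      caster <- switch(ft$kind, string = as.character, int = as.integer,
                       real = as.numeric, bool = as.logical)
      vapply(vals, function(v) {
        if (is.null(v) || (length(v) == 1 && is.na(v)))
          caster(NA) else caster(v)
      }, caster(NA))
    }
  })
  names(cols) <- nms
  tibble::as_tibble(cols)
}

#' Convert a tibble back to a bag value
#'
#' Inverse of [bag_to_tbl()]. List-columns are taken as nested value bags;
#' character label columns are kept as opaque label keys.
#'
#' @param tbl a tibble.
#' @return an unnamed list of tuples.
#' @export
tbl_to_bag <- function(tbl) {
  if (nrow(tbl) == 0) return(list())
  nms <- names(tbl)
  lapply(seq_len(nrow(tbl)), function(i) {
    tup <- lapply(nms, function(f) {
      col <- tbl[[f]]
      if (is.list(col)) col[[i]] else col[[i]]
    })
    names(tup) <- nms
    tup
  })
}

# total tuple count of a value bag, counting nested tuples recursively;
# the runtime's unit of partition "load"
deep_tuple_count <- function(bag) {
  if (length(bag) == 0) return(0L)
  sum(vapply(bag, function(tup) {
    1L + sum(vapply(tup, function(v) {
      if (is_bag_value(v) && !is_label_value(v)) deep_tuple_count(v) else 0L
    }, integer(1)))
  }, integer(1)))
}
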