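#' Nested types
#'
#' The type system of the query language: scalars, tuples with named fields,
#' bags of tuples, and label types (surrogate keys standing in for a nested
#' collection level in the shredded representation). Types are finite trees;
#' bag elements are always tuple-typed and field names within a tuple are
#' unique.
#'
#' @param kind one of `"string"`, `"int"`, `"real"`, `"bool"`.
#' @name ntype
NULL

SCALAR_KINDS <- c("string", "int", "real", "bool")

#' @rdname ntype
#' @export
nt_scalar <- function(kind) {
  kind <- match.arg(kind, SCALAR_KINDS)
  structure(list(k = "scalar", kind = kind), class = "nrc_type")
}

#' @rdname ntype
#' @param fields named list of `nrc_type` objects (order is significant for
#'   printing only; field names must be unique).
#' @export
nt_tuple <- function(fields) {
  stopifnot(is.list(fields), !is.null(names(fields)),
            !anyDuplicated(names(fields)))
  structure(list(k = "tuple", fields = fields), class = "nrc_type")
}

#' @rdname ntype
#' @param elem element type; must be a tuple type.
#' @export
nt_bag <- function(elem) {
  stopifnot(inherits(elem, "nrc_type"))
  if (elem$k != "tuple") stop("bag elements must be tuple-typed", call. = FALSE)
  structure(list(k = "bag", elem = elem), class = "nrc_type")
}

#' @rdname ntype
#' @param level_id opaque identifier of the dictionary level this label keys.
#' @export
nt_label <- function(level_id) {
  structure(list(k = "label", level = level_id), class = "nrc_type")
}

is_scalar_type <- function(t) t$k == "scalar"
is_tuple_type  <- function(t) t$k == "tuple"
is_bag_type    <- function(t) t$k == "bag"
is_label_type  <- function(t) t$k == "label"

#' Does a tuple type contain no bag-typed attributes?
#' @param t an `nrc_type`.
#' @export
is_flat_tuple <- function(t) {
  stopifnot(is_tuple_type(t))
  !any(vapply(t$fields, is_bag_type, logical(1)))
}

is_numeric_kind <- function(t) is_scalar_type(t) && t$kind %in% c("int", "real")

#' Structural type equality
#' @param a,b `nrc_type` objects.
#' @export
type_equal <- function(a, b) {
  if (a$k != b$k) return(FALSE)
  switch(a$k,
    scalar = a$kind == b$kind,
    label  = identical(a$level, b$level),
    bag    = type_equal(a$elem, b$elem),
    tuple  = {
      na <- sort(names(a$fields)); nb <- sort(names(b$fields))
      if (!identical(na, nb)) return(FALSE)
      all(vapply(na, function(f) type_equal(a$fields[[f]], b$fields[[f]]),
                 logical(1)))
    })
}

#' @export
format.nrc_type <- function(x, ...) {
  switch(x$k,
    scalar = x$kind,
    label  = paste0("Label<", x$level, ">"),
    bag    = paste0("[ ", format(x$elem), " ]"),
    tuple  = paste0("{ ",
                    paste(names(x$fields),
                          vapply(x$fields, format, character(1)),
                          sep = ": ", collapse = ", "),
                    " }"))
}

#' @export
print.nrc_type <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# upward coercion for arithmetic: int op int -> int, otherwise real
arith_result_kind <- function(a, b) {
  if (a$kind == "int" && b$kind == "int") "int" else "real"
}

# number of bag levels in a type (top bag counts as 1)
n_bag_levels <- function(t) {
  if (is_bag_type(t)) {
    1L + sum(vapply(t$elem$fields, n_bag_levels, integer(1)))
  } else if (is_tuple_type(t)) {
    sum(vapply(t$fields, n_bag_levels, integer(1)))
  } else 0L
}
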