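#' Shredded evaluation and execution
#'
#' Runs a shredded program over shredded inputs. Nested inputs are encoded
#' with [shred_value()]; every component is a flat program over flat
#' relations, so evaluation is either in-memory ([eval_shredded()]) or on
#' the partitioned runtime ([execute_shredded()], which compiles each flat
#' component with [compile_standard()] and accounts shuffle/broadcast volume
#' exactly like the standard route). Per-assignment results are assembled
#' into shredded values (top bag plus label dictionaries); the label domain
#' of each level supplies the dictionary key set, so labels whose child
#' level produced no rows appear as empty dictionary entries.
#'
#' @param sp an `nrc_shredded_program` from [shred_program()].
#' @param inputs named list of input bag values (nested lists); nested
#'   inputs may also be passed pre-shredded as `nrc_shredded_value`s.
#' @param sharing use sharing-aware input shredding (one dictionary entry
#'   per distinct inner bag).
#' @return list with `values` (per original assignment, an
#'   `nrc_shredded_value`), `relations` (all flat component results),
#'   `access_log` (per component, the flat relations it reads), and for
#'   [execute_shredded()] also `stats`.
#' @export
eval_shredded <- function(sp, inputs, sharing = FALSE) {
  rels <- shred_inputs(sp, inputs, sharing)
  results <- eval_reference(sp$flat_program, rels)
  assemble_shredded(sp, results, access_log = component_reads(sp))
}

#' @rdname eval_shredded
#' @param config a [cluster_config()].
#' @export
execute_shredded <- function(sp, inputs, config = cluster_config(),
                             sharing = FALSE) {
  rels <- shred_inputs(sp, inputs, sharing)
  rel_schemas <- input_relation_schemas(sp)
  tbls <- list()
  for (nm in names(rels)) {
    if (!is.null(rel_schemas[[nm]]))
      tbls[[nm]] <- bag_to_tbl(rels[[nm]], rel_schemas[[nm]]$elem)
  }
  compiled <- compile_standard(sp$flat_program, rel_schemas)
  run <- execute_standard(compiled, tbls, config)
  out <- assemble_shredded(sp, run$results,
                           access_log = component_reads(sp))
  out$stats <- run$stats
  out
}

# flat input relations (as bag values) for a shredded program's inputs
shred_inputs <- function(sp, inputs, sharing = FALSE) {
  rels <- list()
  for (nm in names(sp$input_schemas)) {
    v <- inputs[[nm]]
    if (is.null(v)) next
    t <- sp$input_schemas[[nm]]
    if (is_flat_tuple(t$elem)) {
      rels[[nm]] <- v
    } else {
      sv <- if (inherits(v, "nrc_shredded_value")) v
            else shred_value(v, sp$shredded_schemas[[nm]], sharing = sharing)
      rels <- c(rels, shredded_relations(sv))
    }
  }
  rels
}

input_relation_schemas <- function(sp) {
  out <- list()
  for (nm in names(sp$input_schemas)) {
    t <- sp$input_schemas[[nm]]
    if (is_flat_tuple(t$elem)) {
      out[[nm]] <- t
    } else {
      for (rel in sp$shredded_schemas[[nm]]$relations)
        out[[rel$name]] <- nt_bag(nt_tuple(rel$fields))
    }
  }
  out
}

component_reads <- function(sp) {
  log <- list()
  for (a in sp$flat_program$assignments)
    log[[a$name]] <- input_refs(a$expr)
  log
}

# assemble per-assignment shredded values from flat component results
assemble_shredded <- function(sp, results, access_log = NULL) {
  values <- list()
  for (nm in names(sp$components)) {
    comp <- sp$components[[nm]]
    schema <- sp$shredded_schemas[[nm]]
    top <- results[[comp[1]]]
    dicts <- list()
    for (lid in comp[-1]) {
      dom <- results[[paste0(lid, "_dom")]]
      rows <- results[[lid]]
      d <- stats::setNames(
        replicate(length(dom), list()),
        vapply(dom, function(tup) as.character(tup$label), character(1)))
      for (tup in rows) {
        key <- as.character(tup$label)
        tup$label <- NULL
        d[[key]] <- c(d[[key]], list(tup))
      }
      dicts[[lid]] <- d
    }
    values[[nm]] <- structure(list(top = top, dicts = dicts,
                                   schema = schema),
                              class = "nrc_shredded_value")
  }
  list(values = values, relations = results, access_log = access_log)
}

#' Run a program end to end via the shredded route
#'
#' Shreds the program and its nested inputs, evaluates all flat components,
#' and unshreds every assignment's result back to a nested value.
#'
#' @inheritParams shred_program
#' @inheritParams eval_shredded
#' @param config optional [cluster_config()]; when supplied the components
#'   run on the partitioned runtime, otherwise in memory.
#' @return list with `results` (named list of nested bag values),
#'   `shredded` (the per-assignment shredded values) and `stats` (runtime
#'   execution only).
#' @export
run_shredded <- function(program, input_schemas, inputs, config = NULL,
                         sharing = FALSE) {
  sp <- shred_program(program, input_schemas)
  run <- if (is.null(config)) eval_shredded(sp, inputs, sharing = sharing)
         else execute_shredded(sp, inputs, config, sharing = sharing)
  results <- lapply(run$values, unshred_value)
  list(results = results, shredded = run$values, stats = run$stats,
       program = sp)
}
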