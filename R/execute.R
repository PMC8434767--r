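#' Execute a compiled program on the partitioned runtime
#'
#' Runs every assignment's plan in order on the simulated cluster,
#' materializing each result so later assignments can scan it, and converts
#' the final relations back to nested bag values. Execution is deterministic
#' given the inputs and the configuration's hash seed.
#'
#' @param compiled an `nrc_compiled` object from [compile_standard()].
#' @param inputs named list of input bag values (nested lists, as consumed by
#'   [eval_reference()]).
#' @param config a [cluster_config()].
#' @return list with `results` (named list of bag values, one per
#'   assignment) and `stats` (the execution statistics accumulator).
#' @export
execute_standard <- function(compiled, inputs, config = cluster_config()) {
  stats <- new_exec_stats()
  tbls <- list()
  for (nm in names(compiled$input_schemas)) {
    v <- inputs[[nm]]
    if (is.null(v)) next
    tbls[[nm]] <- if (is.data.frame(v)) v
      else bag_to_tbl(v, compiled$input_schemas[[nm]]$elem)
  }
  extra <- setdiff(names(inputs), names(tbls))
  for (nm in extra) tbls[[nm]] <- inputs[[nm]]  # pre-built tibbles
  results <- list()
  for (nm in names(compiled$plans)) {
    pbag <- exec_plan(compiled$plans[[nm]]$plan, tbls, config, stats)
    tbl <- pbag_collect(pbag)
    tbls[[nm]] <- tbl
    results[[nm]] <- tbl_to_bag(tbl)
  }
  list(results = results, stats = stats)
}

#' Run a program end to end via the standard route
#'
#' Convenience wrapper: typecheck, compile with [compile_standard()], execute
#' with [execute_standard()], and return the final assignment's value.
#'
#' @inheritParams compile_standard
#' @inheritParams execute_standard
#' @param naive compile the lossy inner-flatten diagnostic variant.
#' @export
run_standard <- function(program, input_schemas, inputs,
                         config = cluster_config(), naive = FALSE) {
  compiled <- compile_standard(program, input_schemas, naive = naive)
  execute_standard(compiled, inputs, config)
}

#' Outer-flatten cardinality law
#'
#' The correctness-preserving outer flatten emits one row per child element
#' plus one NULL-padded row per empty parent, for a total of
#' `sum(max(1, size_i))` rows over `top_count` parents; the naive (lossy)
#' flatten emits only `sum(size_i)` rows, losing parents with empty inner
#' collections. Both counts are returned for comparison.
#'
#' @param top_count number of parent tuples.
#' @param child_sizes integer vector of inner-bag sizes, one per parent.
#' @return list with `outer` and `naive` cardinalities.
#' @export
outer_flatten_cardinality <- function(top_count, child_sizes) {
  if (length(child_sizes) != top_count)
    stop("child_sizes must have one entry per parent", call. = FALSE)
  if (any(child_sizes < 0)) stop("negative inner-bag size", call. = FALSE)
  list(outer = sum(pmax(1, as.numeric(child_sizes))),
       naive = sum(as.numeric(child_sizes)))
}
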