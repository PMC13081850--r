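# Composition operations (combine pools) and state operations (select,
# reorder, filter, replicate).

#' Concatenate pools end-to-end
#'
#' Fixed-mode Cartesian composition: sizes multiply, and each output
#' sequence is the concatenation of one member per input, regions and
#' styles carried at their shifted offsets.
#'
#' @param ... Input pools (at least one), in concatenation order.
#' @return A pool of cardinality `prod(sizes)`.
#' @export
#' @examples
#' p <- join_pools(from_seq("AC"), from_seq("GT"))
#' seq_chars(generate(p, 0)$seq)  # "ACGT"
join_pools <- function(...) {
  inputs <- flatten_pools(list(...))
  if (length(inputs) < 1L) stop("join needs >= 1 input", call. = FALSE)
  new_operation(
    kind = "join", mode = "fixed", inputs = inputs,
    construct = function(node, istate, seqs, ctx) {
      list(seq = concat_tagged(seqs), card = NULL)
    })
}

#' Merge pools into one (disjoint union)
#'
#' Output states are the disjoint union of the input pools' states, laid
#' out in declaration order; each state activates exactly one branch.
#' The active branch's label is recorded on the design card
#' (`component`) and contributed as a bare token to the sequence name;
#' operations on inactive branches contribute null card values.
#'
#' @param ... Input pools; names become branch labels.
#' @param labels Optional explicit branch labels (default: argument
#'   names, then `p1`, `p2`, ...).
#' @param prefix Optional card qualifier (default `"stack"`).
#' @return A pool of cardinality `sum(sizes)`.
#' @export
stack_pools <- function(..., labels = NULL, prefix = NULL) {
  dots <- list(...)
  nm <- names(dots) %||% rep("", length(dots))
  inputs <- flatten_pools(dots)
  if (is.null(labels)) {
    labels <- if (length(inputs) == length(dots) && any(nzchar(nm))) {
      ifelse(nzchar(nm), nm, paste0("p", seq_along(inputs)))
    } else {
      nm2 <- names(inputs) %||% rep("", length(inputs))
      ifelse(nzchar(nm2), nm2, paste0("p", seq_along(inputs)))
    }
  }
  stopifnot(length(labels) == length(inputs))
  if (anyDuplicated(labels)) {
    stop("stack branch labels must be distinct", call. = FALSE)
  }
  node <- new_operation(
    kind = "stack", mode = "fixed", inputs = inputs, layout = "union",
    tracked = "component", labels = as.list(labels),
    params = list(labels = as.list(labels), prefix = prefix))
  if (!is.null(prefix)) node$qualifier <- prefix
  node
}

# Accept either pools as ... or a single list of pools.
flatten_pools <- function(dots) {
  if (length(dots) == 1L && !is_pool(dots[[1]]) && is.list(dots[[1]])) {
    dots[[1]]
  } else {
    dots
  }
}

#' Replicate every member of a pool
#'
#' Internal state = replicate index; the sequence is unchanged and the
#' replicate index is recorded on the design card.
#'
#' @param parent Input pool.
#' @param n Number of replicates (`>= 1`).
#' @param prefix Name-token prefix.
#' @return A pool of cardinality `n * |parent|`.
#' @export
repeat_pool <- function(parent, n, prefix = NULL) {
  stopifnot(n >= 1)
  new_operation(
    kind = "repeat", mode = "sequential", inputs = list(parent),
    internal_cardinality = n, prefix = prefix, tracked = "replicate",
    params = list(n = n, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      list(seq = seqs[[1]], card = list(replicate = istate))
    })
}

#' Select, reorder, or filter the states of a pool
#'
#' `select_states()` keeps the given parent states, in the given order;
#' `reorder_states()` applies a permutation of all parent states;
#' `filter_pool()` keeps the parent states whose generated sequence
#' satisfies a predicate. All three record the original parent state on
#' the design card.
#'
#' Filtering cannot know its cardinality without evaluating the
#' predicate, so the kept-state index is materialized by a one-time scan
#' of the parent at the first size query and cached (a documented eager
#' cost; sequences of random-mode parents are evaluated under
#' `materialize_seed`).
#'
#' @param parent Input pool (enumerable size).
#' @param indices 0-based parent states to keep, in order.
#' @param permutation 0-based permutation of `0:(size-1)`.
#' @param predicate `function(chars)` returning `TRUE` to keep a member
#'   (`chars` is the plain character string).
#' @param materialize_seed Master seed used for the materialization scan.
#' @param prefix Name-token prefix.
#' @return A pool.
#' @export
select_states <- function(parent, indices, prefix = NULL) {
  N <- pool_size(parent)
  indices <- as.numeric(indices)
  if (length(indices) < 1L) stop("empty selection", call. = FALSE)
  if (is_bigint(N)) {
    if (any(indices >= 2^53)) stop("indices out of range", call. = FALSE)
  } else if (any(indices < 0) || any(indices >= N)) {
    stop("index out of range [0, ", sn_format(N), ")", call. = FALSE)
  }
  node <- new_operation(
    kind = "select", mode = "fixed", inputs = list(parent),
    layout = "remap", internal_cardinality = length(indices),
    prefix = prefix, tracked = "parent_state",
    params = list(indices = indices, prefix = prefix),
    map_state = function(node, s) node$params$indices[s + 1])
  node
}

#' @rdname select_states
#' @export
reorder_states <- function(parent, permutation, prefix = NULL) {
  N <- pool_size(parent)
  if (is_bigint(N) || N > 1e7) {
    stop("reorder requires an enumerable parent size", call. = FALSE)
  }
  permutation <- as.numeric(permutation)
  if (length(permutation) != N ||
      !identical(sort(permutation), as.numeric(seq_len(N) - 1))) {
    stop("permutation must be a bijection of 0:(size-1)", call. = FALSE)
  }
  new_operation(
    kind = "reorder", mode = "fixed", inputs = list(parent),
    layout = "remap", internal_cardinality = N,
    prefix = prefix, tracked = "parent_state",
    params = list(permutation = permutation, prefix = prefix),
    map_state = function(node, s) node$params$permutation[s + 1])
}

#' @rdname select_states
#' @export
filter_pool <- function(parent, predicate, materialize_seed = 0,
                        prefix = NULL) {
  stopifnot(is.function(predicate))
  N <- pool_size(parent)
  if (is_bigint(N) || N > 1e6) {
    stop("filter requires an enumerable parent (size <= 1e6); ",
         "filter earlier in the DAG", call. = FALSE)
  }
  new_operation(
    kind = "filter", mode = "fixed", inputs = list(parent),
    layout = "remap",
    internal_cardinality = function(node) {
      pm <- node$params
      keep <- vapply(seq_len(N) - 1, function(s) {
        isTRUE(pm$predicate(gen_node(node$inputs[[1L]], s,
                                     pm$materialize_seed)$seq$chars))
      }, logical(1))
      node$.map <- (seq_len(N) - 1)[keep]
      length(node$.map)
    },
    prefix = prefix, tracked = "parent_state",
    params = list(predicate = predicate,
                  materialize_seed = materialize_seed, prefix = prefix),
    map_state = function(node, s) node$.map[s + 1])
}
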