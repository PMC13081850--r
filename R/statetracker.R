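# The state algebra: bijective composition and decomposition of integer
# states across the two operation topologies.
#
# Most operations have a Cartesian-product state space: the possible output
# states are (internal state) x (state of input 1) x ... x (state of input
# k). These use mixed-radix decomposition, with the internal state as the
# LEAST significant digit and the inputs in declaration order with
# increasing significance, so that consecutive states enumerate an
# operation's own variants before advancing any parent. Pool-merging
# operations instead have a disjoint-union state space: the received state
# selects exactly one input branch and is passed on (minus the branch
# offset); inactive branches receive no state.

#' Cartesian-product state layout
#'
#' Describes the state space of an operation whose outputs are the
#' Cartesian product of its own internal variants and the states of each
#' input pool.
#'
#' @param internal_cardinality Number of internal variants (1 for
#'   fixed-mode operations). Numeric, decimal string, or [as_bigint()]
#'   value.
#' @param input_cardinalities List (or vector) of the input pools'
#'   cardinalities, in declaration order.
#' @return A `product_layout` with fields `internal`, `inputs`, and
#'   `total` (= internal x prod(inputs), exact).
#' @seealso [decompose_product()], [union_layout()]
#' @export
#' @examples
#' ly <- product_layout(3, list(4, 5))
#' ly$total  # 60
product_layout <- function(internal_cardinality, input_cardinalities = list()) {
  internal <- sn_coerce(internal_cardinality)
  inputs <- lapply(as.list(input_cardinalities), sn_coerce)
  if (sn_cmp(internal, 1) < 0) {
    stop("internal cardinality must be >= 1", call. = FALSE)
  }
  for (ci in inputs) {
    if (sn_cmp(ci, 1) < 0) stop("input cardinalities must be >= 1", call. = FALSE)
  }
  total <- internal
  for (ci in inputs) total <- sn_mul(total, ci)
  structure(list(internal = internal, inputs = inputs, total = total),
            class = "product_layout")
}

#' Disjoint-union state layout
#'
#' Describes the state space of a pool-merging operation: output states are
#' the tagged union of the input pools' states, laid out consecutively in
#' declaration order.
#'
#' @param input_cardinalities List (or vector) of input cardinalities.
#' @return A `union_layout` with fields `inputs`, `offsets` (cumulative
#'   sums starting at 0), and `total` (= sum of inputs, exact).
#' @seealso [decompose_union()], [product_layout()]
#' @export
#' @examples
#' union_layout(list(3, 5))$offsets  # 0, 3
union_layout <- function(input_cardinalities) {
  inputs <- lapply(as.list(input_cardinalities), sn_coerce)
  if (length(inputs) == 0L) stop("union layout needs >= 1 input", call. = FALSE)
  for (ci in inputs) {
    if (sn_cmp(ci, 1) < 0) stop("input cardinalities must be >= 1", call. = FALSE)
  }
  offsets <- vector("list", length(inputs))
  acc <- 0
  for (i in seq_along(inputs)) {
    offsets[[i]] <- acc
    acc <- sn_add(acc, inputs[[i]])
  }
  structure(list(inputs = inputs, offsets = offsets, total = acc),
            class = "union_layout")
}

check_state_range <- function(s, total, what = "state") {
  if (sn_cmp(s, 0) < 0 || sn_cmp(s, total) >= 0) {
    stop(sprintf("%s %s out of range [0, %s)", what, sn_format(s),
                 sn_format(total)), call. = FALSE)
  }
}

#' Decompose a state over a Cartesian-product layout
#'
#' Splits a state into the operation's internal state and one component
#' state per input, by mixed-radix decomposition. The internal state is the
#' least significant digit; inputs follow in declaration order with
#' increasing significance. Exact inverse of [compose_product()].
#'
#' @param s State: non-negative exact integer (numeric, decimal string, or
#'   bigint), `0 <= s < layout$total`.
#' @param layout A [product_layout()].
#' @return List with `internal` and `components` (list, one state per
#'   input).
#' @export
#' @examples
#' decompose_product(5, product_layout(2, list(3)))  # internal 1, component 2
decompose_product <- function(s, layout) {
  stopifnot(inherits(layout, "product_layout"))
  s <- sn_coerce(s)
  check_state_range(s, layout$total)
  dm <- sn_divmod(s, layout$internal)
  internal <- dm$r
  rem <- dm$q
  k <- length(layout$inputs)
  components <- vector("list", k)
  for (i in seq_len(k)) {
    dm <- sn_divmod(rem, layout$inputs[[i]])
    components[[i]] <- dm$r
    rem <- dm$q
  }
  list(internal = internal, components = components)
}

#' Compose a state over a Cartesian-product layout
#'
#' Exact inverse of [decompose_product()].
#'
#' @param internal Internal-state digit, `0 <= internal < layout$internal`.
#' @param components List of component states, one per input, each within
#'   its input's cardinality.
#' @param layout A [product_layout()].
#' @return The composed state (numeric if below 2^53, bigint otherwise).
#' @export
compose_product <- function(internal, components, layout) {
  stopifnot(inherits(layout, "product_layout"))
  internal <- sn_coerce(internal)
  components <- lapply(components, sn_coerce)
  if (length(components) != length(layout$inputs)) {
    stop("need one component state per input", call. = FALSE)
  }
  check_state_range(internal, layout$internal, "internal state")
  for (i in seq_along(components)) {
    check_state_range(components[[i]], layout$inputs[[i]],
                      sprintf("component state %d", i))
  }
  s <- 0
  for (i in rev(seq_along(components))) {
    s <- sn_add(sn_mul(s, layout$inputs[[i]]), components[[i]])
  }
  sn_add(sn_mul(s, layout$internal), internal)
}

#' Decompose a state over a disjoint-union layout
#'
#' Selects the unique input branch whose offset interval contains `s`. The
#' active branch receives `s - offset`; all other slots carry the inactive
#' marker (`NULL`). There is no internal state.
#'
#' @param s State, `0 <= s < layout$total`.
#' @param layout A [union_layout()].
#' @return List with `branch` (1-based active input index), `state` (the
#'   branch-local state), and `components` (list with `NULL` in every
#'   inactive slot).
#' @export
#' @examples
#' decompose_union(4, union_layout(list(3, 5)))  # branch 2, state 1
decompose_union <- function(s, layout) {
  stopifnot(inherits(layout, "union_layout"))
  s <- sn_coerce(s)
  check_state_range(s, layout$total)
  k <- length(layout$inputs)
  branch <- k
  for (i in seq_len(k - 1L)) {
    if (sn_cmp(s, layout$offsets[[i + 1L]]) < 0) {
      branch <- i
      break
    }
  }
  local <- sn_sub(s, layout$offsets[[branch]])
  components <- vector("list", k)
  components[[branch]] <- local
  list(branch = branch, state = local, components = components)
}

#' Compose a state over a disjoint-union layout
#'
#' Exact inverse of [decompose_union()].
#'
#' @param branch 1-based index of the active input.
#' @param state Branch-local state.
#' @param layout A [union_layout()].
#' @return The composed state.
#' @export
compose_union <- function(branch, state, layout) {
  stopifnot(inherits(layout, "union_layout"))
  branch <- as.integer(branch)
  if (branch < 1L || branch > length(layout$inputs)) {
    stop("branch index out of range", call. = FALSE)
  }
  state <- sn_coerce(state)
  check_state_range(state, layout$inputs[[branch]], "branch-local state")
  sn_add(layout$offsets[[branch]], state)
}
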