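# Pools, the operation contract, and lazy per-state sequence generation.
#
# A Pool is a node of a directed acyclic graph and is produced by exactly
# one operation; here the two are unified in one environment ("pool"),
# since every operation returns exactly one pool. Pools are lazy: building
# a DAG and querying its size never constructs a sequence. Generating the
# sequence for a state runs a backward pass (the state is decomposed,
# node by node, into internal states and component states per the layouts
# in statetracker.R) fused with a forward pass (each node builds its
# output from its internal state and its inputs' sequences). The result -
# sequence, name, design card - is a pure function of (pool, state,
# master seed).

`%||%` <- function(a, b) if (is.null(a)) b else a

.oligopool_env <- new.env(parent = emptyenv())
.oligopool_env$gen_count <- 0

# Number of sequence constructions performed so far (instrumentation used
# to verify that size queries are purely algebraic).
generation_count <- function() .oligopool_env$gen_count

#' Create an operation node (extensibility hook)
#'
#' All built-in operations are made with this constructor; custom
#' operations get state tracking, naming, design cards, and rendering for
#' free by supplying a `construct` function.
#'
#' @param kind Short operation-kind label (used in node ids and `print_dag`).
#' @param mode One of `"sequential"`, `"random"`, `"fixed"`. Fixed-mode
#'   operations must have internal cardinality 1; random-mode operations
#'   must declare an explicit sample count as their internal cardinality
#'   (all state spaces are finite).
#' @param inputs List of input pools (state-consuming, declaration order).
#' @param internal_cardinality Number of internal variants, or a function
#'   `function(node)` resolved (once) at the first size query.
#' @param construct `function(node, istate, seqs, ctx)` returning
#'   `list(seq = <tagged_seq>, card = <named list or NULL>)`. `seqs` is the
#'   list of input sequences; `ctx` has `$state` (the state this node
#'   received) and `$seed` (the master seed).
#' @param layout `"product"` (Cartesian product of internal x inputs,
#'   mixed-radix), `"union"` (disjoint union over inputs), `"diagonal"`
#'   (the received state is passed to the single input unchanged *and*
#'   kept as the internal state), or `"remap"` (output state i maps to
#'   input state `map_state(node, i)`).
#' @param prefix Optional name-token prefix; prefixed operations
#'   contribute `prefix_<internal state>` tokens to sequence names.
#' @param tracked Character vector of design-card variable names this
#'   operation records.
#' @param params Parameter list kept for design-file serialization.
#' @param aux_inputs Named list of auxiliary pools consumed by internal
#'   sampling rather than by state digits (e.g. motif pools of a
#'   multi-site scan).
#' @param labels Branch labels (union layout only).
#' @param map_state `function(node, s)` for remap layout.
#' @return A pool (environment of class `"pool"`).
#' @export
new_operation <- function(kind,
                          mode = c("sequential", "random", "fixed"),
                          inputs = list(),
                          internal_cardinality = 1,
                          construct = NULL,
                          layout = c("product", "union", "diagonal", "remap"),
                          prefix = NULL,
                          tracked = character(0),
                          params = list(),
                          aux_inputs = list(),
                          labels = NULL,
                          map_state = NULL) {
  mode <- match.arg(mode)
  layout <- match.arg(layout)
  for (p in c(inputs, aux_inputs)) {
    if (!is_pool(p)) stop("inputs must be pools", call. = FALSE)
  }
  if (!is.function(internal_cardinality)) {
    internal_cardinality <- sn_coerce(internal_cardinality)
    # remap layouts have no internal state either; their cardinality is
    # the size of the index map
    if (mode == "fixed" && layout != "remap" &&
        sn_cmp(internal_cardinality, 1) != 0L) {
      stop("fixed-mode operations have no internal state ",
           "(internal cardinality must be 1)", call. = FALSE)
    }
  }
  if (layout %in% c("diagonal", "remap") && length(inputs) != 1L) {
    stop(layout, " layout requires exactly one input", call. = FALSE)
  }
  if (layout == "union" && length(inputs) < 1L) {
    stop("union layout requires at least one input", call. = FALSE)
  }
  node <- new.env(parent = emptyenv())
  node$kind <- kind
  node$mode <- mode
  node$layout <- layout
  node$inputs <- inputs
  node$aux_inputs <- aux_inputs
  node$internal <- internal_cardinality
  node$construct <- construct
  node$prefix <- prefix
  node$tracked <- tracked
  node$params <- params
  node$labels <- labels
  node$map_state <- map_state
  node$qualifier <- prefix %||% kind
  node$id <- node_id_for(node)
  class(node) <- "pool"
  node
}

is_pool <- function(x) inherits(x, "pool")

# Stable, process-independent node identifier derived from the subtree
# structure (kind, prefix, parameter digest, input ids) - never from
# runtime memory identity, so keyed RNG streams reproduce across sessions.
node_id_for <- function(node) {
  digest <- paste(vapply(node$params, function(p) {
    paste(utils::capture.output(utils::str(p, give.head = TRUE)),
          collapse = " ")
  }, character(1)), collapse = ";")
  h <- str_hash(node$kind, node$prefix %||% "", digest,
                paste(vapply(node$inputs, function(p) p$id, character(1)),
                      collapse = ","),
                paste(vapply(node$aux_inputs, function(p) p$id, character(1)),
                      collapse = ","))
  sprintf("%s-%06x", node$kind, h %% 16777216)
}

resolve_internal <- function(node) {
  if (is.function(node$internal)) {
    node$internal <- sn_coerce(node$internal(node))
  }
  node$internal
}

#' Size of a pool
#'
#' Total number of sequences indexed by the pool, computed purely from the
#' layout algebra - no sequence is constructed. (The one documented
#' exception: a `filter_pool()` must materialize its kept-state index on
#' first query, which requires generating its parent's sequences.)
#'
#' @param p A pool.
#' @return Exact cardinality (numeric if below 2^53, bigint otherwise).
#' @export
#' @examples
#' pool_size(from_seq("ACGT"))  # 1
pool_size <- function(p) {
  stopifnot(is_pool(p))
  if (!is.null(p$.size)) return(p$.size)
  internal <- resolve_internal(p)
  size <- switch(p$layout,
    product = {
      tot <- internal
      for (q in p$inputs) tot <- sn_mul(tot, pool_size(q))
      tot
    },
    union = {
      tot <- 0
      for (q in p$inputs) tot <- sn_add(tot, pool_size(q))
      tot
    },
    diagonal = pool_size(p$inputs[[1L]]),
    remap = internal
  )
  p$.size <- size
  size
}

tok_width <- function(node) {
  if (!is.null(node$.tok_width)) return(node$.tok_width)
  card <- if (node$layout == "diagonal") {
    pool_size(node$inputs[[1L]])
  } else {
    resolve_internal(node)
  }
  w <- max(2L, nchar(sn_format(sn_sub(card, 1))))
  node$.tok_width <- w
  w
}

pad_state <- function(s, width) {
  txt <- sn_format(s)
  if (nchar(txt) >= width) txt else {
    paste0(strrep("0", width - nchar(txt)), txt)
  }
}

own_token <- function(node, istate) {
  if (is.null(node$prefix)) return(character(0))
  card <- if (node$layout == "diagonal") {
    pool_size(node$inputs[[1L]])
  } else {
    resolve_internal(node)
  }
  if (!is_bigint(card) && card == 1) return(node$prefix)
  paste0(node$prefix, "_", pad_state(istate, tok_width(node)))
}

qualify <- function(node, card) {
  if (is.null(card) || length(card) == 0L) return(NULL)
  names(card) <- paste0(node$qualifier, ".", names(card))
  card
}

# Design-card column names contributed by the subtree rooted at `node`.
card_schema <- function(node) {
  if (!is.null(node$.schema)) return(node$.schema)
  own <- if (length(node$tracked)) {
    paste0(node$qualifier, ".", node$tracked)
  } else {
    character(0)
  }
  # aux inputs are sampled internally; their cards do not flow through
  kids <- unlist(lapply(node$inputs, card_schema))
  sch <- if (node$layout == "union") {
    unique(c(own, kids))
  } else {
    unique(c(kids, own))
  }
  node$.schema <- sch
  sch
}

# A prefixed or tracked operation must appear at most once per root-to-leaf
# path (branches of a union are distinct paths and may reuse qualifiers -
# that is what merges their card columns).
validate_qualifiers <- function(node) {
  if (isTRUE(node$.qualok)) return(invisible(TRUE))
  walk <- function(n) {
    own <- if (!is.null(n$prefix) || length(n$tracked)) n$qualifier else NULL
    kid_lists <- lapply(n$inputs, walk)
    quals <- if (n$layout == "union") {
      unique(unlist(kid_lists))
    } else {
      unlist(kid_lists)
    }
    all <- c(quals, own)
    if (n$layout != "union" && anyDuplicated(all)) {
      stop(sprintf(
        "duplicate name prefix / card qualifier '%s' on one path (node %s)",
        all[duplicated(all)][1L], n$id), call. = FALSE)
    }
    all
  }
  walk(node)
  node$.qualok <- TRUE
  invisible(TRUE)
}

# Fused backward (state decomposition) + forward (sequence construction)
# pass. Returns list(seq, tokens, card).
gen_node <- function(node, s, seed) {
  if (node$layout == "union") {
    k <- length(node$inputs)
    internal <- resolve_internal(node)  # noop; unions have internal 1
    branch <- k
    acc <- 0
    for (i in seq_len(k)) {
      nx <- sn_add(acc, pool_size(node$inputs[[i]]))
      if (sn_cmp(s, nx) < 0) { branch <- i; break }
      acc <- nx
    }
    child <- gen_node(node$inputs[[branch]], sn_sub(s, acc), seed)
    label <- node$labels[[branch]]
    card <- c(qualify(node, list(component = label)), child$card)
    # inactive branches contribute null-valued card columns
    for (i in seq_len(k)) {
      if (i == branch) next
      for (col in card_schema(node$inputs[[i]])) {
        if (!col %in% names(card)) card[[col]] <- NA
      }
    }
    return(list(seq = child$seq, tokens = c(label, child$tokens),
                card = card))
  }

  if (node$layout == "remap") {
    pool_size(node)  # ensure any lazy index map is materialized
    ps <- node$map_state(node, s)
    child <- gen_node(node$inputs[[1L]], ps, seed)
    card <- c(child$card, qualify(node, list(parent_state = ps)))
    tokens <- c(child$tokens, own_token(node, s))
    return(list(seq = child$seq, tokens = tokens, card = card))
  }

  if (node$layout == "diagonal") {
    child <- gen_node(node$inputs[[1L]], s, seed)
    .oligopool_env$gen_count <- .oligopool_env$gen_count + 1
    out <- node$construct(node, s, list(child$seq),
                          list(state = s, seed = seed))
    card <- c(child$card, qualify(node, out$card))
    tokens <- c(child$tokens, own_token(node, s))
    return(list(seq = out$seq, tokens = tokens, card = card))
  }

  # product layout
  internal <- resolve_internal(node)
  dm <- sn_divmod(s, internal)
  istate <- dm$r
  rem <- dm$q
  k <- length(node$inputs)
  seqs <- vector("list", k)
  tokens <- character(0)
  card <- NULL
  for (i in seq_len(k)) {
    dm <- sn_divmod(rem, pool_size(node$inputs[[i]]))
    child <- gen_node(node$inputs[[i]], dm$r, seed)
    rem <- dm$q
    seqs[[i]] <- child$seq
    tokens <- c(tokens, child$tokens)
    card <- c(card, child$card)
  }
  .oligopool_env$gen_count <- .oligopool_env$gen_count + 1
  out <- node$construct(node, istate, seqs, list(state = s, seed = seed))
  if (is.null(out$seq)) {
    stop(sprintf("construction failed at node %s, state %s",
                 node$id, sn_format(s)), call. = FALSE)
  }
  list(seq = out$seq, tokens = c(tokens, own_token(node, istate)),
       card = c(card, qualify(node, out$card)))
}

#' Generate one sequence from a pool
#'
#' Runs the backward state-assignment pass and the forward construction
#' pass for state `s`. Pure in `(p, s, master_seed)`: repeated calls, in
#' any order and in any process, return identical results. The caller's
#' RNG state is preserved.
#'
#' @param p A pool.
#' @param s State, `0 <= s < pool_size(p)` (numeric, decimal string, or
#'   bigint).
#' @param master_seed Integer master seed for all random-mode draws
#'   (sequential- and fixed-mode output does not depend on it).
#' @return A `generation_result`: list with `name`, `seq` (a
#'   `tagged_seq`), `card` (named list), and `state`.
#' @export
#' @examples
#' p <- from_seq("AC<x/>GT")
#' generate(p, 0)$name
generate <- function(p, s, master_seed = 0) {
  stopifnot(is_pool(p))
  validate_qualifiers(p)
  s <- sn_coerce(s)
  total <- pool_size(p)
  if (sn_cmp(s, total) >= 0) {
    stop(sprintf("state %s out of range for pool %s of size %s",
                 sn_format(s), p$id, sn_format(total)), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  r <- gen_node(p, s, master_seed)
  name <- if (length(r$tokens)) {
    paste(r$tokens, collapse = ".")
  } else {
    w <- max(2L, nchar(sn_format(sn_sub(total, 1))))
    paste0("s", pad_state(s, w))
  }
  structure(list(name = name, seq = r$seq, card = as.list(r$card),
                 state = s),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat(x$name, " ", render_ansi(x$seq), "\n", sep = "")
  if (length(x$card)) {
    vals <- vapply(x$card, function(v) {
      if (length(v) == 0L || all(is.na(v))) "NA" else paste(v, collapse = ";")
    }, character(1))
    cat("  ", paste(names(x$card), vals, sep = "=", collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Print the DAG of a pool
#'
#' Deterministic indented text listing of every node - operation kind,
#' mode, cardinality, and inputs - topologically ordered with leaves
#' first.
#'
#' @param p The root pool.
#' @return The text lines, invisibly; printed as a side effect.
#' @export
print_dag <- function(p) {
  stopifnot(is_pool(p))
  nodes <- list()
  visit <- function(n) {
    for (seen in nodes) if (identical(seen, n)) return(invisible(NULL))
    for (q in n$inputs) visit(q)
    for (q in n$aux_inputs) visit(q)
    for (seen in nodes) if (identical(seen, n)) return(invisible(NULL))
    nodes[[length(nodes) + 1L]] <<- n
  }
  visit(p)
  idx_of <- function(n) {
    for (i in seq_along(nodes)) if (identical(nodes[[i]], n)) return(i)
    NA_integer_
  }
  lines <- vapply(seq_along(nodes), function(i) {
    n <- nodes[[i]]
    ins <- vapply(n$inputs, idx_of, integer(1))
    aux <- vapply(n$aux_inputs, idx_of, integer(1))
    intxt <- if (length(ins) || length(aux)) {
      paste0("  inputs=[",
             paste(c(sprintf("%d", ins), sprintf("~%d", aux)),
                   collapse = ","), "]")
    } else {
      ""
    }
    sprintf("[%d] %-16s mode=%-10s size=%s%s%s",
            i, n$kind, n$mode, sn_format(pool_size(n)), intxt,
            if (identical(n, p)) "  <- root" else "")
  }, character(1))
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}

#' @export
print.pool <- function(x, ...) {
  cat(sprintf("<pool %s> kind=%s mode=%s size=%s\n",
              x$id, x$kind, x$mode, sn_format(pool_size(x))))
  invisible(x)
}

#' Sample sequences from a pool
#'
#' Draws `n` states without replacement (seeded, reproducible) and returns
#' their generation results; useful for auditing a design before
#' generating the full library.
#'
#' @param p A pool.
#' @param n Number of sequences to sample (`n >= 1`). If `n` is at least
#'   the pool size, all states are returned in order, with a warning when
#'   `n` is strictly larger.
#' @param master_seed Master seed (also keys the state draw).
#' @return List of `generation_result`s.
#' @export
sample_library <- function(p, n, master_seed = 0) {
  stopifnot(is_pool(p), n >= 1)
  total <- pool_size(p)
  if (!is_bigint(total) && n >= total) {
    if (n > total) {
      warning(sprintf("n = %d exceeds pool size %s; returning all states",
                      n, sn_format(total)), call. = FALSE)
    }
    states <- seq_len(total) - 1
  } else {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    seed_stream(master_seed, p$id, 0, "sample_library")
    if (!is_bigint(total) && total <= 1e7) {
      states <- sort(sample.int(total, n) - 1)
    } else {
      # rejection-free enough at these scales: draw digit-wise and dedupe
      states <- list()
      while (length(states) < n) {
        cand <- random_state_below(total)
        if (!any(vapply(states, function(x) sn_cmp(x, cand) == 0L,
                        logical(1)))) {
          states[[length(states) + 1L]] <- cand
        }
      }
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  lapply(states, function(s) generate(p, s, master_seed))
}

# Uniform state in [0, total) using the current RNG stream.
random_state_below <- function(total) {
  if (!is_bigint(total)) return(floor(stats::runif(1) * total))
  repeat {
    digs <- floor(stats::runif(length(unclass(total))) * .BI_BASE)
    cand <- sn_demote(new_bigint(digs))
    if (sn_cmp(cand, total) < 0) return(cand)
  }
}
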