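# File export and declarative design files.

#' Export a pool to FASTA
#'
#' One record per state in state order; headers are the automatic
#' sequence names; sequences are the plain characters (no tags or
#' styles), wrapped at 60 columns. Written in chunks via Biostrings, so
#' large pools stream without holding the whole library in memory.
#'
#' @param p A pool.
#' @param path Output path.
#' @param states Optional subset/order of states (default: all).
#' @param master_seed Master seed.
#' @param chunk_size States per write chunk.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(p, path, states = NULL, master_seed = 0,
                         chunk_size = 10000) {
  stopifnot(is_pool(p))
  if (is.null(states)) {
    total <- pool_size(p)
    if (is_bigint(total)) {
      stop("pool too large to export in full; pass explicit states",
           call. = FALSE)
    }
    states <- seq_len(total) - 1
  }
  first <- TRUE
  for (lo in seq(1, length(states), by = chunk_size)) {
    idx <- states[lo:min(lo + chunk_size - 1, length(states))]
    results <- lapply(idx, function(s) generate(p, s, master_seed))
    set_ <- Biostrings::DNAStringSet(
      vapply(results, function(r) r$seq$chars, character(1)))
    names(set_) <- vapply(results, function(r) r$name, character(1))
    Biostrings::writeXStringSet(set_, path, append = !first, width = 60L)
    first <- FALSE
  }
  invisible(path)
}

#' Export design cards to CSV
#'
#' UTF-8 CSV with header row; list-valued card entries are
#' semicolon-joined; row order is state order.
#'
#' @inheritParams export_fasta
#' @return `path`, invisibly.
#' @export
export_cards <- function(p, path, states = NULL, master_seed = 0) {
  tab <- compile_cards(p, states = states, master_seed = master_seed)
  utils::write.csv(tab, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Declarative design files: a YAML serialization of DAGs.
#
# Schema:
#   master_seed: <int>           (optional, default 0)
#   root: <id>
#   nodes:
#     - id: <unique id>
#       op: <operation kind>
#       inputs: [<id>, ...]      (insert_multiscan: template first, then sites)
#       params: {...}            (constructor arguments)

# YAML 1.1 parses a bare `n` key as boolean FALSE; restore it.
fix_yaml_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) names(x)[names(x) == "FALSE"] <- "n"
    x <- lapply(x, fix_yaml_keys)
  }
  x
}

design_registry <- function() {
  list(
    from_seqs = function(inputs, params) {
      do.call(from_seqs, c(list(texts = params$texts %||% params$text),
                           params[intersect(names(params),
                                            c("style", "prefix"))]))
    },
    from_pwm = function(inputs, params) {
      pwm <- do.call(rbind, lapply(params$pwm, as.numeric))
      do.call(from_pwm, c(list(pwm = pwm, n = params$n),
                          params[intersect(names(params),
                                           c("style", "prefix"))]))
    },
    from_iupac = function(inputs, params) {
      do.call(from_iupac, c(list(motif = params$motif),
                            params[intersect(names(params),
                                             c("style", "prefix"))]))
    },
    random_kmers = function(inputs, params) {
      do.call(random_kmers, params[intersect(names(params),
                                             c("k", "n", "style", "prefix"))])
    },
    mutagenize = function(inputs, params) {
      do.call(mutagenize,
              c(list(parent = inputs[[1]]),
                params[intersect(names(params),
                                 c("scheme", "region", "positions", "rate",
                                   "n", "prefix", "style"))]))
    },
    mutagenize_orf = function(inputs, params) {
      do.call(mutagenize_orf,
              c(list(parent = inputs[[1]]),
                params[intersect(names(params),
                                 c("scheme", "region", "positions", "rate",
                                   "n", "codon_policy", "prefix", "style"))]))
    },
    delete_scan = function(inputs, params) {
      do.call(delete_scan,
              c(list(parent = inputs[[1]]),
                params[intersect(names(params),
                                 c("region", "window", "prefix", "style"))]))
    },
    flip = function(inputs, params) {
      flip(inputs[[1]], prefix = params$prefix)
    },
    shuffle = function(inputs, params) {
      shuffle_region(inputs[[1]], n = params$n, region = params$region,
                     prefix = params$prefix)
    },
    recombine = function(inputs, params) {
      recombine(inputs[[1]], inputs[[2]],
                n_crossovers = params$n_crossovers, n = params$n,
                prefix = params$prefix)
    },
    get_barcodes = function(inputs, params) {
      do.call(get_barcodes,
              c(list(parent = inputs[[1]]),
                params[intersect(names(params),
                                 c("region", "length", "prefix", "style"))]))
    },
    stylize = function(inputs, params) {
      do.call(stylize,
              c(list(parent = inputs[[1]]),
                params[intersect(names(params),
                                 c("region", "fg", "bg", "bold",
                                   "underline"))]))
    },
    edit_seq = function(inputs, params) {
      do.call(edit_seq,
              c(list(parent = inputs[[1]]),
                params[intersect(names(params),
                                 c("start", "end", "replacement", "region",
                                   "style"))]))
    },
    insert_at = function(inputs, params) {
      do.call(insert_at,
              c(list(parent = inputs[[1]], payload = inputs[[2]]),
                params[intersect(names(params),
                                 c("region", "offsets", "prefix"))]))
    },
    insert_multiscan = function(inputs, params) {
      sites <- inputs[-1]
      names(sites) <- as.character(params$labels)
      do.call(insert_multiscan,
              c(list(template = inputs[[1]], sites = sites),
                params[intersect(names(params),
                                 c("region", "n", "max_rejections",
                                   "prefix"))]))
    },
    join = function(inputs, params) do.call(join_pools, inputs),
    stack = function(inputs, params) {
      stack_pools(inputs, labels = as.character(params$labels),
                  prefix = params$prefix)
    },
    `repeat` = function(inputs, params) {
      repeat_pool(inputs[[1]], n = params$n, prefix = params$prefix)
    },
    select = function(inputs, params) {
      select_states(inputs[[1]], indices = as.numeric(params$indices),
                    prefix = params$prefix)
    },
    reorder = function(inputs, params) {
      reorder_states(inputs[[1]], permutation = as.numeric(params$permutation),
                     prefix = params$prefix)
    }
  )
}

#' Validate a design list or file
#'
#' Schema check only: unique ids, resolvable references, known operation
#' kinds, acyclicity, exactly one root. Does not instantiate the DAG.
#'
#' @param x A design list, or a path to a YAML design file.
#' @return `TRUE`, invisibly; errors carry node-id context.
#' @export
validate_design <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  x <- fix_yaml_keys(x)
  if (is.null(x$nodes) || !length(x$nodes)) {
    stop("design has no nodes", call. = FALSE)
  }
  ids <- vapply(x$nodes, function(nd) as.character(nd$id %||% ""),
                character(1))
  if (any(!nzchar(ids))) stop("every node needs an id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate node id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  if (is.null(x$root)) stop("design has no root", call. = FALSE)
  if (!x$root %in% ids) {
    stop("root '", x$root, "' is not a node id", call. = FALSE)
  }
  known <- names(design_registry())
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  byid <- stats::setNames(x$nodes, ids)
  walk <- function(id) {
    if (state[[id]] == 1L) {
      stop("cycle detected at node '", id, "'", call. = FALSE)
    }
    if (state[[id]] == 2L) return(invisible(NULL))
    state[[id]] <<- 1L
    nd <- byid[[id]]
    if (!(nd$op %in% known)) {
      stop("node '", id, "': unknown operation '", nd$op, "'",
           call. = FALSE)
    }
    for (ref in nd$inputs %||% list()) {
      if (!ref %in% ids) {
        stop("node '", id, "': unresolved input '", ref, "'",
             call. = FALSE)
      }
      walk(ref)
    }
    state[[id]] <<- 2L
  }
  for (id in ids) walk(id)
  invisible(TRUE)
}

#' Build a pool from a design file
#'
#' Constructs the DAG described by a YAML design file (or an equivalent
#' list). The same file and master seed always yield an identical
#' library.
#'
#' @param x Path to a YAML design file, or a design list.
#' @return The root pool; the file's `master_seed` (default 0) is
#'   attached as attribute `"master_seed"`.
#' @export
build_from_design <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  x <- fix_yaml_keys(x)
  validate_design(x)
  registry <- design_registry()
  ids <- vapply(x$nodes, function(nd) as.character(nd$id), character(1))
  byid <- stats::setNames(x$nodes, ids)
  built <- new.env(parent = emptyenv())
  build <- function(id) {
    if (exists(id, envir = built, inherits = FALSE)) {
      return(get(id, envir = built))
    }
    nd <- byid[[id]]
    inputs <- lapply(nd$inputs %||% list(), build)
    pool <- registry[[nd$op]](inputs, nd$params %||% list())
    pool$design_id <- id
    built[[id]] <- pool
    pool
  }
  root <- build(x$root)
  attr(root, "master_seed") <- x$master_seed %||% 0
  root
}

#' Serialize a pool's DAG to a design list or YAML file
#'
#' Inverse of [build_from_design()] for the serializable operation
#' catalog (filters carry arbitrary R predicates and cannot be
#' serialized).
#'
#' @param p The root pool.
#' @param path Optional YAML output path; when `NULL` the design list is
#'   returned.
#' @param master_seed Master seed to record in the design.
#' @return The design list (invisibly when `path` is given).
#' @export
design_to_list <- function(p, path = NULL, master_seed = 0) {
  stopifnot(is_pool(p))
  nodes <- list()
  order_ <- list()
  visit <- function(n) {
    for (seen in order_) if (identical(seen, n)) return(invisible(NULL))
    for (q in n$inputs) visit(q)
    for (q in n$aux_inputs) visit(q)
    for (seen in order_) if (identical(seen, n)) return(invisible(NULL))
    order_[[length(order_) + 1L]] <<- n
  }
  visit(p)
  id_of <- function(n) {
    for (i in seq_along(order_)) {
      if (identical(order_[[i]], n)) {
        return(order_[[i]]$design_id %||% sprintf("n%d_%s", i, n$kind))
      }
    }
  }
  op_name <- function(n) if (n$kind == "repeat") "repeat" else n$kind
  for (i in seq_along(order_)) {
    n <- order_[[i]]
    if (!op_name(n) %in% names(design_registry())) {
      stop("operation '", n$kind, "' cannot be serialized", call. = FALSE)
    }
    params <- n$params
    params$card_vars <- NULL
    if (!is.null(params$pwm)) {
      params$pwm <- lapply(seq_len(nrow(params$pwm)),
                           function(r) as.numeric(params$pwm[r, ]))
    }
    params <- params[!vapply(params, is.null, logical(1))]
    entry <- list(id = id_of(n), op = op_name(n))
    ins <- c(n$inputs, unname(n$aux_inputs))
    if (length(ins)) {
      entry$inputs <- lapply(ins, id_of)
    }
    if (length(params)) entry$params <- params
    nodes[[length(nodes) + 1L]] <- entry
  }
  design <- list(master_seed = master_seed, root = id_of(p), nodes = nodes)
  if (!is.null(path)) {
    yaml::write_yaml(design, path)
    return(invisible(design))
  }
  design
}
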