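# Design cards and tabular compilation.
#
# Every tracked operation on the active path of a generated sequence
# contributes its tracked variables, qualified by the operation's prefix
# (or kind), e.g. "mut.positions". Operations on inactive union branches
# contribute nulls, so compiled tables are rectangular and usable directly
# as downstream covariates.

#' Compile design cards into a table
#'
#' One row per generated state with columns `name`, `sequence`, then the
#' union of all card variables in first-appearance order. Multi-valued
#' entries are collapsed with `";"`; variables missing from a row (e.g.
#' on an inactive branch) are `NA`.
#'
#' @param x A pool, or a list of `generation_result`s from one root pool.
#' @param states States to compile when `x` is a pool (default: all).
#' @param master_seed Master seed used when `x` is a pool.
#' @return A [tibble::tibble()].
#' @export
#' @examples
#' compile_cards(from_seqs(c("AC", "GT")))
compile_cards <- function(x, states = NULL, master_seed = 0) {
  if (is_pool(x)) {
    if (is.null(states)) {
      total <- pool_size(x)
      if (is_bigint(total) || total > 1e6) {
        stop("pool too large to compile in full; pass explicit states",
             call. = FALSE)
      }
      states <- seq_len(total) - 1
    }
    results <- lapply(states, function(s) generate(x, s, master_seed))
  } else {
    results <- x
    stopifnot(all(vapply(results, inherits, logical(1),
                         "generation_result")))
  }
  nm <- vapply(results, function(r) r$name, character(1))
  if (anyDuplicated(nm)) {
    stop("integrity error: duplicate sequence names in card table: ",
         nm[duplicated(nm)][1L], call. = FALSE)
  }
  cols <- character(0)
  for (r in results) cols <- union(cols, names(r$card))
  flat <- function(v) {
    if (is.null(v) || length(v) == 0L) return(NA_character_)
    if (length(v) == 1L && is.na(v)) return(NA_character_)
    paste(format(v, trim = TRUE, scientific = FALSE), collapse = ";")
  }
  out <- c(list(name = nm,
                sequence = vapply(results, function(r) r$seq$chars,
                                  character(1))),
           stats::setNames(lapply(cols, function(cn) {
             vapply(results, function(r) flat(r$card[[cn]]), character(1))
           }), cols))
  tibble::as_tibble(out)
}

#' Print a styled listing of a library's first sequences
#'
#' @param p A pool.
#' @param n Number of rows (`n >= 1`); capped at the pool size.
#' @param master_seed Master seed.
#' @param plain If `TRUE`, strip all styling.
#' @return The printed lines, invisibly.
#' @export
print_library <- function(p, n = 10, master_seed = 0, plain = FALSE) {
  stopifnot(is_pool(p))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  total <- pool_size(p)
  k <- if (is_bigint(total)) n else min(n, total)
  results <- lapply(seq_len(k) - 1, function(s) generate(p, s, master_seed))
  names_ <- vapply(results, function(r) r$name, character(1))
  w <- max(nchar(names_))
  lines <- vapply(seq_along(results), function(i) {
    sprintf("%-*s  %s", w, names_[i],
            render_ansi(results[[i]]$seq, plain = plain))
  }, character(1))
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}
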