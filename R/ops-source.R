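# Source operations: create the initial pools of a DAG.

#' Pool of user-specified sequences
#'
#' `from_seq()` wraps a single sequence; `from_seqs()` wraps several (state
#' i yields the i-th sequence). Texts may carry XML-style region tags (see
#' [parse_tagged()]). An optional base style is applied to every character
#' of every sequence, and per-sequence design-card variables can be
#' attached via `card_vars`.
#'
#' @param text,texts Sequence text(s), optionally tagged.
#' @param style Optional named list of style attributes (e.g.
#'   `list(fg = "blue")`) applied to all characters.
#' @param prefix Optional name-token prefix.
#' @param card_vars Optional data frame (one row per sequence) of extra
#'   design-card variables recorded for each member.
#' @return A pool of cardinality `length(texts)`.
#' @export
#' @examples
#' p <- from_seqs(c("ACGT", "AY"))
#' pool_size(p)  # 2
from_seqs <- function(texts, style = NULL, prefix = NULL, card_vars = NULL) {
  texts <- as.character(texts)
  if (length(texts) < 1L) stop("need at least one sequence", call. = FALSE)
  parsed <- lapply(texts, parse_tagged)
  if (!is.null(style)) {
    parsed <- lapply(parsed, function(s) {
      do.call(overlay_style, c(list(s, 0, nchar(s$chars)), style))
    })
  }
  if (!is.null(card_vars)) {
    card_vars <- as.data.frame(card_vars)
    stopifnot(nrow(card_vars) == length(texts))
  }
  tracked <- c(if (length(texts) > 1L) "index", names(card_vars))
  node <- new_operation(
    kind = "from_seqs", mode = "sequential",
    internal_cardinality = length(texts),
    prefix = prefix, tracked = tracked %||% character(0),
    params = list(texts = texts, style = style, prefix = prefix,
                  card_vars = card_vars),
    construct = function(node, istate, seqs, ctx) {
      i <- istate + 1
      card <- if (length(node$params$texts) > 1L) list(index = istate)
      cv <- node$params$card_vars
      if (!is.null(cv)) card <- c(card, as.list(cv[i, , drop = FALSE]))
      list(seq = node$.parsed[[i]], card = card)
    })
  node$.parsed <- parsed
  node
}

#' @rdname from_seqs
#' @export
from_seq <- function(text, style = NULL, prefix = NULL) {
  from_seqs(text, style = style, prefix = prefix)
}

#' Pool of sequences sampled from a position weight matrix
#'
#' A random-mode source: state i draws one sequence column-wise from the
#' PWM, with draws keyed by (master seed, node, i) so every member is
#' reproducible in isolation.
#'
#' @param pwm Numeric matrix, positions x 4, columns in A, C, G, T order;
#'   each row must sum to 1 (tolerance 1e-9) with no negative entries.
#' @param n Declared sample count (the pool's cardinality).
#' @param style,prefix See [from_seqs()].
#' @return A pool of cardinality `n`.
#' @export
from_pwm <- function(pwm, n, style = NULL, prefix = NULL) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4L) stop("PWM must have 4 columns (A,C,G,T)", call. = FALSE)
  if (any(pwm < 0) || any(abs(rowSums(pwm) - 1) > 1e-9)) {
    stop("PWM rows must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(n >= 1)
  node <- new_operation(
    kind = "from_pwm", mode = "random", internal_cardinality = n,
    prefix = prefix, tracked = "kmer",
    params = list(pwm = unname(pwm), n = n, style = style, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      chars <- pwm_draw(node, istate, ctx$seed)
      s <- new_tagged(chars)
      if (!is.null(node$params$style)) {
        s <- do.call(overlay_style,
                     c(list(s, 0, nchar(chars)), node$params$style))
      }
      list(seq = s, card = list(kmer = chars))
    })
  node$.cum <- t(apply(pwm, 1L, cumsum))
  node
}

# One keyed PWM draw; shared by generation and by eager batch sampling so
# both produce byte-identical members.
pwm_draw <- function(node, istate, master_seed) {
  seed_stream(master_seed, node$id, istate)
  u <- stats::runif(nrow(node$.cum))
  idx <- rowSums(node$.cum < u) + 1L
  paste(c("A", "C", "G", "T")[idx], collapse = "")
}

.IUPAC_EXPANSIONS <- c(A = "A", C = "C", G = "G", T = "T",
                       M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT",
                       K = "GT", V = "ACG", H = "ACT", D = "AGT",
                       B = "CGT", N = "ACGT")

#' Pool enumerating the expansions of an IUPAC motif
#'
#' Sequential source of cardinality `prod(degeneracies)`; states enumerate
#' expansions mixed-radix with the leftmost position least significant.
#'
#' @param motif String over IUPAC nucleotide codes.
#' @param style,prefix See [from_seqs()].
#' @return A pool.
#' @export
#' @examples
#' pool_size(from_iupac("NN"))  # 16
from_iupac <- function(motif, style = NULL, prefix = NULL) {
  motif <- validate_alphabet(motif, "IUPAC motif")
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  choices <- lapply(.IUPAC_EXPANSIONS[chars], function(s) {
    strsplit(s, "", fixed = TRUE)[[1]]
  })
  radix <- vapply(choices, length, integer(1))
  node <- new_operation(
    kind = "from_iupac", mode = "sequential",
    internal_cardinality = prod(radix),
    prefix = prefix, tracked = "index",
    params = list(motif = motif, style = style, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      rem <- istate
      out <- character(length(node$.choices))
      for (i in seq_along(node$.choices)) {
        r <- node$.radix[i]
        out[i] <- node$.choices[[i]][rem %% r + 1]
        rem <- rem %/% r
      }
      s <- new_tagged(paste(out, collapse = ""))
      if (!is.null(node$params$style)) {
        s <- do.call(overlay_style,
                     c(list(s, 0, length(out)), node$params$style))
      }
      list(seq = s, card = list(index = istate))
    })
  node$.choices <- choices
  node$.radix <- radix
  node
}

#' Pool of uniform random k-mers
#'
#' @param k k-mer length (`k >= 1`).
#' @param n Declared sample count.
#' @param style,prefix See [from_seqs()].
#' @return A pool of cardinality `n`.
#' @export
random_kmers <- function(k, n, style = NULL, prefix = NULL) {
  stopifnot(k >= 1, n >= 1)
  new_operation(
    kind = "random_kmers", mode = "random", internal_cardinality = n,
    prefix = prefix,
    params = list(k = k, n = n, style = style, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      seed_stream(ctx$seed, node$id, istate)
      chars <- paste(sample(c("A", "C", "G", "T"), node$params$k,
                            replace = TRUE), collapse = "")
      s <- new_tagged(chars)
      if (!is.null(node$params$style)) {
        s <- do.call(overlay_style,
                     c(list(s, 0, node$params$k), node$params$style))
      }
      list(seq = s, card = NULL)
    })
}
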