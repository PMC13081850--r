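# Transformation operations: modify sequence content.

# Geometry (region bounds, reading frames, wild-type codons) is measured
# once, at operation build time, from the parent's state-0 sequence under
# master seed 0, and re-validated against each generated parent. This
# keeps cardinalities available without generation while failing loudly if
# an upstream operation makes the geometry state-dependent.
build_template <- function(parent) gen_node(parent, 0, 0)$seq

resolve_span <- function(seq, region) {
  if (is.null(region)) c(0, nchar(seq$chars)) else region_bounds(seq, region)
}

.DNA4 <- c("A", "C", "G", "T")

#' Nucleotide-level mutagenesis
#'
#' In sequential `single` scheme, yields one variant per possible
#' character change at each target position (internal cardinality
#' `3 * length(positions)`): the internal state decodes to (position,
#' substitute) with substitutes enumerated in fixed `A < C < G < T` order
#' minus the current base, substitute varying fastest. In `random` scheme,
#' each target position is mutated independently with probability `rate`
#' and the substitute is uniform over the three alternatives; `n` declares
#' the sample count.
#'
#' @param parent Input pool.
#' @param scheme `"single"` or `"random"`.
#' @param region Optional region name to restrict mutagenesis to.
#' @param positions Optional 0-based positions (relative to the region
#'   start if `region` is given); default all positions in the target.
#' @param rate Per-position mutation probability (random scheme).
#' @param n Sample count (random scheme).
#' @param prefix Name-token prefix.
#' @param style Style attributes applied to mutated characters.
#' @return A pool.
#' @export
mutagenize <- function(parent, scheme = c("single", "random"),
                       region = NULL, positions = NULL,
                       rate = 0.1, n = NULL, prefix = NULL,
                       style = list(fg = "red", bold = TRUE)) {
  scheme <- match.arg(scheme)
  tpl <- build_template(parent)
  b <- resolve_span(tpl, region)
  if (is.null(positions)) positions <- seq_len(b[2] - b[1]) - 1
  if (length(positions) == 0L) stop("empty position set", call. = FALSE)
  if (any(positions < 0) || any(positions >= b[2] - b[1])) {
    stop("positions outside the target region", call. = FALSE)
  }
  internal <- switch(scheme,
                     single = 3 * length(positions),
                     random = {
                       stopifnot(!is.null(n), n >= 1)
                       n
                     })
  new_operation(
    kind = "mutagenize", mode = if (scheme == "single") "sequential" else "random",
    inputs = list(parent), internal_cardinality = internal,
    prefix = prefix, tracked = c("pos", "from", "to"),
    params = list(scheme = scheme, region = region, positions = positions,
                  rate = rate, n = n, prefix = prefix, style = style),
    construct = function(node, istate, seqs, ctx) {
      seq <- seqs[[1]]
      pm <- node$params
      b <- resolve_span(seq, pm$region)
      if (pm$scheme == "single") {
        pidx <- istate %/% 3 + 1
        sidx <- istate %% 3 + 1
        abs_pos <- b[1] + pm$positions[pidx]
        from <- substr(seq$chars, abs_pos + 1, abs_pos + 1)
        to <- setdiff(.DNA4, from)[sidx]
        seq <- apply_edit(seq, abs_pos, abs_pos + 1, to, style = pm$style)
        list(seq = seq, card = list(pos = abs_pos, from = from, to = to))
      } else {
        P <- length(pm$positions)
        seed_stream(ctx$seed, node$id, istate)
        hit <- stats::runif(P) < pm$rate
        pick <- floor(stats::runif(P) * 3) + 1
        pos <- numeric(0); from <- character(0); to <- character(0)
        for (i in which(hit)) {
          abs_pos <- b[1] + pm$positions[i]
          f <- substr(seq$chars, abs_pos + 1, abs_pos + 1)
          t <- setdiff(.DNA4, f)[pick[i]]
          seq <- apply_edit(seq, abs_pos, abs_pos + 1, t, style = pm$style)
          pos <- c(pos, abs_pos); from <- c(from, f); to <- c(to, t)
        }
        list(seq = seq, card = list(pos = pos, from = from, to = to))
      }
    })
}

#' Codon-aware mutagenesis of an open reading frame
#'
#' Generates amino-acid substitution variants of a framed coding span.
#' Schemes:
#' * `single` (sequential): all `P x 19` single-residue substitutions over
#'   the `P` eligible codon positions, substitute residues in alphabetical
#'   single-letter order excluding the wild type, residue varying fastest;
#' * `pairwise` (sequential): all `choose(P, 2) x 19^2` substitutions over
#'   unordered position pairs in lexicographic order;
#' * `random`: each eligible position mutates independently with
#'   probability `rate` to a uniform substitute (zero-mutation draws are
#'   kept - resampling would bias the per-position marginal); `n` declares
#'   the sample count.
#'
#' The codon for a substitute residue is chosen by `codon_policy`;
#' `"missense_only_first"` uses the most frequent codon for that residue
#' in the usage table, so an emitted codon always translates to the
#' intended substitute and never to the wild type.
#'
#' By default all codons are eligible except an initial ATG and a terminal
#' stop. Design-card positions are 1-based residue indices.
#'
#' @param parent Input pool.
#' @param scheme `"single"`, `"pairwise"`, or `"random"`.
#' @param region Region name of the ORF; `NULL` uses the whole sequence.
#'   Span length must be a multiple of 3.
#' @param positions Optional 1-based eligible codon positions.
#' @param rate,n Random-scheme parameters.
#' @param codon_policy Currently `"missense_only_first"`.
#' @param usage Codon-usage table ([load_codon_usage()]); default packaged
#'   human table.
#' @param prefix Name-token prefix.
#' @param style Style applied to mutated codons.
#' @return A pool.
#' @export
mutagenize_orf <- function(parent, scheme = c("single", "pairwise", "random"),
                           region = NULL, positions = NULL,
                           rate = 0.1, n = NULL,
                           codon_policy = "missense_only_first",
                           usage = NULL, prefix = NULL,
                           style = list(fg = "red", bold = TRUE)) {
  scheme <- match.arg(scheme)
  if (codon_policy != "missense_only_first") {
    stop("unknown codon policy: ", codon_policy, call. = FALSE)
  }
  usage <- usage %||% load_codon_usage()
  top <- top_codons(usage)
  tpl <- build_template(parent)
  b <- resolve_span(tpl, region)
  span <- substr(tpl$chars, b[1] + 1, b[2])
  if (nchar(span) %% 3 != 0) {
    stop("frame error: ORF span length ", nchar(span),
         " is not a multiple of 3", call. = FALSE)
  }
  wt_aa <- strsplit(translate_dna(span), "", fixed = TRUE)[[1]]
  n_codons <- length(wt_aa)
  if (is.null(positions)) {
    positions <- seq_len(n_codons)
    if (wt_aa[1] == "M") positions <- positions[-1]
    if (wt_aa[n_codons] == "*") positions <- setdiff(positions, n_codons)
  }
  if (length(positions) == 0L) {
    stop("position exclusion leaves no eligible codons", call. = FALSE)
  }
  if (any(positions < 1) || any(positions > n_codons)) {
    stop("positions outside the ORF (1..", n_codons, ")", call. = FALSE)
  }
  if (any(wt_aa[positions] == "*")) {
    stop("eligible positions must code a standard residue", call. = FALSE)
  }
  P <- length(positions)
  subs <- lapply(positions, function(i) setdiff(.AA20, wt_aa[i]))
  pairs <- if (scheme == "pairwise") {
    if (P < 2L) stop("pairwise scheme needs >= 2 eligible positions",
                     call. = FALSE)
    utils::combn(P, 2)
  }
  internal <- switch(scheme,
                     single = P * 19,
                     pairwise = choose(P, 2) * 361,
                     random = {
                       stopifnot(!is.null(n), n >= 1)
                       n
                     })
  node <- new_operation(
    kind = "mutagenize_orf",
    mode = if (scheme == "random") "random" else "sequential",
    inputs = list(parent), internal_cardinality = internal,
    prefix = prefix, tracked = c("positions", "wt", "sub", "scheme"),
    params = list(scheme = scheme, region = region, positions = positions,
                  rate = rate, n = n, codon_policy = codon_policy,
                  prefix = prefix, style = style),
    construct = function(node, istate, seqs, ctx) {
      seq <- seqs[[1]]
      pm <- node$params
      b <- resolve_span(seq, pm$region)
      if (b[2] - b[1] != 3 * node$.n_codons) {
        stop(sprintf("node %s, state %s: ORF span length changed upstream",
                     node$id, sn_format(ctx$state)), call. = FALSE)
      }
      if (pm$scheme == "single") {
        pidx <- istate %/% 19 + 1
        ridx <- istate %% 19 + 1
        mut_pos <- node$.positions[pidx]
        mut_aa <- node$.subs[[pidx]][ridx]
      } else if (pm$scheme == "pairwise") {
        pair <- istate %/% 361 + 1
        rem <- istate %% 361
        pidx <- node$.pairs[, pair]
        mut_pos <- node$.positions[pidx]
        mut_aa <- c(node$.subs[[pidx[1]]][rem %/% 19 + 1],
                    node$.subs[[pidx[2]]][rem %% 19 + 1])
      } else {
        P <- length(node$.positions)
        seed_stream(ctx$seed, node$id, istate)
        hit <- stats::runif(P) < pm$rate
        pick <- floor(stats::runif(P) * 19) + 1
        mut_pos <- node$.positions[hit]
        mut_aa <- vapply(seq_along(mut_pos), function(j) {
          node$.subs[[which(hit)[j]]][pick[which(hit)[j]]]
        }, character(1))
      }
      for (j in seq_along(mut_pos)) {
        cs <- b[1] + 3 * (mut_pos[j] - 1)
        seq <- apply_edit(seq, cs, cs + 3, node$.top[[mut_aa[j]]],
                          style = pm$style)
      }
      list(seq = seq,
           card = list(positions = mut_pos, wt = node$.wt_aa[mut_pos],
                       sub = mut_aa, scheme = pm$scheme))
    })
  node$.wt_aa <- wt_aa
  node$.n_codons <- n_codons
  node$.positions <- positions
  node$.subs <- subs
  node$.pairs <- pairs
  node$.top <- as.list(top)
  node
}

#' Sliding-window deletion scan over a region
#'
#' Sequential operation with one variant per window placement (internal
#' cardinality `region length - window + 1`); variant i deletes
#' `[start + i, start + i + window)`, collapsing the region by `window`.
#'
#' @param parent Input pool.
#' @param region Region name to scan.
#' @param window Deletion width (`<=` region length).
#' @param prefix Name-token prefix.
#' @param style Style applied to the remaining characters of the scanned
#'   region (a visual cue for the deletion).
#' @return A pool.
#' @export
delete_scan <- function(parent, region, window, prefix = NULL,
                        style = list(fg = "green")) {
  tpl <- build_template(parent)
  b <- region_bounds(tpl, region)
  L <- b[2] - b[1]
  if (window < 1 || window > L) {
    stop("window must be in [1, region length = ", L, "]", call. = FALSE)
  }
  new_operation(
    kind = "delete_scan", mode = "sequential",
    inputs = list(parent), internal_cardinality = L - window + 1,
    prefix = prefix, tracked = c("del_start", "window"),
    params = list(region = region, window = window, prefix = prefix,
                  style = style),
    construct = function(node, istate, seqs, ctx) {
      seq <- seqs[[1]]
      pm <- node$params
      b <- region_bounds(seq, pm$region)
      s0 <- b[1] + istate
      seq <- apply_edit(seq, s0, s0 + pm$window, "")
      if (!is.null(pm$style)) {
        b2 <- region_bounds(seq, pm$region)
        if (b2[2] > b2[1]) {
          seq <- do.call(overlay_style,
                         c(list(seq, b2[1], b2[2]), pm$style))
        }
      }
      list(seq = seq, card = list(del_start = istate, window = pm$window))
    })
}

#' Both orientations of a pool
#'
#' Internal state 0 keeps the forward sequence, 1 yields its reverse
#' complement; pool size doubles.
#'
#' @param parent Input pool.
#' @param prefix Name-token prefix.
#' @return A pool.
#' @export
flip <- function(parent, prefix = NULL) {
  new_operation(
    kind = "flip", mode = "sequential", inputs = list(parent),
    internal_cardinality = 2, prefix = prefix, tracked = "orientation",
    params = list(prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      if (istate == 0) {
        list(seq = seqs[[1]], card = list(orientation = "fwd"))
      } else {
        list(seq = reverse_complement(seqs[[1]]),
             card = list(orientation = "rev"))
      }
    })
}

#' Random within-region shuffles
#'
#' Each internal state applies one uniformly random permutation (keyed
#' RNG) to the characters of the target span. Style runs keep their
#' coordinates: styling follows positions, not characters, under a
#' shuffle.
#'
#' @param parent Input pool.
#' @param n Sample count.
#' @param region Region to shuffle; `NULL` shuffles the whole sequence.
#' @param prefix Name-token prefix.
#' @return A pool.
#' @export
shuffle_region <- function(parent, n, region = NULL, prefix = NULL) {
  stopifnot(n >= 1)
  new_operation(
    kind = "shuffle", mode = "random", inputs = list(parent),
    internal_cardinality = n, prefix = prefix,
    params = list(n = n, region = region, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      seq <- seqs[[1]]
      b <- resolve_span(seq, node$params$region)
      L <- b[2] - b[1]
      if (L > 1) {
        seed_stream(ctx$seed, node$id, istate)
        perm <- sample.int(L)
        span <- strsplit(substr(seq$chars, b[1] + 1, b[2]), "",
                         fixed = TRUE)[[1]]
        seq <- apply_edit(seq, b[1], b[2],
                          paste(span[perm], collapse = ""))
      }
      list(seq = seq, card = NULL)
    })
}

#' Random recombination of two equal-length parents
#'
#' Each internal state draws `n_crossovers` sorted crossover points
#' (keyed RNG) and alternates segments starting from parent A. With zero
#' crossovers the output is parent A verbatim. Regions and styles are
#' taken from parent A (lengths are equal by precondition).
#'
#' @param parent_a,parent_b Input pools of equal-length sequences.
#' @param n_crossovers Number of crossover points per variant.
#' @param n Sample count.
#' @param prefix Name-token prefix.
#' @return A pool of cardinality `n * |A| * |B|`.
#' @export
recombine <- function(parent_a, parent_b, n_crossovers, n, prefix = NULL) {
  stopifnot(n >= 1, n_crossovers >= 0)
  new_operation(
    kind = "recombine", mode = "random",
    inputs = list(parent_a, parent_b), internal_cardinality = n,
    prefix = prefix, tracked = "crossovers",
    params = list(n_crossovers = n_crossovers, n = n, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      a <- seqs[[1]]; bseq <- seqs[[2]]
      L <- nchar(a$chars)
      if (nchar(bseq$chars) != L) {
        stop("recombine requires equal-length parents", call. = FALSE)
      }
      k <- node$params$n_crossovers
      if (k == 0 || L < 2) {
        return(list(seq = a, card = list(crossovers = numeric(0))))
      }
      seed_stream(ctx$seed, node$id, istate)
      pts <- sort(sample.int(L - 1, min(k, L - 1)))
      bounds <- c(0, pts, L)
      pieces <- character(length(bounds) - 1)
      for (i in seq_along(pieces)) {
        src <- if (i %% 2 == 1) a$chars else bseq$chars
        pieces[i] <- substr(src, bounds[i] + 1, bounds[i + 1])
      }
      out <- a
      out$chars <- paste(pieces, collapse = "")
      list(seq = out, card = list(crossovers = pts))
    })
}

#' Guaranteed-distinct barcodes for every pool member
#'
#' One barcode per incoming state: the barcode for overall state `s` is
#' the base-4 encoding (A, C, G, T digits, most significant first) of a
#' seeded bijective affine permutation of `s` within `[0, 4^length)`.
#' Injectivity of the permutation guarantees pairwise-distinct barcodes
#' across the whole pool with no global bookkeeping, which is what lazy
#' per-state generation requires. The barcode replaces the content of
#' `region` and is styled bold.
#'
#' @param parent Input pool; `4^length` must be at least its size.
#' @param region Region (or anchor) receiving the barcode.
#' @param length Barcode length in nucleotides.
#' @param prefix Name-token prefix (default `"bc"`).
#' @param style Style applied to barcode characters.
#' @return A pool of the same cardinality as `parent`.
#' @export
get_barcodes <- function(parent, region, length, prefix = "bc",
                         style = list(bold = TRUE)) {
  stopifnot(length >= 1)
  N <- pool_size(parent)
  cap <- if (length <= 26) 4^length else {
    Reduce(sn_mul, rep(list(4), length))
  }
  if (sn_cmp(cap, N) < 0) {
    minL <- ceiling(log(if (is_bigint(N)) 2^53 else N) / log(4))
    stop(sprintf(
      "4^%d = %s barcodes cannot cover pool size %s; need length >= %d",
      length, sn_format(cap), sn_format(N), minL), call. = FALSE)
  }
  node <- new_operation(
    kind = "get_barcodes", mode = "random", inputs = list(parent),
    internal_cardinality = 1, layout = "diagonal",
    prefix = prefix, tracked = "barcode",
    params = list(region = region, length = length, prefix = prefix,
                  style = style),
    construct = function(node, istate, seqs, ctx) {
      pm <- node$params
      cap <- node$.cap
      key <- sprintf("%.0f", ctx$seed)
      ab <- node$.perm[[key]]
      if (is.null(ab)) {
        seed_stream(ctx$seed, node$id, 0, "perm")
        if (!is_bigint(cap)) {
          a <- 2 * floor(stats::runif(1) * (cap / 2)) + 1
          b <- floor(stats::runif(1) * cap)
        } else {
          a <- sn_add(sn_mul(2, random_state_below(sn_divmod(cap, 2)$q)), 1)
          b <- random_state_below(cap)
        }
        ab <- list(a = a, b = b)
        node$.perm[[key]] <- ab
      }
      perm <- if (!is_bigint(cap) && cap <= 2^26) {
        (ab$a * istate + ab$b) %% cap
      } else {
        sn_divmod(sn_add(sn_mul(ab$a, istate), ab$b), cap)$r
      }
      digits <- character(pm$length)
      rem <- perm
      for (i in rev(seq_len(pm$length))) {
        dm <- sn_divmod(rem, 4)
        digits[i] <- .DNA4[dm$r + 1]
        rem <- dm$q
      }
      bc <- paste(digits, collapse = "")
      seq <- seqs[[1]]
      b <- region_bounds(seq, pm$region)
      seq <- apply_edit(seq, b[1], b[2], bc, style = pm$style)
      list(seq = seq, card = list(barcode = bc))
    })
  node$.cap <- cap
  node$.perm <- list()
  node
}

#' Overlay a style on a region (content unchanged)
#'
#' @param parent Input pool.
#' @param region Region to style; `NULL` styles the whole sequence.
#' @param fg,bg,bold,underline Style attributes (see [overlay_style()]).
#' @return A pool of the same cardinality.
#' @export
stylize <- function(parent, region = NULL, fg = NULL, bg = NULL,
                    bold = NULL, underline = NULL) {
  new_operation(
    kind = "stylize", mode = "fixed", inputs = list(parent),
    params = list(region = region, fg = fg, bg = bg, bold = bold,
                  underline = underline),
    construct = function(node, istate, seqs, ctx) {
      pm <- node$params
      list(seq = overlay_style(seqs[[1]], region = pm$region, fg = pm$fg,
                               bg = pm$bg, bold = pm$bold,
                               underline = pm$underline),
           card = NULL)
    })
}

#' Apply a fixed edit to every member
#'
#' Deterministic single edit (replacement, deletion, or insertion) at a
#' fixed interval, optionally relative to a region start.
#'
#' @param parent Input pool.
#' @param start,end 0-based half-open target interval (relative to the
#'   region start if `region` is given).
#' @param replacement Replacement string (may be empty).
#' @param region Optional region name anchoring the coordinates.
#' @param style Optional style for the replacement characters.
#' @return A pool of the same cardinality.
#' @export
edit_seq <- function(parent, start, end, replacement, region = NULL,
                     style = NULL) {
  new_operation(
    kind = "edit_seq", mode = "fixed", inputs = list(parent),
    params = list(start = start, end = end, replacement = replacement,
                  region = region, style = style),
    construct = function(node, istate, seqs, ctx) {
      pm <- node$params
      off <- if (is.null(pm$region)) 0 else {
        region_bounds(seqs[[1]], pm$region)[1]
      }
      list(seq = apply_edit(seqs[[1]], off + pm$start, off + pm$end,
                            pm$replacement, style = pm$style),
           card = NULL)
    })
}

#' Insert a payload pool into a region
#'
#' Product composition over (parent, payload): every combination of a
#' parent member and a payload member occurs. Without `offsets`, the
#' payload replaces the content of `region` (a zero-length anchor region
#' grows over the payload, so the region keeps addressing it). With
#' `offsets`, the operation additionally enumerates one pure insertion
#' point per offset (0-based, relative to the region start), giving
#' internal cardinality `length(offsets)`; the design card records the
#' offset used.
#'
#' @param parent Host pool.
#' @param payload Payload pool.
#' @param region Target region or anchor in the host.
#' @param offsets Optional integer vector of insertion offsets.
#' @param prefix Name-token prefix.
#' @return A pool of cardinality
#'   `length(offsets %||% 1) * |parent| * |payload|`.
#' @export
insert_at <- function(parent, payload, region, offsets = NULL,
                      prefix = NULL) {
  new_operation(
    kind = "insert_at", mode = if (is.null(offsets)) "fixed" else "sequential",
    inputs = list(parent, payload),
    internal_cardinality = if (is.null(offsets)) 1 else length(offsets),
    prefix = prefix,
    tracked = if (is.null(offsets)) character(0) else "offset",
    params = list(region = region, offsets = offsets, prefix = prefix),
    construct = function(node, istate, seqs, ctx) {
      pm <- node$params
      host <- seqs[[1]]
      b <- region_bounds(host, pm$region)
      if (is.null(pm$offsets)) {
        list(seq = splice_tagged(host, b[1], b[2], seqs[[2]]), card = NULL)
      } else {
        off <- pm$offsets[istate + 1]
        p <- b[1] + off
        list(seq = splice_tagged(host, p, p, seqs[[2]]),
             card = list(offset = off))
      }
    })
}

#' Scan-insert several motif pools at random non-overlapping placements
#'
#' Each of the `n` internal states (keyed RNG) draws one member from every
#' site pool, then draws pairwise-disjoint placements inside `region` by
#' rejection sampling, and overwrites the region content with the sites
#' (placements are equal-length substitutions, so the region length is
#' preserved). Site pools are consumed by internal sampling, not by state
#' digits: the output cardinality is `n * |parent states|`, independent of
#' the site pools' sizes.
#'
#' @param template Host pool with the target region.
#' @param sites Named list of site pools; names label the design-card
#'   columns (`<label>_offset`, `<label>_orient`, `<label>_member`).
#' @param region Region to place sites into.
#' @param n Sample count.
#' @param max_rejections Placement attempts before giving up with an
#'   error naming the state.
#' @param prefix Name-token prefix.
#' @return A pool of cardinality `n * |template|`.
#' @export
insert_multiscan <- function(template, sites, region, n,
                             max_rejections = 1000, prefix = NULL) {
  stopifnot(n >= 1, length(sites) >= 1)
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    names(sites) <- paste0("site", seq_along(sites))
  }
  labels <- names(sites)
  tracked <- as.vector(t(outer(labels, c("_offset", "_orient", "_member"),
                               paste0)))
  sizes <- vapply(sites, function(p) {
    sz <- pool_size(p)
    if (is_bigint(sz)) stop("site pools must have enumerable sizes",
                            call. = FALSE)
    sz
  }, numeric(1))
  node <- new_operation(
    kind = "insert_multiscan", mode = "random",
    inputs = list(template), aux_inputs = sites,
    internal_cardinality = n, prefix = prefix, tracked = tracked,
    params = list(region = region, n = n, max_rejections = max_rejections,
                  prefix = prefix, labels = labels),
    construct = function(node, istate, seqs, ctx) {
      pm <- node$params
      host <- seqs[[1]]
      b <- region_bounds(host, pm$region)
      rl <- b[2] - b[1]
      seed_stream(ctx$seed, node$id, istate, "members")
      members <- floor(stats::runif(length(node$aux_inputs)) *
                         unname(node$.sizes))
      picks <- lapply(seq_along(node$aux_inputs), function(i) {
        gen_node(node$aux_inputs[[i]], members[i], ctx$seed)
      })
      lens <- vapply(picks, function(r) nchar(r$seq$chars), numeric(1))
      if (sum(lens) > rl) {
        stop(sprintf("node %s: sites (%d nt) cannot fit region '%s' (%d nt)",
                     node$id, sum(lens), pm$region, rl), call. = FALSE)
      }
      seed_stream(ctx$seed, node$id, istate, "placement")
      starts <- NULL
      for (try in seq_len(pm$max_rejections)) {
        cand <- floor(stats::runif(length(lens)) * (rl - lens + 1))
        o <- order(cand)
        if (all(cand[o][-1] >= (cand + lens)[o][-length(o)])) {
          starts <- cand
          break
        }
      }
      if (is.null(starts)) {
        stop(sprintf(
          "node %s, state %s: no disjoint placement in %d attempts",
          node$id, sn_format(ctx$state), pm$max_rejections), call. = FALSE)
      }
      out <- host
      for (i in seq_along(picks)) {
        out <- splice_tagged(out, b[1] + starts[i],
                             b[1] + starts[i] + lens[i], picks[[i]]$seq)
      }
      card <- list()
      for (i in seq_along(pm$labels)) {
        orient <- NA_character_
        cn <- names(picks[[i]]$card)
        hit <- grep("\\.orientation$", cn)
        if (length(hit)) orient <- picks[[i]]$card[[hit[1]]]
        card[[paste0(pm$labels[i], "_offset")]] <- starts[i]
        card[[paste0(pm$labels[i], "_orient")]] <- orient
        card[[paste0(pm$labels[i], "_member")]] <- members[i]
      }
      list(seq = out, card = card)
    })
  node$.sizes <- sizes
  node
}
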