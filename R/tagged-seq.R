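# Region-tagged, stylable DNA sequences.
#
# A tagged_seq carries three aligned pieces of information:
#   * chars   - the DNA characters (one string; IUPAC codes allowed in
#               source material, strict ACGT enforced by operations that
#               need it),
#   * regions - named half-open [start, end) intervals, 0-based; zero
#               length allowed (anchors that sit between characters),
#   * styles  - an ordered list of style overlays (interval + attributes);
#               later overlays win attribute-wise, so a mutated position
#               can be underlined inside a region that is already colored.
#
# All coordinates in the package are 0-based half-open. Regions may nest
# properly; partially crossing intervals are rejected rather than silently
# split.

.IUPAC_CHARS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                  "V", "H", "D", "B", "N")

new_tagged <- function(chars, regions = list(name = character(0),
                                             start = numeric(0),
                                             end = numeric(0)),
                       styles = list()) {
  structure(list(chars = chars, regions = regions, styles = styles),
            class = "tagged_seq")
}

#' Length of a tagged sequence
#' @param x A `tagged_seq`.
#' @return Number of characters.
#' @export
seq_length <- function(x) nchar(x$chars)

#' Plain characters of a tagged sequence
#' @param x A `tagged_seq`.
#' @return The DNA string, without tags or styles.
#' @export
seq_chars <- function(x) x$chars

#' Regions of a tagged sequence
#' @param x A `tagged_seq`.
#' @return A data frame with columns `name`, `start`, `end` (0-based
#'   half-open).
#' @export
seq_regions <- function(x) {
  data.frame(name = x$regions$name, start = x$regions$start,
             end = x$regions$end, stringsAsFactors = FALSE)
}

region_bounds <- function(x, name) {
  i <- match(name, x$regions$name)
  if (is.na(i)) {
    stop(sprintf("region '%s' not found (available: %s)", name,
                 if (length(x$regions$name)) {
                   paste(unique(x$regions$name), collapse = ", ")
                 } else "none"), call. = FALSE)
  }
  c(x$regions$start[i], x$regions$end[i])
}

validate_alphabet <- function(chars, where = "sequence") {
  if (grepl("[a-z]", chars)) {
    warning("lowercase characters in ", where, " were uppercased",
            call. = FALSE)
    chars <- toupper(chars)
  }
  bad <- setdiff(unique(strsplit(chars, "", fixed = TRUE)[[1]]), .IUPAC_CHARS)
  if (length(bad)) {
    stop(sprintf("non-IUPAC character(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  chars
}

check_nesting <- function(regions) {
  k <- length(regions$name)
  if (k < 2L) return(invisible(TRUE))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      a1 <- regions$start[i]; b1 <- regions$end[i]
      a2 <- regions$start[j]; b2 <- regions$end[j]
      disjoint <- b1 <= a2 || b2 <= a1
      nested <- (a1 <= a2 && b2 <= b1) || (a2 <= a1 && b1 <= b2)
      if (!disjoint && !nested) {
        stop(sprintf("regions '%s' [%d,%d) and '%s' [%d,%d) cross improperly",
                     regions$name[i], a1, b1, regions$name[j], a2, b2),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Parse XML-style sequence markup
#'
#' Turns a string such as `"AAA<cre>CCCGGG</cre>TTT"` into a tagged
#' sequence: tag pairs become named regions, self-closing tags such as
#' `"ACGT<ins/>ACGT"` become zero-length anchor regions sitting between
#' characters, and the remaining characters form the DNA string.
#'
#' @param text Sequence text with optional `<name>...</name>` and
#'   `<name/>` tags. Tag names are alphanumeric identifiers.
#' @return A `tagged_seq`.
#' @export
#' @examples
#' s <- parse_tagged("AAA<cre>CCCGGG</cre>TTT")
#' seq_chars(s)    # "AAACCCGGGTTT"
#' seq_regions(s)  # cre: [3, 9)
parse_tagged <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("<(/?)([A-Za-z][A-Za-z0-9_]*)(/?)>", text, perl = TRUE)[[1]]
  name <- character(0); start <- numeric(0); end <- numeric(0)
  if (m[1] == -1L) {
    chars <- validate_alphabet(text)
    return(new_tagged(chars))
  }
  lens <- attr(m, "match.length")
  pieces <- character(0)
  pos <- 0          # position in stripped sequence
  cursor <- 1L      # position in raw text
  stack_name <- character(0)
  stack_pos <- numeric(0)
  for (k in seq_along(m)) {
    tag <- substr(text, m[k], m[k] + lens[k] - 1L)
    if (m[k] > cursor) {
      piece <- substr(text, cursor, m[k] - 1L)
      pieces <- c(pieces, piece)
      pos <- pos + nchar(piece)
    }
    cursor <- m[k] + lens[k]
    closing <- grepl("^</", tag)
    selfclosing <- grepl("/>$", tag)
    tagname <- gsub("[</>]", "", tag)
    if (selfclosing) {
      name <- c(name, tagname); start <- c(start, pos); end <- c(end, pos)
    } else if (closing) {
      if (length(stack_name) == 0L || stack_name[length(stack_name)] != tagname) {
        stop(sprintf("unmatched closing tag </%s> at character %d",
                     tagname, m[k]), call. = FALSE)
      }
      i <- length(stack_name)
      # close the most recently opened tag; fill in its end coordinate
      ridx <- max(which(name == tagname & is.na(end)))
      end[ridx] <- pos
      stack_name <- stack_name[-i]; stack_pos <- stack_pos[-i]
    } else {
      stack_name <- c(stack_name, tagname)
      stack_pos <- c(stack_pos, pos)
      name <- c(name, tagname); start <- c(start, pos); end <- c(end, NA_real_)
    }
  }
  if (length(stack_name)) {
    stop(sprintf("unclosed tag <%s>", stack_name[length(stack_name)]),
         call. = FALSE)
  }
  if (cursor <= nchar(text)) {
    pieces <- c(pieces, substr(text, cursor, nchar(text)))
  }
  chars <- validate_alphabet(paste(pieces, collapse = ""))
  regions <- list(name = name, start = start, end = end)
  check_nesting(regions)
  new_tagged(chars, regions)
}

#' Serialize a tagged sequence back to markup
#'
#' Re-emits region tags at their boundaries: `parse_tagged()` of the result
#' recovers the same characters and regions.
#'
#' @param x A `tagged_seq`.
#' @return A single string with XML-style tags (styles are not serialized).
#' @export
serialize_tagged <- function(x) {
  rg <- x$regions
  k <- length(rg$name)
  if (k == 0L) return(x$chars)
  # events: 0 = close, 1 = self-closing, 2 = open; sort keys give proper
  # nesting (closes before opens at equal positions, outer opens first)
  ev_pos <- c(rg$end[rg$start < rg$end], rg$start[rg$start == rg$end],
              rg$start[rg$start < rg$end])
  idx_pair <- which(rg$start < rg$end)
  idx_anchor <- which(rg$start == rg$end)
  ev_idx <- c(idx_pair, idx_anchor, idx_pair)
  ev_type <- c(rep(0L, length(idx_pair)), rep(1L, length(idx_anchor)),
               rep(2L, length(idx_pair)))
  # close: inner (later start) first; open: outer (later end) first
  ev_key2 <- ifelse(ev_type == 0L, -rg$start[ev_idx],
                    ifelse(ev_type == 2L, -rg$end[ev_idx], 0))
  # coextensive regions: close in reverse opening order
  ev_key3 <- ifelse(ev_type == 0L, -ev_idx, ev_idx)
  o <- order(ev_pos, ev_type, ev_key2, ev_key3)
  out <- character(0)
  cursor <- 0
  for (e in o) {
    p <- ev_pos[e]
    if (p > cursor) {
      out <- c(out, substr(x$chars, cursor + 1L, p))
      cursor <- p
    }
    nm <- rg$name[ev_idx[e]]
    out <- c(out, switch(ev_type[e] + 1L,
                         paste0("</", nm, ">"),
                         paste0("<", nm, "/>"),
                         paste0("<", nm, ">")))
  }
  if (cursor < nchar(x$chars)) {
    out <- c(out, substr(x$chars, cursor + 1L, nchar(x$chars)))
  }
  paste(out, collapse = "")
}

#' Apply an edit to a tagged sequence
#'
#' Replaces the half-open interval `[start, end)` with `replacement`
#' (empty replacement = deletion; zero-length interval = insertion) and
#' shifts all region and style coordinates by the length difference
#' `delta = nchar(replacement) - (end - start)`:
#' a region strictly right of the edit shifts by `delta`; a region
#' containing the edit stretches by `delta`; a zero-length anchor exactly
#' at an insertion point grows to cover the inserted text (so serial
#' operations can keep targeting the same region). An edit that partially
#' crosses a region boundary is an error. Inserted characters are unstyled
#' unless `style` is given.
#'
#' @param x A `tagged_seq`.
#' @param start,end 0-based half-open target interval.
#' @param replacement Replacement string (may be empty).
#' @param style Optional named list of style attributes (`fg`, `bg`,
#'   `bold`, `underline`) applied to the replacement characters.
#' @return The edited `tagged_seq`.
#' @export
#' @examples
#' s <- parse_tagged("AAA<cre>CCCGGG</cre>TTT")
#' seq_regions(apply_edit(s, 3, 9, ""))  # cre collapses to [3, 3)
apply_edit <- function(x, start, end, replacement = "", style = NULL) {
  L <- nchar(x$chars)
  if (start < 0 || end > L || start > end) {
    stop(sprintf("edit interval [%s,%s) out of bounds for length %d",
                 start, end, L), call. = FALSE)
  }
  if (nchar(replacement)) {
    replacement <- validate_alphabet(replacement, "replacement")
  }
  payload <- new_tagged(replacement)
  if (!is.null(style)) {
    payload$styles <- list(list(start = 0, end = nchar(replacement),
                                attrs = style))
  }
  splice_tagged(x, start, end, payload)
}

# Core splice: replace host [start, end) with a whole tagged payload,
# carrying the payload's regions and styles at their new offsets.
splice_tagged <- function(x, start, end, payload) {
  delta <- nchar(payload$chars) - (end - start)
  rg <- x$regions
  ns <- rg$start; ne <- rg$end
  for (i in seq_along(rg$name)) {
    a <- rg$start[i]; b <- rg$end[i]
    if (start < end) {                       # replacement / deletion
      if (b <= start) {
      } else if (a >= end) {
        ns[i] <- a + delta; ne[i] <- b + delta
      } else if (a <= start && b >= end) {
        ne[i] <- b + delta                   # stretch
      } else {
        stop(sprintf(
          "edit [%s,%s) partially overlaps region '%s' [%s,%s)",
          start, end, rg$name[i], a, b), call. = FALSE)
      }
    } else {                                 # insertion at point p = start
      p <- start
      if (a <= p && p < b) {
        ne[i] <- b + delta                   # interior point: stretch
      } else if (a == b && a == p) {
        ne[i] <- b + delta                   # anchor grows over insert
      } else if (a >= p && b > p) {
        ns[i] <- a + delta; ne[i] <- b + delta
      } else if (a == b && a > p) {
        ns[i] <- a + delta; ne[i] <- b + delta
      }
    }
  }
  regions <- list(name = rg$name, start = ns, end = ne)
  # Host style runs: an equal-length substitution modifies characters in
  # place, so their styles persist (later overlays still win per
  # attribute - this is what lets a mutated position stay inside a shaded
  # region). Length-changing edits clip the affected span and shift the
  # remainder; inserted characters default to unstyled.
  if (delta == 0 && end > start) {
    styles <- x$styles
  } else {
    styles <- list()
    for (st in x$styles) {
      a <- st$start; b <- st$end
      if (a < min(b, start)) {
        styles[[length(styles) + 1L]] <-
          list(start = a, end = min(b, start), attrs = st$attrs)
      }
      if (b > end) {
        styles[[length(styles) + 1L]] <-
          list(start = max(a, end) + delta, end = b + delta,
               attrs = st$attrs)
      }
    }
  }
  for (st in payload$styles) {
    styles[[length(styles) + 1L]] <-
      list(start = st$start + start, end = st$end + start, attrs = st$attrs)
  }
  if (length(payload$regions$name)) {
    regions$name <- c(regions$name, payload$regions$name)
    regions$start <- c(regions$start, payload$regions$start + start)
    regions$end <- c(regions$end, payload$regions$end + start)
  }
  chars <- paste0(substr(x$chars, 1L, start), payload$chars,
                  substr(x$chars, end + 1L, nchar(x$chars)))
  new_tagged(chars, regions, styles)
}

# Concatenate tagged sequences, offsetting regions and styles.
concat_tagged <- function(seqs) {
  chars <- paste(vapply(seqs, function(s) s$chars, character(1)),
                 collapse = "")
  name <- character(0); start <- numeric(0); end <- numeric(0)
  styles <- list()
  off <- 0
  for (s in seqs) {
    name <- c(name, s$regions$name)
    start <- c(start, s$regions$start + off)
    end <- c(end, s$regions$end + off)
    for (st in s$styles) {
      styles[[length(styles) + 1L]] <-
        list(start = st$start + off, end = st$end + off, attrs = st$attrs)
    }
    off <- off + nchar(s$chars)
  }
  new_tagged(chars, list(name = name, start = start, end = end), styles)
}

.COMPLEMENT_FROM <- "ACGTMRWSYKVHDBN"
.COMPLEMENT_TO   <- "TGCAKYWSRMBDHVN"

#' Reverse complement of a tagged sequence
#'
#' Complements per the standard IUPAC table and reverses; a region
#' `[a, b)` maps to `[L - b, L - a)` and style runs move with their
#' characters.
#'
#' @param x A `tagged_seq` or plain character string.
#' @return Object of the same type as `x`.
#' @export
#' @examples
#' reverse_complement("AACG")  # "CGTT"
reverse_complement <- function(x) {
  rc <- function(s) {
    paste(rev(strsplit(chartr(.COMPLEMENT_FROM, .COMPLEMENT_TO, s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }
  if (is.character(x)) {
    x <- validate_alphabet(x)
    return(rc(x))
  }
  stopifnot(inherits(x, "tagged_seq"))
  L <- nchar(x$chars)
  regions <- list(name = x$regions$name,
                  start = L - x$regions$end,
                  end = L - x$regions$start)
  styles <- lapply(x$styles, function(st) {
    list(start = L - st$end, end = L - st$start, attrs = st$attrs)
  })
  new_tagged(rc(x$chars), regions, styles)
}

.GENETIC_CODE_TABLE <- NULL

genetic_code <- function() {
  # standard code, via the canonical Biostrings table
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate a DNA span with the standard genetic code
#'
#' @param x DNA string (or `tagged_seq`) whose length is a multiple of 3.
#' @return Amino-acid string; stop codons render as `"*"`.
#' @export
#' @examples
#' translate_dna("ATGGGT")  # "MG"
translate_dna <- function(x) {
  if (inherits(x, "tagged_seq")) x <- x$chars
  if (nchar(x) %% 3 != 0) {
    stop("length not a multiple of 3: ", nchar(x), call. = FALSE)
  }
  if (nchar(x) == 0L) return("")
  codons <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  gc <- genetic_code()
  aa <- gc[codons]
  if (anyNA(aa)) {
    stop("ambiguous base in codon(s): ",
         paste(codons[is.na(aa)], collapse = ", "), call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Overlay style attributes on an interval
#'
#' Attributes named in the overlay replace prior values on those
#' characters; attributes not named persist (so an underline overlay keeps
#' an earlier background color).
#'
#' @param x A `tagged_seq`.
#' @param start,end 0-based half-open interval, or `NULL` with `region`.
#' @param region Region name to style instead of explicit coordinates.
#' @param fg,bg Color names (`black`, `red`, `green`, `yellow`, `blue`,
#'   `magenta`/`purple`, `cyan`, `white`, `gray`, `orange`).
#' @param bold,underline Logical flags.
#' @return The styled `tagged_seq`.
#' @export
overlay_style <- function(x, start = NULL, end = NULL, region = NULL,
                          fg = NULL, bg = NULL, bold = NULL,
                          underline = NULL) {
  if (!is.null(region)) {
    b <- region_bounds(x, region)
    start <- b[1]; end <- b[2]
  }
  if (is.null(start) || is.null(end)) {
    start <- 0; end <- nchar(x$chars)
  }
  if (start < 0 || end > nchar(x$chars) || start > end) {
    stop("style interval out of bounds", call. = FALSE)
  }
  attrs <- list(fg = fg, bg = bg, bold = bold, underline = underline)
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  if (length(attrs) == 0L) return(x)
  x$styles[[length(x$styles) + 1L]] <-
    list(start = start, end = end, attrs = attrs)
  x
}

.ANSI_FG <- c(black = "30", red = "31", green = "32", yellow = "33",
              blue = "34", magenta = "35", purple = "35", cyan = "36",
              white = "37", gray = "90", grey = "90", orange = "38;5;208")
.ANSI_BG <- c(black = "40", red = "41", green = "42", yellow = "43",
              blue = "44", magenta = "45", purple = "45", cyan = "46",
              white = "47", gray = "100", grey = "100", orange = "48;5;208")

# Resolve per-character style attributes (last writer wins per attribute).
resolve_styles <- function(x) {
  n <- nchar(x$chars)
  fg <- rep(NA_character_, n); bg <- rep(NA_character_, n)
  bold <- rep(FALSE, n); underline <- rep(FALSE, n)
  for (st in x$styles) {
    if (st$end <= st$start) next
    idx <- seq(st$start + 1L, st$end)
    a <- st$attrs
    if (!is.null(a$fg)) fg[idx] <- a$fg
    if (!is.null(a$bg)) bg[idx] <- a$bg
    if (!is.null(a$bold)) bold[idx] <- isTRUE(a$bold)
    if (!is.null(a$underline)) underline[idx] <- isTRUE(a$underline)
  }
  list(fg = fg, bg = bg, bold = bold, underline = underline)
}

#' Render a tagged sequence with ANSI escape codes
#'
#' Deterministic: adjacent characters sharing a style are emitted as one
#' run with a single escape sequence, and stripping all escape codes
#' recovers the characters exactly.
#'
#' @param x A `tagged_seq`.
#' @param plain If `TRUE`, return the bare characters with no escapes.
#' @return A single string.
#' @export
render_ansi <- function(x, plain = FALSE) {
  if (plain || length(x$styles) == 0L) return(x$chars)
  n <- nchar(x$chars)
  if (n == 0L) return("")
  res <- resolve_styles(x)
  key <- paste(res$fg, res$bg, res$bold, res$underline, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- character(length(r$lengths))
  for (i in seq_along(r$lengths)) {
    piece <- substr(x$chars, starts[i], ends[i])
    j <- starts[i]
    codes <- character(0)
    if (res$bold[j]) codes <- c(codes, "1")
    if (res$underline[j]) codes <- c(codes, "4")
    if (!is.na(res$fg[j])) {
      cc <- .ANSI_FG[[res$fg[j]]]
      if (is.null(cc)) stop("unknown color: ", res$fg[j], call. = FALSE)
      codes <- c(codes, cc)
    }
    if (!is.na(res$bg[j])) {
      cc <- .ANSI_BG[[res$bg[j]]]
      if (is.null(cc)) stop("unknown color: ", res$bg[j], call. = FALSE)
      codes <- c(codes, cc)
    }
    out[i] <- if (length(codes)) {
      paste0("\033[", paste(codes, collapse = ";"), "m", piece, "\033[0m")
    } else {
      piece
    }
  }
  paste(out, collapse = "")
}

#' Strip ANSI escape codes from a string
#' @param x Character vector.
#' @return `x` with all SGR escape sequences removed.
#' @export
strip_ansi <- function(x) gsub("\033\\[[0-9;]*m", "", x)

#' @export
print.tagged_seq <- function(x, ...) {
  cat(render_ansi(x), "\n", sep = "")
  rg <- seq_regions(x)
  if (nrow(rg)) {
    cat(paste0("  <", rg$name, "> [", rg$start, ",", rg$end, ")",
               collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}
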