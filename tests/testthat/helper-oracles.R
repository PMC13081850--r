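# Independent oracles used by the property tests.

# Coordinate-maintenance oracle: instead of delta-shift arithmetic, mark
# every character with the regions it belongs to, perform the edit on the
# character vector (inserted characters inherit the memberships of the
# regions that contain the edit), and read the new region coordinates
# back from the marks. Valid for non-anchor regions.
oracle_edit_regions <- function(x, start, end, replacement) {
  rg <- seq_regions(x)
  n <- seq_length(x)
  member <- lapply(seq_len(nrow(rg)), function(r) {
    seq_len(n) > rg$start[r] & seq_len(n) <= rg$end[r]
  })
  contains <- vapply(seq_len(nrow(rg)), function(r) {
    if (start < end) {
      rg$start[r] <= start && rg$end[r] >= end
    } else {
      rg$start[r] <= start && start < rg$end[r]
    }
  }, logical(1))
  k <- nchar(replacement)
  keep_left <- seq_len(n) <= start
  keep_right <- seq_len(n) > end
  new_member <- lapply(seq_along(member), function(r) {
    c(member[[r]][keep_left], rep(contains[r], k), member[[r]][keep_right])
  })
  data.frame(name = rg$name,
             start = vapply(new_member, function(m) {
               if (any(m)) min(which(m)) - 1 else NA_real_
             }, numeric(1)),
             end = vapply(new_member, function(m) {
               if (any(m)) max(which(m)) else NA_real_
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

# Random tagged text with properly nested (non-anchor, non-empty) regions.
random_tagged_seq <- function(len = 30, n_regions = 2) {
  chars <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  s <- parse_tagged(chars)
  for (i in seq_len(n_regions)) {
    a <- sample.int(len - 1, 1) - 1
    b <- a + sample.int(len - a, 1)
    rg <- seq_regions(s)
    ok <- all(vapply(seq_len(nrow(rg)), function(r) {
      ra <- rg$start[r]; rb <- rg$end[r]
      (b <= ra || a >= rb) || (a >= ra && b <= rb) || (a <= ra && b >= rb)
    }, logical(1)))
    if (!ok) next
    s$regions$name <- c(s$regions$name, paste0("r", i))
    s$regions$start <- c(s$regions$start, a)
    s$regions$end <- c(s$regions$end, b)
  }
  s
}

# An edit target compatible with the nesting contract: entirely inside
# one innermost region or entirely outside all regions.
random_valid_edit <- function(s) {
  n <- seq_length(s)
  rg <- seq_regions(s)
  for (tries in 1:50) {
    a <- sample.int(n + 1, 1) - 1
    b <- a + sample.int(n - a + 1, 1) - 1
    ok <- all(vapply(seq_len(nrow(rg)), function(r) {
      ra <- rg$start[r]; rb <- rg$end[r]
      if (a < b) {
        (b <= ra || a >= rb) || (a >= ra && b <= rb)
      } else {
        TRUE
      }
    }, logical(1)))
    if (ok) return(c(a, b))
  }
  c(0, 0)
}
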