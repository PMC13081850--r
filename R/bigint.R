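# Exact non-negative integer arithmetic for state indexing.
#
# Combinatorial library sizes overflow 32-bit integers immediately and the
# 2^53 exact range of doubles soon after (a product of a few mutagenesis
# pools easily exceeds 2^63). States and cardinalities are therefore
# carried either as exact integer-valued doubles (fast path, < 2^53) or as
# little-endian base-1e6 digit vectors of class "bigint". Only the
# operations the state algebra needs exist: compare, add, subtract,
# multiply, and divmod.

.BI_BASE <- 1e6
.MAX_EXACT <- 2^53 - 1

new_bigint <- function(digits) {
  n <- length(digits)
  while (n > 1L && digits[n] == 0) n <- n - 1L
  structure(digits[seq_len(n)], class = "bigint")
}

is_bigint <- function(x) inherits(x, "bigint")

#' Convert to an arbitrary-precision integer
#'
#' States and cardinalities larger than 2^53 cannot be represented exactly
#' as doubles; pass them as decimal strings. Values below 2^53 may be given
#' as plain numerics.
#'
#' @param x A non-negative integer-valued numeric, a decimal string, or a
#'   `bigint`.
#' @return An object of class `bigint`.
#' @export
#' @examples
#' as_bigint("18446744073709551616")  # 2^64
as_bigint <- function(x) {
  if (is_bigint(x)) return(x)
  if (is.character(x)) {
    s <- gsub("[ _,]", "", x)
    if (!grepl("^[0-9]+$", s)) {
      stop("not a non-negative decimal integer string: ", x, call. = FALSE)
    }
    s <- sub("^0+(?=.)", "", s, perl = TRUE)
    n <- nchar(s)
    starts <- seq(n, 1, by = -6)  # little-endian: rightmost chunk first
    digs <- vapply(starts, function(i) {
      as.numeric(substr(s, max(1, i - 5), i))
    }, numeric(1))
    return(new_bigint(digs))
  }
  if (is.numeric(x) && length(x) == 1L) {
    if (is.na(x) || x < 0 || x != trunc(x) || x > .MAX_EXACT) {
      stop("cannot convert to bigint: need a non-negative integer below 2^53",
           call. = FALSE)
    }
    d <- numeric(0)
    v <- x
    repeat {
      d <- c(d, v %% .BI_BASE)
      v <- (v - v %% .BI_BASE) / .BI_BASE
      if (v == 0) break
    }
    return(new_bigint(d))
  }
  stop("cannot convert to bigint", call. = FALSE)
}

#' @export
format.bigint <- function(x, ...) {
  n <- length(x)
  if (n == 1L) return(sprintf("%.0f", x[1L]))
  paste0(sprintf("%.0f", x[n]),
         paste(sprintf("%06.0f", rev(x[seq_len(n - 1L)])), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

# NA if the value does not fit exactly in a double.
bi_to_double <- function(x) {
  n <- length(x)
  if (n > 3L) return(NA_real_)
  v <- sum(unclass(x) * .BI_BASE^(seq_len(n) - 1L))
  if (v > .MAX_EXACT) NA_real_ else v
}

bi_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  av <- c(unclass(a), numeric(n - length(a)))
  bv <- c(unclass(b), numeric(n - length(b)))
  s <- av + bv
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= .BI_BASE) 1 else 0
    if (carry) s[i] <- s[i] - .BI_BASE
  }
  if (carry) s <- c(s, 1)
  new_bigint(s)
}

# Requires a >= b.
bi_sub <- function(a, b) {
  n <- length(a)
  av <- unclass(a)
  bv <- c(unclass(b), numeric(n - length(b)))
  d <- av - bv
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BI_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  new_bigint(d)
}

bi_mul_small <- function(a, k) {
  # k a plain integer in [0, 1e6)
  if (k == 0) return(new_bigint(0))
  p <- unclass(a) * k
  carry <- 0
  for (i in seq_along(p)) {
    p[i] <- p[i] + carry
    carry <- floor(p[i] / .BI_BASE)
    p[i] <- p[i] - carry * .BI_BASE
  }
  while (carry > 0) {
    p <- c(p, carry %% .BI_BASE)
    carry <- floor(carry / .BI_BASE)
  }
  new_bigint(p)
}

bi_mul <- function(a, b) {
  la <- length(a); lb <- length(b)
  res <- numeric(la + lb)
  for (j in seq_len(lb)) {
    if (b[j] == 0) next
    idx <- seq_len(la) + j - 1L
    res[idx] <- res[idx] + unclass(a) * b[j]
    # Normalize eagerly so partial sums stay well below 2^53.
    carry <- 0
    for (i in idx) {
      res[i] <- res[i] + carry
      carry <- floor(res[i] / .BI_BASE)
      res[i] <- res[i] - carry * .BI_BASE
    }
    i <- max(idx) + 1L
    while (carry > 0) {
      res[i] <- res[i] + carry
      carry <- floor(res[i] / .BI_BASE)
      res[i] <- res[i] - carry * .BI_BASE
      i <- i + 1L
    }
  }
  new_bigint(res)
}

bi_divmod <- function(a, b) {
  if (bi_cmp(b, new_bigint(0)) == 0L) stop("division by zero", call. = FALSE)
  cm <- bi_cmp(a, b)
  if (cm < 0) return(list(q = new_bigint(0), r = a))
  if (length(b) == 1L) {
    bv <- b[1L]
    q <- numeric(length(a))
    r <- 0
    for (i in rev(seq_along(a))) {
      cur <- r * .BI_BASE + a[i]
      q[i] <- floor(cur / bv)
      r <- cur - q[i] * bv
    }
    return(list(q = new_bigint(q), r = new_bigint(r)))
  }
  # Schoolbook long division, quotient digit by binary search.
  q <- numeric(length(a))
  r <- new_bigint(0)
  for (i in rev(seq_along(a))) {
    r <- new_bigint(c(a[i], unclass(r)))  # r * BASE + digit
    if (bi_cmp(r, b) >= 0) {
      lo <- 1; hi <- .BI_BASE - 1
      while (lo < hi) {
        mid <- ceiling((lo + hi) / 2)
        if (bi_cmp(bi_mul_small(b, mid), r) <= 0) lo <- mid else hi <- mid - 1
      }
      q[i] <- lo
      r <- bi_sub(r, bi_mul_small(b, lo))
    }
  }
  list(q = new_bigint(q), r = r)
}

# ---------------------------------------------------------------------------
# "statenum" layer: exact integers that are plain doubles when they fit in
# 2^53 and bigints otherwise. All state/cardinality arithmetic goes through
# these helpers so the hot path stays numeric.

sn_demote <- function(x) {
  if (!is_bigint(x)) return(x)
  d <- bi_to_double(x)
  if (is.na(d)) x else d
}

sn_coerce <- function(x) {
  if (is_bigint(x)) return(sn_demote(x))
  if (is.character(x)) return(sn_demote(as_bigint(x)))
  if (is.numeric(x) && length(x) == 1L && !is.na(x) &&
      x >= 0 && x == trunc(x) && x <= .MAX_EXACT) {
    return(as.numeric(x))
  }
  stop("expected a non-negative exact integer (numeric below 2^53, ",
       "decimal string, or bigint)", call. = FALSE)
}

sn_is <- function(x) is_bigint(x) || (is.numeric(x) && length(x) == 1L)

sn_add <- function(a, b) {
  if (!is_bigint(a) && !is_bigint(b)) {
    s <- a + b
    if (s <= .MAX_EXACT) return(s)
  }
  sn_demote(bi_add(as_bigint(a), as_bigint(b)))
}

sn_sub <- function(a, b) {
  if (!is_bigint(a) && !is_bigint(b)) return(a - b)
  sn_demote(bi_sub(as_bigint(a), as_bigint(b)))
}

sn_mul <- function(a, b) {
  if (!is_bigint(a) && !is_bigint(b)) {
    if (a == 0 || b <= .MAX_EXACT / a) {
      p <- a * b
      if (p <= .MAX_EXACT) return(p)
    }
  }
  sn_demote(bi_mul(as_bigint(a), as_bigint(b)))
}

sn_divmod <- function(a, b) {
  if (!is_bigint(a) && !is_bigint(b)) {
    return(list(q = a %/% b, r = a %% b))
  }
  dm <- bi_divmod(as_bigint(a), as_bigint(b))
  list(q = sn_demote(dm$q), r = sn_demote(dm$r))
}

sn_cmp <- function(a, b) {
  if (!is_bigint(a) && !is_bigint(b)) {
    return(if (a < b) -1L else if (a > b) 1L else 0L)
  }
  bi_cmp(as_bigint(a), as_bigint(b))
}

sn_format <- function(x) {
  if (is_bigint(x)) format(x) else sprintf("%.0f", x)
}
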