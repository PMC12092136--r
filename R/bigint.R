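# Minimal exact big-integer arithmetic (base 1e4, little-endian digit
# vectors, separate sign). The acceptable-network counts are alternating
# sums of terms like C(n0,i) * 2^((n0-i)*n1) that overflow doubles and
# suffer catastrophic cancellation in floating point at moderate n, so all
# counting is done exactly here. Only the operations the counting formulas
# need are implemented: +, -, *, 2^k, binomial (Pascal), comparison.

BIG_BASE <- 10000L

big_trim <- function(mag) {
  while (length(mag) > 0L && mag[length(mag)] == 0L) {
    mag <- mag[-length(mag)]
  }
  mag
}

big_make <- function(sign, mag) {
  mag <- big_trim(as.integer(mag))
  if (length(mag) == 0L) sign <- 0L
  structure(list(sign = as.integer(sign), mag = mag), class = "bigint")
}

#' Exact big integer from a double or decimal string
#'
#' @param x A single integer-valued double (must be exactly representable,
#'   i.e. |x| < 2^53) or a decimal string, possibly signed.
#' @return A `bigint`.
#' @export
as_bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    s <- trimws(x)
    sign <- 1L
    if (startsWith(s, "-")) { sign <- -1L; s <- substring(s, 2L) }
    if (!grepl("^[0-9]+$", s)) nn_parse_error("not a decimal integer string")
    digs <- integer(0)
    while (nchar(s) > 0L) {
      tail <- substring(s, max(1L, nchar(s) - 3L))
      digs <- c(digs, as.integer(tail))
      s <- substring(s, 1L, max(0L, nchar(s) - 4L))
    }
    return(big_make(sign, digs))
  }
  x <- as.numeric(x)
  if (length(x) != 1L || is.na(x) || x != floor(x) || abs(x) >= 2^53) {
    nn_domain_error("as_bigint() needs an exactly representable integer")
  }
  sign <- if (x < 0) -1L else 1L
  x <- abs(x)
  digs <- integer(0)
  while (x > 0) {
    digs <- c(digs, as.integer(x %% BIG_BASE))
    x <- floor(x / BIG_BASE)
  }
  big_make(sign, digs)
}

# magnitude comparison: -1, 0, 1
big_mag_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

big_mag_add <- function(a, b) {
  k <- max(length(a), length(b))
  a <- c(a, integer(k - length(a)))
  b <- c(b, integer(k - length(b)))
  s <- a + b
  carry <- 0L
  for (i in seq_len(k)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  if (carry > 0L) s <- c(s, carry)
  s
}

# requires |a| >= |b|
big_mag_sub <- function(a, b) {
  b <- c(b, integer(length(a) - length(b)))
  d <- a - b
  for (i in seq_along(d)) {
    if (d[i] < 0L) {
      d[i] <- d[i] + BIG_BASE
      d[i + 1L] <- d[i + 1L] - 1L
    }
  }
  big_trim(d)
}

big_add <- function(x, y) {
  x <- as_bigint(x); y <- as_bigint(y)
  if (x$sign == 0L) return(y)
  if (y$sign == 0L) return(x)
  if (x$sign == y$sign) {
    return(big_make(x$sign, big_mag_add(x$mag, y$mag)))
  }
  cmp <- big_mag_cmp(x$mag, y$mag)
  if (cmp == 0L) return(big_make(0L, integer(0)))
  if (cmp > 0L) big_make(x$sign, big_mag_sub(x$mag, y$mag))
  else big_make(y$sign, big_mag_sub(y$mag, x$mag))
}

big_neg <- function(x) {
  x <- as_bigint(x)
  big_make(-x$sign, x$mag)
}

big_sub <- function(x, y) big_add(x, big_neg(y))

big_mul <- function(x, y) {
  x <- as_bigint(x); y <- as_bigint(y)
  if (x$sign == 0L || y$sign == 0L) return(big_make(0L, integer(0)))
  la <- length(x$mag); lb <- length(y$mag)
  # accumulate in double (products < 1e8, partial sums well under 2^53)
  acc <- numeric(la + lb)
  for (i in seq_len(la)) {
    acc[i:(i + lb - 1L)] <- acc[i:(i + lb - 1L)] + x$mag[i] * as.numeric(y$mag)
  }
  carry <- 0
  out <- integer(la + lb + 2L)
  for (i in seq_along(acc)) {
    v <- acc[i] + carry
    out[i] <- as.integer(v %% BIG_BASE)
    carry <- floor(v / BIG_BASE)
  }
  i <- length(acc)
  while (carry > 0) {
    i <- i + 1L
    out[i] <- as.integer(carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  big_make(x$sign * y$sign, out)
}

# 2^k, k >= 0
big_pow2 <- function(k) {
  k <- as.integer(k)
  if (k < 0L) nn_domain_error("negative exponent")
  out <- as_bigint(1)
  two26 <- as_bigint(2^26)
  while (k >= 26L) {
    out <- big_mul(out, two26)
    k <- k - 26L
  }
  big_mul(out, as_bigint(2^k))
}

# C(n, k) exactly, via Pascal's rule (only addition needed)
big_choose <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 0L || k < 0L) nn_domain_error("negative binomial argument")
  if (k > n) return(as_bigint(0))
  row <- list(as_bigint(1))
  for (r in seq_len(n)) {
    nr <- vector("list", r + 1L)
    nr[[1L]] <- as_bigint(1)
    nr[[r + 1L]] <- as_bigint(1)
    if (r >= 2L) {
      for (j in 2L:r) nr[[j]] <- big_add(row[[j - 1L]], row[[j]])
    }
    row <- nr
  }
  row[[k + 1L]]
}

big_cmp <- function(x, y) {
  d <- big_sub(as_bigint(x), as_bigint(y))
  d$sign
}

#' @export
as.character.bigint <- function(x, ...) {
  if (x$sign == 0L) return("0")
  digs <- rev(x$mag)
  body <- paste0(digs[1L],
                 paste(sprintf("%04d", digs[-1L]), collapse = ""))
  paste0(if (x$sign < 0L) "-" else "", body)
}

#' @export
as.double.bigint <- function(x, ...) {
  v <- 0
  for (d in rev(x$mag)) v <- v * BIG_BASE + d
  v * x$sign
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint>", as.character(x), "\n")
  invisible(x)
}
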