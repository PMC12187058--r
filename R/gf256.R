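# GF(2^8) arithmetic and the systematic (38,36) Reed-Solomon inner code.
# The RS code is used for *detection only*: two parity symbols give minimum
# distance 3, so every single- and double-symbol error in a 38-symbol word is
# caught, and a clean word is identified by all syndromes being zero.

.gf_cache <- new.env(parent = emptyenv())

# log/antilog tables for the field generated by `prim` (default 0x11d,
# x^8+x^4+x^3+x^2+1) with alpha = 2.
gf_tables <- function(prim = 285L) {
  key <- as.character(prim)
  tab <- get0(key, envir = .gf_cache)
  if (!is.null(tab)) return(tab)
  exp <- integer(510L)
  log <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, prim), 255L)
  }
  exp[256:510] <- exp[1:255]
  tab <- list(exp = exp, log = log, prim = prim)
  assign(key, tab, envir = .gf_cache)
  tab
}

#' Multiply two GF(2^8) field elements
#'
#' Carry-less polynomial multiplication reduced by the field's primitive
#' polynomial, computed through log/antilog tables. Vectorized with recycling.
#'
#' @param a,b integers in `[0, 255]`.
#' @param prim primitive polynomial as an integer (default `0x11d`).
#' @return integer vector of products in `[0, 255]`.
#' @examples
#' gf_mul(2L, 128L)  # 29: 0x100 reduced by 0x11d
#' @export
gf_mul <- function(a, b, prim = 285L) {
  a <- as.integer(a); b <- as.integer(b)
  if (any(is.na(a)) || any(is.na(b)) || any(a < 0L | a > 255L) || any(b < 0L | b > 255L))
    stop("field elements must be integers in [0, 255]")
  tab <- gf_tables(prim)
  out <- tab$exp[tab$log[a + 1L] + tab$log[b + 1L] + 1L]
  out[a == 0L | b == 0L] <- 0L
  as.integer(out)
}

gf_pow <- function(a, e, prim = 285L) {
  tab <- gf_tables(prim)
  if (a == 0L) return(if (e == 0L) 1L else 0L)
  tab$exp[(tab$log[a + 1L] * e) %% 255L + 1L]
}

#' Reed-Solomon inner-code parameters
#'
#' @param n codeword length in symbols (default 38).
#' @param k message length in symbols (default 36).
#' @param prim primitive polynomial of GF(2^8).
#' @param fcr exponent of the first consecutive generator root
#'   (default 0: roots `alpha^0, alpha^1, ...`).
#' @return an `rs_params` object (list with `n`, `k`, `prim`, `fcr` and the
#'   generator-polynomial tail coefficients `g`).
#' @export
rs_params <- function(n = 38L, k = 36L, prim = 285L, fcr = 0L) {
  stopifnot(n > k, n <= 255L, k >= 1L)
  n <- as.integer(n); k <- as.integer(k)
  # g(x) = prod_{j=0}^{n-k-1} (x - alpha^(fcr+j)); keep tail coefficients
  # (degree n-k-1 down to 0), leading coefficient is 1.
  g <- 1L
  for (j in 0:(n - k - 1L)) {
    root <- gf_pow(2L, fcr + j, prim)
    # (current g) * (x + root)
    g_hi <- c(g, 0L)
    g_lo <- c(0L, gf_mul(g, root, prim))
    g <- bitwXor(g_hi, g_lo)
  }
  structure(list(n = n, k = k, prim = prim, fcr = as.integer(fcr),
                 g = as.integer(g[-1L])),
            class = "rs_params")
}

# Parity for a matrix of messages (rows = messages, k columns): LFSR long
# division by the generator polynomial, vectorized across rows.
rs_parity_matrix <- function(msg, params) {
  stopifnot(ncol(msg) == params$k)
  nk <- params$n - params$k
  m <- nrow(msg)
  b <- matrix(0L, m, nk)
  g <- params$g
  for (i in seq_len(params$k)) {
    f <- bitwXor(msg[, i], b[, 1L])
    for (t in seq_len(nk)) {
      pr <- gf_mul(f, g[t], params$prim)
      b[, t] <- if (t < nk) bitwXor(b[, t + 1L], pr) else pr
    }
  }
  b
}

#' Systematic RS encoding
#'
#' Appends `n - k` parity symbols to a `k`-symbol message so that the codeword
#' polynomial vanishes at every generator root.
#'
#' @param message integer vector of `k` symbols in `[0, 255]`.
#' @param params an [rs_params()] object.
#' @return integer vector of `n` symbols, `message` first (systematic).
#' @export
rs_encode <- function(message, params = rs_params()) {
  message <- as.integer(message)
  if (length(message) != params$k) stop("message must have exactly k symbols")
  if (any(message < 0L | message > 255L)) stop("symbols must lie in [0, 255]")
  parity <- rs_parity_matrix(matrix(message, nrow = 1L), params)
  c(message, as.integer(parity[1L, ]))
}

# Syndromes for a matrix of codewords (rows = words, n columns): Horner
# evaluation of each word at alpha^(fcr+j), vectorized across rows.
rs_syndromes_matrix <- function(words, params) {
  stopifnot(ncol(words) == params$n)
  nk <- params$n - params$k
  m <- nrow(words)
  syn <- matrix(0L, m, nk)
  for (j in seq_len(nk)) {
    aj <- gf_pow(2L, params$fcr + j - 1L, params$prim)
    s <- integer(m)
    for (i in seq_len(params$n)) {
      s <- bitwXor(gf_mul(s, aj, params$prim), words[, i])
    }
    syn[, j] <- s
  }
  syn
}

#' RS error detection
#'
#' Declares a word clean iff all `n - k` syndromes are zero. No correction is
#' attempted: words failing detection are handed to the clustering stages,
#' and unrecovered oligos become erasures for the outer fountain code.
#'
#' @param word integer vector of `n` symbols, or a matrix with `n` columns
#'   (one word per row).
#' @param params an [rs_params()] object.
#' @return logical: `TRUE` for clean words (vector of length `nrow` for a
#'   matrix input).
#' @export
rs_detect <- function(word, params = rs_params()) {
  if (is.matrix(word)) {
    syn <- rs_syndromes_matrix(word, params)
    return(rowSums(syn != 0L) == 0L)
  }
  word <- as.integer(word)
  if (length(word) != params$n) stop("word must have exactly n symbols")
  syn <- rs_syndromes_matrix(matrix(word, nrow = 1L), params)
  all(syn == 0L)
}
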