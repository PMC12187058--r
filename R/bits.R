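# Bit-level plumbing. Convention throughout the package: a "bit vector" is an
# integer vector of 0/1, most-significant bit first within every byte, symbol,
# and 32-bit seed. This fixes the on-DNA layout (seed || payload || parity ->
# bases) so that stored pools are bit-exact reproducible.

assert_bits <- function(bits) {
  if (!is.numeric(bits) || any(is.na(bits)) || !all(bits %in% c(0L, 1L)))
    stop("expected a vector of 0/1 bits")
  as.integer(bits)
}

#' Convert bits to DNA bases and back
#'
#' Two bits map to one base under the rule A=00, C=01, G=10, T=11
#' (most-significant bit first). `bases_to_bits()` is the exact inverse.
#'
#' @param bits integer vector of 0/1, even length.
#' @param bases string over A/C/G/T.
#' @return `bits_to_bases()`: a single string; `bases_to_bits()`: an integer
#'   vector of 0/1 twice the string length.
#' @examples
#' bits_to_bases(c(0,0,0,1,1,0,1,1))  # "ACGT"
#' @export
bits_to_bases <- function(bits) {
  cpp_bits_to_bases(assert_bits(bits))
}

#' @rdname bits_to_bases
#' @export
bases_to_bits <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  cpp_bases_to_bits(bases)
}

# bytes (raw) <-> bits, big-endian within each byte
bytes_to_bits <- function(raw) {
  if (length(raw) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(raw)), nrow = 8L)
  as.vector(m[8:1, , drop = FALSE])
}

bits_to_bytes <- function(bits) {
  bits <- assert_bits(bits)
  stopifnot(length(bits) %% 8L == 0L)
  m <- matrix(bits, nrow = 8L)
  packBits(as.integer(m[8:1, , drop = FALSE]), type = "raw")
}

# 8-bit symbols (integers 0..255) <-> bits
bits_to_symbols <- function(bits) {
  bits <- assert_bits(bits)
  stopifnot(length(bits) %% 8L == 0L)
  m <- matrix(bits, nrow = 8L)
  as.integer(colSums(m * 2L^(7:0)))
}

symbols_to_bits <- function(sym) {
  stopifnot(all(sym >= 0L & sym <= 255L))
  as.vector(vapply(sym, function(s) as.integer(bitwAnd(bitwShiftR(s, 7:0), 1L)),
                   integer(8)))
}

# 32-bit unsigned seed (stored as double) <-> 32 bits, MSB first
int_to_bits32 <- function(x) {
  stopifnot(length(x) == 1L, x >= 0, x < 2^32, x == floor(x))
  as.integer(floor(x / 2^(31:0)) %% 2)
}

bits32_to_int <- function(bits) {
  bits <- assert_bits(bits)
  stopifnot(length(bits) == 32L)
  sum(bits * 2^(31:0))
}
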