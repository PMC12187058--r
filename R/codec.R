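# File segmentation, oligo assembly/parsing, biochemical constraint
# screening, and the full encoder pipeline. Bit layout of one oligo:
# 32-bit seed || 256-bit payload || 16-bit RS parity = 304 bits = 152 nt.

#' Split a byte string into 256-bit segments
#'
#' Consecutive 256-bit (32-byte) chunks in input order; the last chunk is
#' zero-padded and the original byte length recorded so decoding can truncate
#' exactly.
#'
#' @param data raw vector (non-empty).
#' @return a `segment_set`: list with `bits` (K x 256 integer 0/1 matrix),
#'   `K`, and `n_bytes` (original length).
#' @export
segmentize <- function(data) {
  stopifnot(is.raw(data))
  if (length(data) == 0L) stop("empty input")
  n_bytes <- length(data)
  pad <- (-n_bytes) %% 32L
  if (pad > 0L) data <- c(data, raw(pad))
  bits <- bytes_to_bits(data)
  K <- length(bits) %/% 256L
  structure(list(bits = matrix(bits, nrow = K, ncol = 256L, byrow = TRUE),
                 K = K, n_bytes = n_bytes),
            class = "segment_set")
}

#' Biochemical constraint specification
#'
#' Designed oligos must avoid homopolymer runs of four or more identical
#' bases and keep GC content within a window (inclusive bounds).
#'
#' @param max_run longest allowed homopolymer run (default 3, i.e. runs of
#'   length four or more are rejected).
#' @param gc_min,gc_max GC-content bounds in percent (default 45-55).
#' @param screened_region `"seed_plus_payload"` (default: the 144 nt carrying
#'   seed and payload, matching screening before parity is attached) or
#'   `"full_oligo"`.
#' @return a `constraint_spec` object.
#' @export
constraint_spec <- function(max_run = 3L, gc_min = 45, gc_max = 55,
                            screened_region = c("seed_plus_payload", "full_oligo")) {
  stopifnot(gc_min > 0, gc_min <= gc_max, gc_max < 100, max_run >= 1L)
  structure(list(max_run = as.integer(max_run), gc_min = gc_min, gc_max = gc_max,
                 screened_region = match.arg(screened_region)),
            class = "constraint_spec")
}

#' Check a sequence against the biochemical constraints
#'
#' @param bases ACGT string.
#' @param spec a [constraint_spec()].
#' @return logical (`TRUE` = pass) with attribute `reason` (`"ok"`,
#'   `"homopolymer"`, or `"gc_content"`).
#' @export
check_constraints <- function(bases, spec = constraint_spec()) {
  code <- cpp_check_constraints(bases, spec$max_run, spec$gc_min, spec$gc_max)
  structure(code == 0L, reason = c("ok", "homopolymer", "gc_content")[code + 1L])
}

gc_percent <- function(bases) {
  n <- nchar(bases)
  gc <- nchar(gsub("[AT]", "", bases))
  100 * gc / n
}

#' Assemble an oligo from seed and payload
#'
#' Computes the RS parity over the 36 message symbols (seed || payload) and
#' maps the 304-bit layout to 152 bases.
#'
#' @param seed 32-bit unsigned integer (double).
#' @param payload_bits 256-bit 0/1 vector.
#' @param params [rs_params()] of the inner code.
#' @return list with `seed`, `payload_bits`, `parity_bits`, and `bases`
#'   (152-nt string).
#' @export
assemble_oligo <- function(seed, payload_bits, params = rs_params()) {
  payload_bits <- assert_bits(payload_bits)
  stopifnot(length(payload_bits) == 256L)
  msg_bits <- c(int_to_bits32(seed), payload_bits)
  parity <- rs_encode(bits_to_symbols(msg_bits), params)[(params$k + 1L):params$n]
  parity_bits <- symbols_to_bits(parity)
  list(seed = seed, payload_bits = payload_bits, parity_bits = parity_bits,
       bases = cpp_bits_to_bases(c(msg_bits, parity_bits)))
}

#' Parse a 152-nt oligo read
#'
#' Inverse of [assemble_oligo()] on the clean path; `detect_pass` reports the
#' RS syndrome check.
#'
#' @param bases 152-nt ACGT string.
#' @param params [rs_params()].
#' @return list with `seed`, `payload_bits`, `detect_pass`.
#' @export
parse_oligo <- function(bases, params = rs_params()) {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (nchar(bases) != params$n * 4L)
    stop("oligo must have exactly ", params$n * 4L, " bases")
  bits <- cpp_bases_to_bits(bases)
  sym <- bits_to_symbols(bits)
  list(seed = bits32_to_int(bits[1:32]),
       payload_bits = bits[33:288],
       detect_pass = rs_detect(sym, params))
}

# Batched parse/detect for many equal-length reads: reads -> symbol matrix.
seqs_to_symbol_matrix <- function(seqs, width) {
  codes <- match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                 c("A", "C", "G", "T")) - 1L
  if (anyNA(codes)) stop("non-ACGT character in input sequences")
  cm <- matrix(codes, ncol = width, byrow = TRUE)
  nsym <- width %/% 4L
  out <- matrix(0L, nrow(cm), nsym)
  for (s in seq_len(nsym)) {
    j <- (s - 1L) * 4L
    out[, s] <- cm[, j + 1L] * 64L + cm[, j + 2L] * 16L + cm[, j + 3L] * 4L + cm[, j + 4L]
  }
  out
}

# Vectorized detection over a character vector of 152-nt reads.
detect_sequences <- function(seqs, params = rs_params()) {
  if (length(seqs) == 0L) return(logical(0))
  rs_detect(seqs_to_symbol_matrix(seqs, params$n * 4L), params)
}

# Vectorized (seed, payload) extraction; assumes detection already passed.
parse_sequences <- function(seqs, params = rs_params()) {
  codes <- match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                 c("A", "C", "G", "T")) - 1L
  cm <- matrix(codes, ncol = params$n * 4L, byrow = TRUE)
  bm <- matrix(0L, nrow(cm), params$n * 8L)
  bm[, seq(1L, ncol(bm), 2L)] <- bitwShiftR(cm, 1L)
  bm[, seq(2L, ncol(bm), 2L)] <- bitwAnd(cm, 1L)
  seeds <- as.numeric(bm[, 1:32, drop = FALSE] %*% 2^(31:0))
  list(seeds = seeds, payloads = bm[, 33:288, drop = FALSE])
}

#' Encode a file into constraint-screened oligos
#'
#' Rejection-samples droplet seeds (sequential increments from a random
#' 32-bit start) until each droplet's screened region passes
#' [check_constraints()]. Deterministic given `rng_seed`.
#'
#' @param data raw vector to encode.
#' @param n_droplets number of oligos to emit.
#' @param config optional [lt_config()]; defaults to `lt_config(K)` with `K`
#'   implied by `data`.
#' @param spec a [constraint_spec()].
#' @param rng_seed integer seed controlling the start of the seed search.
#' @param params [rs_params()] of the inner code.
#' @param max_attempts rejection budget per droplet.
#' @return an `oligo_set`: data.frame with columns `index`, `seed`, `degree`,
#'   `bases`, plus attributes `K`, `n_bytes`, `config`, `spec`,
#'   `attempted` (total candidate seeds examined).
#' @export
encode_file <- function(data, n_droplets, config = NULL,
                        spec = constraint_spec(), rng_seed = 1L,
                        params = rs_params(), max_attempts = 10000L) {
  stopifnot(n_droplets >= 1L)
  segments <- segmentize(data)
  if (is.null(config)) config <- lt_config(segments$K)
  stopifnot(config$K == segments$K)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  # Weyl sequence: odd golden-ratio stride visits all 2^32 seeds without
  # repetition, and unlike +1 increments never parks the search inside a
  # region whose high seed bits map to a constraint-violating base pattern
  seed_cursor <- floor(runif(1) * 2^32)
  seed_stride <- 2654435761

  full <- spec$screened_region == "full_oligo"
  seeds <- numeric(n_droplets)
  degrees <- integer(n_droplets)
  bases <- character(n_droplets)
  payloads <- matrix(0L, n_droplets, 256L)
  attempted <- 0L
  for (i in seq_len(n_droplets)) {
    ok <- FALSE
    for (try in seq_len(max_attempts)) {
      s <- seed_cursor
      seed_cursor <- (seed_cursor + seed_stride) %% 2^32
      attempted <- attempted + 1L
      nbr <- lt_neighbors(s, config)
      payload <- cpp_xor_rows(segments$bits, nbr)
      msg_bits <- c(int_to_bits32(s), payload)
      if (full) {
        parity <- rs_encode(bits_to_symbols(msg_bits), params)[(params$k + 1L):params$n]
        cand <- cpp_bits_to_bases(c(msg_bits, symbols_to_bits(parity)))
        region <- cand
      } else {
        region <- cpp_bits_to_bases(msg_bits)
      }
      if (cpp_check_constraints(region, spec$max_run, spec$gc_min, spec$gc_max) == 0L) {
        seeds[i] <- s
        degrees[i] <- length(nbr)
        payloads[i, ] <- payload
        bases[i] <- if (full) cand else NA_character_
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("rejection-sampling budget exhausted for droplet ", i)
  }
  if (!full) {
    # parity for all accepted droplets at once
    seed_bits <- t(vapply(seeds, int_to_bits32, integer(32)))
    msg_mat <- cbind(seed_bits, payloads)
    sym <- matrix(0L, n_droplets, params$k)
    for (sidx in seq_len(params$k)) {
      j <- (sidx - 1L) * 8L
      sym[, sidx] <- as.integer(msg_mat[, (j + 1L):(j + 8L), drop = FALSE] %*% 2L^(7:0))
    }
    parity <- rs_parity_matrix(sym, params)
    for (i in seq_len(n_droplets)) {
      pb <- symbols_to_bits(as.integer(parity[i, ]))
      bases[i] <- cpp_bits_to_bases(c(msg_mat[i, ], pb))
    }
  }
  out <- data.frame(index = seq_len(n_droplets), seed = seeds,
                    degree = degrees, bases = bases,
                    stringsAsFactors = FALSE)
  structure(out, K = segments$K, n_bytes = segments$n_bytes,
            config = config, spec = spec, attempted = attempted,
            class = c("oligo_set", "data.frame"))
}

# RNG bookkeeping: run seeded code without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read designed oligos as FASTA
#'
#' One record per droplet; id is the zero-padded droplet index, description
#' the seed in hex.
#'
#' @param oligos an `oligo_set` from [encode_file()].
#' @param path file path.
#' @return `read_oligos_fasta()` returns a data.frame with `index`, `seed`,
#'   `bases`.
#' @export
write_oligos_fasta <- function(oligos, path) {
  # seeds are doubles up to 2^32-1; format hex in two 16-bit halves
  hex <- sprintf("%04x%04x", as.integer(oligos$seed %/% 2^16),
                 as.integer(oligos$seed %% 2^16))
  x <- Biostrings::DNAStringSet(oligos$bases)
  names(x) <- sprintf("oligo%06d seed=%s", oligos$index, hex)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_oligos_fasta
#' @export
read_oligos_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  seed_hex <- sub(".*seed=([0-9a-f]+).*", "\\1", nm)
  data.frame(index = seq_along(x),
             seed = vapply(seed_hex, hex_to_double, numeric(1), USE.NAMES = FALSE),
             bases = as.character(x),
             stringsAsFactors = FALSE)
}

hex_to_double <- function(h) {
  digits <- match(strsplit(tolower(h), "")[[1]],
                  c(0:9, letters[1:6])) - 1
  sum(digits * 16^(rev(seq_along(digits)) - 1))
}
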