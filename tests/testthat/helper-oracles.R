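# Independent oracles. None of these share code paths with the package:
# field arithmetic by carry-less shift-and-add, polynomial evaluation by
# Horner over that multiply, edit distance by a plain R DP, erasure decoding
# by Gaussian elimination over GF(2), and candidate streams by exhaustive
# enumeration.

# carry-less "Russian peasant" GF(2^8) multiply, reduced by prim
peasant_mul <- function(a, b, prim = 285L) {
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    b <- bitwShiftR(b, 1L)
    a <- bitwShiftL(a, 1L)
    if (a >= 256L) a <- bitwAnd(bitwXor(a, prim), 255L)
  }
  r
}

# evaluate a codeword polynomial (first symbol = highest degree) at x
horner_eval <- function(word, x, prim = 285L) {
  acc <- 0L
  for (s in word) acc <- bitwXor(peasant_mul(acc, x, prim), s)
  acc
}

# plain unit-cost edit distance DP (totals only)
brute_edit <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# Gaussian elimination over GF(2): which variables are uniquely determined by
# A x = y (A: m x K over 0/1; y: m x nbits), and their values.
ge_gf2 <- function(A, Y) {
  A <- A %% 2L
  m <- nrow(A); K <- ncol(A)
  pivots <- integer(0)
  pivot_row <- integer(0)
  r <- 1L
  for (col in seq_len(K)) {
    pr <- which(A[r:m, col] == 1L)
    if (length(pr) == 0L) next
    pr <- pr[1L] + r - 1L
    if (pr != r) {
      A[c(pr, r), ] <- A[c(r, pr), ]
      Y[c(pr, r), ] <- Y[c(r, pr), ]
    }
    for (rr in seq_len(m)) {
      if (rr != r && A[rr, col] == 1L) {
        A[rr, ] <- bitwXor(A[rr, ], A[r, ])
        Y[rr, ] <- bitwXor(Y[rr, ], Y[r, ])
      }
    }
    pivots <- c(pivots, col)
    pivot_row <- c(pivot_row, r)
    r <- r + 1L
    if (r > m) break
  }
  free <- setdiff(seq_len(K), pivots)
  determined <- logical(K)
  values <- matrix(0L, K, ncol(Y))
  for (i in seq_along(pivots)) {
    row <- A[pivot_row[i], ]
    if (all(row[free] == 0L)) {
      determined[pivots[i]] <- TRUE
      values[pivots[i], ] <- Y[pivot_row[i], ]
    }
  }
  list(determined = determined, values = values)
}

# exhaustive bit-candidate stream: all assignments over split positions,
# sorted by (score desc, flip count asc, lexicographic flip tuple)
exhaustive_bit_stream <- function(bitmat, weights) {
  votes1 <- colSums(bitmat * weights, na.rm = TRUE)
  total <- colSums((!is.na(bitmat)) * weights)
  p1 <- votes1 / total
  majority <- as.integer(p1 > 0.5)
  split <- which(p1 > 0 & p1 < 1)
  n <- length(split)
  combos <- expand.grid(rep(list(0:1), n))
  cand <- lapply(seq_len(nrow(combos)), function(i) {
    flip <- split[which(combos[i, ] == 1L)]
    bits <- majority
    bits[flip] <- 1L - bits[flip]
    freq <- ifelse(bits[split] == 1L, p1[split], 1 - p1[split])
    list(bits = bits, score = prod(freq), flips = flip)
  })
  key <- vapply(cand, function(x)
    paste(sprintf("%04d", x$flips), collapse = ","), "")
  nf <- vapply(cand, function(x) length(x$flips), integer(1))
  sc <- vapply(cand, `[[`, numeric(1), "score")
  cand[order(-round(log(sc), 9), nf, key)]
}

# exhaustive null-candidate stream for d columns
exhaustive_null_stream <- function(freq, cols, d) {
  combos <- utils::combn(cols, d)
  sc <- apply(combos, 2, function(ix) prod(freq[ix]))
  key <- apply(combos, 2, function(ix) paste(sprintf("%05d", ix), collapse = ","))
  ord <- order(-round(log(sc), 9), key)
  lapply(ord, function(i) list(positions = combos[, i], score = sc[i]))
}

# fixtures -------------------------------------------------------------

random_bases <- function(n, len = NULL) {
  if (is.null(len)) len <- n
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

# assemble n clean oligos with sequential seeds and random payloads
make_test_oligos <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    data.frame(
      index = seq_len(n),
      seed = as.numeric(seq_len(n) + 1000),
      bases = vapply(seq_len(n), function(i)
        assemble_oligo(i + 1000, sample(0:1, 256, replace = TRUE))$bases, ""),
      stringsAsFactors = FALSE)
  })
}

# substitute the base at position pos with a different fixed base
substitute_base <- function(bases, pos) {
  b <- substr(bases, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), b)[1]
  paste0(substr(bases, 1, pos - 1), repl,
         substr(bases, pos + 1, nchar(bases)))
}

delete_base_at <- function(bases, pos) {
  paste0(substr(bases, 1, pos - 1), substr(bases, pos + 1, nchar(bases)))
}

insert_base_at <- function(bases, pos, b = "A") {
  paste0(substr(bases, 1, pos - 1), b, substr(bases, pos, nchar(bases)))
}

zero_profile <- function() {
  error_profile(0, 0, 0,
                sub_runs = c(1, 0, 0, 0), del_runs = c(1, 0, 0, 0),
                ins_runs = c(1, 0, 0, 0),
                length_dist = c(0, 0, 0, 1, 0, 0), f_bad = 0, m_bad = 1)
}
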