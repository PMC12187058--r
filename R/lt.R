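# LT fountain outer code: robust-soliton degree distribution, seeded droplet
# generation by XOR of segment subsets, and iterative (peeling) erasure
# decoding. The seed -> (degree, neighbors) map is a fixed, versioned 32-bit
# LCG (see src/core.cpp): it must stay stable across releases because the
# seeds are physically stored in the DNA pool.

#' Robust-soliton degree distribution
#'
#' Ideal soliton `rho(d)` plus the heavy-tail/spike term `tau(d)` with
#' parameters `c` and `delta`, normalized to sum to one.
#'
#' @param K number of source segments.
#' @param c spike-strength constant (> 0).
#' @param delta decoder failure-bound parameter in (0, 1).
#' @return numeric probability vector of length `K` over degrees `1..K`.
#' @export
robust_soliton <- function(K, c = 0.025, delta = 0.001) {
  stopifnot(K >= 1, c > 0, delta > 0, delta < 1)
  K <- as.integer(K)
  if (K == 1L) return(1)
  rho <- c(1 / K, 1 / ((2:K) * (1:(K - 1))))
  R <- c * log(K / delta) * sqrt(K)
  tau <- numeric(K)
  spike <- as.integer(round(K / R))
  if (R >= 1 && spike >= 2L && spike <= K) {
    d <- seq_len(spike - 1L)
    tau[d] <- R / (d * K)
    tau[spike] <- R * log(R / delta) / K
  }
  p <- rho + tau
  p / sum(p)
}

#' LT code configuration
#'
#' Bundles the segment count, the degree distribution (precomputed as a CDF
#' for the inverse-CDF draw), and the soliton parameters.
#'
#' @param K number of 256-bit segments.
#' @param c,delta robust-soliton parameters (see [robust_soliton()]).
#' @return an `lt_config` object.
#' @export
lt_config <- function(K, c = 0.025, delta = 0.001) {
  p <- robust_soliton(K, c, delta)
  structure(list(K = as.integer(K), c = c, delta = delta,
                 degree_dist = p, cum_dist = cumsum(p)),
            class = "lt_config")
}

lt_neighbors <- function(seed, config) {
  cpp_lt_neighbors(seed, config$cum_dist, config$K)
}

#' Generate one droplet from a seed
#'
#' Deterministically maps a 32-bit seed to a degree (inverse-CDF draw from the
#' robust-soliton distribution) and a neighbor set (Floyd's sampling without
#' replacement), and XORs the selected segments' payloads.
#'
#' @param seed 32-bit unsigned integer (supplied as a double).
#' @param segments a `segment_set` from [segmentize()] (all `K` segments
#'   present).
#' @param config an [lt_config()] object with matching `K`.
#' @return list with `seed`, `neighbors` (sorted 1-based segment indices) and
#'   `payload_bits` (256 bits).
#' @export
droplet_from_seed <- function(seed, segments, config) {
  stopifnot(inherits(segments, "segment_set"), config$K == segments$K)
  nbr <- lt_neighbors(seed, config)
  list(seed = seed,
       neighbors = nbr,
       payload_bits = cpp_xor_rows(segments$bits, nbr))
}

#' Iterative (peeling) erasure decoding
#'
#' Repeatedly resolves degree-1 droplets and XOR-subtracts each resolved
#' segment from every droplet containing it, until a fixpoint. Payloads are
#' assumed error-free: upstream RS detection has already filtered them.
#' Droplets sharing a seed are collapsed before decoding (a payload
#' disagreement logs a warning and keeps the first by input order).
#'
#' @param seeds numeric vector of droplet seeds.
#' @param payloads integer 0/1 matrix, one 256-bit row per droplet.
#' @param config an [lt_config()] object.
#' @return list with `recovered` (K x 256 bit matrix), `resolved` (logical K),
#'   and `unresolved` (integer indices of segments never resolved).
#' @export
peel_decode <- function(seeds, payloads, config) {
  K <- config$K
  nbits <- if (is.matrix(payloads)) ncol(payloads) else length(payloads)
  if (!is.matrix(payloads)) payloads <- matrix(payloads, nrow = 1L)
  stopifnot(length(seeds) == nrow(payloads))

  # collapse duplicate seeds (first occurrence wins)
  if (anyDuplicated(seeds)) {
    first <- !duplicated(seeds)
    for (s in unique(seeds[duplicated(seeds)])) {
      rows <- which(seeds == s)
      ref <- payloads[rows[1L], ]
      if (any(vapply(rows[-1L], function(r) any(payloads[r, ] != ref), logical(1))))
        warning("droplets with seed ", s, " disagree on payload; keeping first")
    }
    seeds <- seeds[first]
    payloads <- payloads[first, , drop = FALSE]
  }

  m <- length(seeds)
  recovered <- matrix(0L, K, nbits)
  resolved <- logical(K)
  if (m == 0L) {
    return(list(recovered = recovered, resolved = resolved,
                unresolved = seq_len(K)))
  }

  nbrs <- lapply(seeds, lt_neighbors, config = config)
  pay <- lapply(seq_len(m), function(i) payloads[i, ])
  deg <- vapply(nbrs, length, integer(1))
  # reverse index: segment -> droplets containing it
  seg2drop <- vector("list", K)
  for (i in seq_len(m)) for (s in nbrs[[i]]) {
    seg2drop[[s]] <- c(seg2drop[[s]], i)
  }

  queue <- which(deg == 1L)
  while (length(queue) > 0L) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    if (deg[i] != 1L) next
    s <- nbrs[[i]][1L]
    if (!resolved[s]) {
      resolved[s] <- TRUE
      recovered[s, ] <- pay[[i]]
      for (j in seg2drop[[s]]) {
        if (deg[j] == 0L) next
        if (s %in% nbrs[[j]]) {
          pay[[j]] <- bitwXor(pay[[j]], recovered[s, ])
          nbrs[[j]] <- setdiff(nbrs[[j]], s)
          deg[j] <- length(nbrs[[j]])
          if (deg[j] == 1L) queue <- c(queue, j)
        }
      }
    } else {
      # segment already known: subtract and keep peeling
      pay[[i]] <- bitwXor(pay[[i]], recovered[s, ])
      nbrs[[i]] <- integer(0)
      deg[i] <- 0L
    }
  }
  list(recovered = recovered, resolved = resolved,
       unresolved = which(!resolved))
}
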