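# Code-aided probabilistic majority-based (CAPMB) consensus. For a cluster's
# alignment: when the aligned length exceeds the original oligo length,
# candidate sets of "null" columns (of exactly the excess size) are ranked by
# the product of per-column gap frequencies; for each fixed null set the
# remaining rows are converted to bits and bit-level candidates are ranked by
# the product of per-position vote frequencies, starting from the plain
# majority. The first candidate passing the injected error-detection callable
# is the consensus; exhausting both budgeted streams is a normal outcome.

#' Rank null-column candidates
#'
#' Columns where a gap occurs at least once are scored by their weighted gap
#' frequency; candidates are all subsets of size `l_align - l_origin`,
#' emitted in non-increasing product-score order (ties: lexicographic on the
#' sorted position tuple), truncated to `budget`.
#'
#' @param alignment alignment list from [center_star_msa()] (`rows`,
#'   `weights`, `l_align`).
#' @param l_origin original oligo length.
#' @param budget maximum number of candidates (default 128).
#' @param max_columns when the candidate space is too large to enumerate,
#'   restrict to this many highest-frequency null columns (default 30).
#' @return list of candidates, each `list(positions, score)`; empty when the
#'   cluster cannot supply enough null columns.
#' @export
null_rank <- function(alignment, l_origin, budget = 128L, max_columns = 30L) {
  d <- alignment$l_align - l_origin
  if (d < 0L) stop("aligned length shorter than the original length")
  if (d == 0L) return(list(list(positions = integer(0), score = 1)))
  rows <- strsplit(alignment$rows, "", fixed = TRUE)
  w <- alignment$weights
  gapmat <- vapply(rows, function(r) r == "-", logical(alignment$l_align))
  freq <- as.numeric(gapmat %*% w) / sum(w)
  cols <- which(freq > 0)
  if (length(cols) < d) return(list())
  if (choose(length(cols), d) > 50000) {
    keep <- order(-freq[cols], cols)[seq_len(min(length(cols), max_columns))]
    cols <- sort(cols[keep])
    if (length(cols) < d || choose(length(cols), d) > 50000)
      return(list())  # candidate space too ambiguous for the budget
  }
  combos <- utils::combn(cols, d)
  score <- apply(combos, 2L, function(ix) prod(freq[ix]))
  key <- apply(combos, 2L, function(ix) paste(sprintf("%05d", ix), collapse = ","))
  ord <- order(-round(log(score), 9), key)
  ord <- ord[seq_len(min(length(ord), budget))]
  lapply(ord, function(i) list(positions = combos[, i], score = score[i]))
}

# k-best subsets of flip positions by product of ratios (Lawler-style lazy
# enumeration). logr must be sorted non-increasing, all <= 0. Frontier kept
# as parallel vectors: numeric scores for a fast which.max, the sets
# themselves in a list, tie-breaks (fewer flips, then lexicographic position
# tuple) evaluated only when scores actually tie.
topk_flip_sets <- function(logr, k) {
  n <- length(logr)
  out <- list(list(set = integer(0), logs = 0))
  if (n == 0L || k == 1L) return(out)
  # tie key: sum of 2^-pos encodes the sorted position tuple exactly (all
  # subsets of 1..n, n <= ~40, give distinct dyadic sums); among equal
  # scores and equal flip counts, larger key = lexicographically earlier.
  h_logs <- logr[1L]
  h_sets <- list(1L)
  h_nl <- 1L
  h_tie <- 0.5
  while (length(out) < k && length(h_logs) > 0L) {
    top <- max(h_logs)
    cand <- which(h_logs >= top - 1e-12)
    if (length(cand) > 1L)
      cand <- cand[order(h_nl[cand], -h_tie[cand])]
    pick <- cand[1L]
    set <- h_sets[[pick]]
    logs <- h_logs[pick]
    tie <- h_tie[pick]
    out[[length(out) + 1L]] <- list(set = set, logs = logs)
    m <- set[length(set)]
    if (m < n) {
      h_logs[pick] <- logs + logr[m + 1L]
      h_sets[[pick]] <- c(set, m + 1L)
      h_nl[pick] <- length(set) + 1L
      h_tie[pick] <- tie + 2^-(m + 1L)
      h_logs <- c(h_logs, logs - logr[m] + logr[m + 1L])
      h_sets[[length(h_sets) + 1L]] <- c(set[-length(set)], m + 1L)
      h_nl <- c(h_nl, length(set))
      h_tie <- c(h_tie, tie - 2^-m + 2^-(m + 1L))
    } else {
      h_logs <- h_logs[-pick]
      h_sets[[pick]] <- NULL
      h_nl <- h_nl[-pick]
      h_tie <- h_tie[-pick]
    }
  }
  out
}

#' Rank bit-level consensus candidates
#'
#' Per-position vote frequencies are computed over non-abstaining weighted
#' rows (a residual gap abstains rather than votes). Candidate 1 is the
#' per-position majority (ties: bit 0); subsequent candidates flip
#' non-unanimous positions in non-increasing product-score order. At most
#' `max_split` lowest-confidence positions are searched; any further split
#' positions stay frozen at their majority value.
#'
#' @param bitmat integer matrix of 0/1/NA, one row per unique member.
#' @param weights row multiplicities.
#' @param budget maximum number of candidates (default 1024).
#' @param max_split maximum number of searched split positions (default 20).
#' @return list of candidates `list(bits, score)` in rank order, or `NULL`
#'   if some position has no votes at all.
#' @export
bit_rank <- function(bitmat, weights, budget = 1024L, max_split = 20L) {
  stopifnot(is.matrix(bitmat), nrow(bitmat) == length(weights))
  votes1 <- colSums(bitmat * weights, na.rm = TRUE)
  total <- colSums((!is.na(bitmat)) * weights)
  if (any(total == 0)) return(NULL)
  p1 <- votes1 / total
  majority <- as.integer(p1 > 0.5)        # tie at 0.5 -> bit 0
  p_major <- pmax(p1, 1 - p1)
  split <- which(p1 > 0 & p1 < 1)
  conf <- abs(p1[split] - 0.5)
  free <- split[order(conf, split)]
  free <- free[seq_len(min(length(free), max_split))]
  # flip ratios sorted non-increasing (tie: position ascending)
  r <- (1 - p_major[free]) / p_major[free]
  ord <- order(-round(log(r), 12), free)
  free <- free[ord]
  logr <- log(r[ord])
  base_logscore <- sum(log(p_major[split]))
  sets <- topk_flip_sets(logr, budget)
  lapply(sets, function(nd) {
    bits <- majority
    flips <- free[nd$set]
    bits[flips] <- 1L - bits[flips]
    list(bits = bits, score = exp(base_logscore + nd$logs))
  })
}

# rows (gapped base strings) at fixed null set -> bit matrix with NA at gaps
rows_to_bitmat <- function(rows, drop_cols, l_origin) {
  chars <- strsplit(rows, "", fixed = TRUE)
  n <- length(rows)
  out <- matrix(NA_integer_, n, 2L * l_origin)
  for (i in seq_len(n)) {
    r <- chars[[i]]
    if (length(drop_cols) > 0L) r <- r[-drop_cols]
    code <- match(r, c("A", "C", "G", "T")) - 1L   # NA for '-'
    out[i, seq(1L, 2L * l_origin, 2L)] <- bitwShiftR(code, 1L)
    out[i, seq(2L, 2L * l_origin, 2L)] <- bitwAnd(code, 1L)
  }
  out
}

#' Make an RS-syndrome detector callable
#'
#' CAPMB takes the inner code as an injected pass/fail callable on bit
#' sequences, so any detection/correction code can stand behind it.
#'
#' @param params [rs_params()].
#' @return function mapping a 0/1 bit vector of length `8 * n` (or a matrix
#'   with one candidate per row) to logical.
#' @export
make_rs_detector <- function(params = rs_params()) {
  force(params)
  function(bits) {
    if (is.matrix(bits)) {
      sym <- matrix(0L, nrow(bits), params$n)
      for (s in seq_len(params$n)) {
        j <- (s - 1L) * 8L
        sym[, s] <- as.integer(bits[, (j + 1L):(j + 8L), drop = FALSE] %*% 2L^(7:0))
      }
      rs_detect(sym, params)
    } else {
      rs_detect(bits_to_symbols(bits), params)
    }
  }
}

#' CAPMB consensus for an aligned cluster
#'
#' Outer loop over ranked null-column candidates; for each fixed null set the
#' remaining columns are converted to bits and the inner loop walks ranked
#' bit candidates through the detector. The first passing candidate is the
#' consensus. Both loops are budget-capped; running out of candidates is the
#' normal `exhausted` status.
#'
#' @param cluster a `read_cluster` with an alignment (see
#'   [center_star_msa()]).
#' @param detector pass/fail callable on 0/1 bit vectors (default: RS(38,36)
#'   syndrome check).
#' @param l_origin original oligo length (default 152).
#' @param budgets list with `max_null`, `max_bit`, `max_split`.
#' @return a `consensus_result`: list with `sequence` (or `NA`), `status`
#'   (`"error_free"` or `"exhausted"`), `null_candidates_tried`,
#'   `bit_candidates_tried`.
#' @export
capmb <- function(cluster, detector = make_rs_detector(), l_origin = 152L,
                  budgets = list(max_null = 128L, max_bit = 1024L,
                                 max_split = 20L)) {
  if (is.null(cluster$alignment)) cluster <- center_star_msa(cluster)
  aln <- cluster$alignment
  if (aln$l_align < l_origin)
    stop("aligned length shorter than the original length; cluster rejected")
  nulls <- null_rank(aln, l_origin, budget = budgets$max_null)
  n_null <- 0L
  n_bit <- 0L
  for (nc in nulls) {
    n_null <- n_null + 1L
    bm <- rows_to_bitmat(aln$rows, nc$positions, l_origin)
    cands <- bit_rank(bm, aln$weights, budget = budgets$max_bit,
                      max_split = budgets$max_split)
    if (is.null(cands)) next   # a position with no votes under this null set
    # candidates are tried strictly in rank order; detection is evaluated in
    # growing batches purely for speed (the first candidate usually decides)
    idx <- 1L
    chunk <- 1L
    hit_bits <- NULL
    while (idx <= length(cands)) {
      take <- seq(idx, min(idx + chunk - 1L, length(cands)))
      cmat <- do.call(rbind, lapply(cands[take], `[[`, "bits"))
      pass <- tryCatch(detector(cmat), error = function(e) NULL)
      if (is.null(pass) || length(pass) != nrow(cmat))
        pass <- vapply(seq_len(nrow(cmat)),
                       function(i) isTRUE(detector(cmat[i, ])), logical(1))
      hit <- which(pass)
      if (length(hit) > 0L) {
        n_bit <- n_bit + hit[1L]
        hit_bits <- cmat[hit[1L], ]
        break
      }
      n_bit <- n_bit + nrow(cmat)
      idx <- idx + length(take)
      chunk <- min(chunk * 8L, 512L)
    }
    if (!is.null(hit_bits)) {
      return(structure(list(sequence = cpp_bits_to_bases(hit_bits),
                            status = "error_free",
                            null_candidates_tried = n_null,
                            bit_candidates_tried = n_bit),
                       class = "consensus_result"))
    }
  }
  structure(list(sequence = NA_character_, status = "exhausted",
                 null_candidates_tried = n_null,
                 bit_candidates_tried = n_bit),
            class = "consensus_result")
}
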