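# The three clustering procedures and the alignment machinery.
# Stage 1 groups identical original-length reads. Stage 2 runs a greedy
# sphere sweep (abundance-ranked centers absorb everything within edit
# distance tau_e). Stage 3 matches abnormal-length reads to single EDOL
# centers by the length-adjusted edit distance, optionally capped per error
# type. Alignment is a deterministic center-star construction around the
# cluster center ("once a gap, always a gap"), which for small near-identical
# clusters is equivalent to a heuristic MSA but reproducible.

#' Edit distance with per-type operation counts
#'
#' Unit-cost global alignment with a canonical backtrace (tie order:
#' match/substitution, then deletion, then insertion, walking back from the
#' end). The total `sub + del + ins` equals the Levenshtein distance;
#' orientation is `a -> b`, so `del - ins == nchar(a) - nchar(b)`.
#'
#' @param a,b ACGT strings (empty allowed).
#' @return named integer vector `c(sub, del, ins)`.
#' @export
edit_distance_counts <- function(a, b) {
  cpp_edit_counts(a, b)
}

#' Length-adjusted edit distance
#'
#' Edit distance minus the absolute length difference: indels forced by the
#' length mismatch between an original-length center and an abnormal-length
#' query are not held against the pair. Never negative.
#'
#' @param center original-length string.
#' @param query string of any length.
#' @return non-negative integer.
#' @export
adjusted_distance <- function(center, query) {
  d <- cpp_edit_distance(center, query, -1L)
  d - abs(nchar(center) - nchar(query))
}

# unique sequences with multiplicities, ordered by count desc then sequence
collapse_counts <- function(bases) {
  tb <- table(bases)
  cnt <- as.integer(tb)
  seqs <- names(tb)
  ord <- order(-cnt, seqs)
  data.frame(bases = seqs[ord], count = cnt[ord], stringsAsFactors = FALSE)
}

new_cluster <- function(center, members) {
  structure(list(center = center, members = members,
                 size = sum(members$count), alignment = NULL),
            class = "read_cluster")
}

#' Stage-1 exact clustering
#'
#' One cluster per distinct original-length sequence; the consensus is the
#' sequence itself. Output sorted by cluster size descending, ties broken
#' lexicographically by sequence.
#'
#' @param bases character vector of original-length reads.
#' @return list of `read_cluster` objects.
#' @export
stage1_cluster <- function(bases) {
  u <- collapse_counts(bases)
  lapply(seq_len(nrow(u)), function(i)
    new_cluster(u$bases[i], u[i, , drop = FALSE]))
}

#' Stage-2 sphere clustering
#'
#' Unique sequences are ranked by multiplicity (ties lexicographic); each
#' sequence joins the first existing center within edit distance `tau_e`,
#' otherwise it opens a new center (greedy sweep).
#'
#' @param bases character vector of EDOL reads (original length).
#' @param tau_e maximum edit distance to a center (default 5).
#' @return list of `read_cluster` objects in center-creation order, each with
#'   members carrying a `distance` column.
#' @export
sphere_cluster <- function(bases, tau_e = 5L) {
  u <- collapse_counts(bases)
  if (nrow(u) == 0L) return(list())
  assign <- cpp_sphere_sweep(u$bases, as.integer(tau_e))
  centers <- unique(assign)
  lapply(centers, function(ci) {
    idx <- which(assign == ci)
    mem <- u[idx, , drop = FALSE]
    mem$distance <- vapply(mem$bases, function(s)
      cpp_edit_distance(u$bases[ci], s, as.integer(tau_e)), integer(1),
      USE.NAMES = FALSE)
    new_cluster(u$bases[ci], mem)
  })
}

#' Cluster thresholds
#'
#' @param tau_e stage-2 sphere radius (default 5).
#' @param tau_adj stage-3 maximum adjusted distance (default 4).
#' @param cap_sub,cap_del,cap_ins optional per-error-type maxima applied to
#'   the canonical edit script in stage 3 (`NA` = no cap).
#' @return a `cluster_thresholds` object.
#' @export
cluster_thresholds <- function(tau_e = 5L, tau_adj = 4L,
                               cap_sub = NA, cap_del = NA, cap_ins = NA) {
  stopifnot(tau_e >= 0L, tau_adj >= 0L)
  structure(list(tau_e = as.integer(tau_e), tau_adj = as.integer(tau_adj),
                 cap_sub = cap_sub, cap_del = cap_del, cap_ins = cap_ins),
            class = "cluster_thresholds")
}

#' Stage-3 tailored length-adjusted clustering
#'
#' Every EDOL read is a center; an abnormal-length read joins the center with
#' the smallest adjusted distance provided it does not exceed `tau_adj` and
#' the optional per-type caps hold on the canonical script. Ties go to the
#' earlier center (EDOL input order). Centers with no members remain
#' singletons. A cluster holds a single EDOL read plus its AL members.
#'
#' @param edol_bases character vector of residual EDOL reads (length 152).
#' @param al_bases character vector of abnormal-length reads inside the
#'   target window.
#' @param thresholds a [cluster_thresholds()].
#' @return list of `read_cluster` objects, one per unique EDOL sequence;
#'   members carry `adjusted`, `e_sub`, `e_del`, `e_ins` columns (NA for the
#'   center row).
#' @export
stage3_cluster <- function(edol_bases, al_bases,
                           thresholds = cluster_thresholds()) {
  centers <- collapse_counts(edol_bases)
  if (nrow(centers) == 0L) return(list())
  al <- collapse_counts(al_bases)
  cap <- function(x) if (is.na(x)) -1L else as.integer(x)
  if (nrow(al) > 0L) {
    hit <- cpp_stage3_assign(centers$bases, al$bases,
                             thresholds$tau_adj,
                             cap(thresholds$cap_sub), cap(thresholds$cap_del),
                             cap(thresholds$cap_ins))
  } else {
    hit <- matrix(0L, 0L, 5L)
  }
  lapply(seq_len(nrow(centers)), function(ci) {
    crow <- centers[ci, , drop = FALSE]
    crow$adjusted <- NA_integer_
    crow$e_sub <- NA_integer_; crow$e_del <- NA_integer_; crow$e_ins <- NA_integer_
    idx <- which(hit[, 1L] == ci)
    if (length(idx) > 0L) {
      mem <- al[idx, , drop = FALSE]
      mem$adjusted <- hit[idx, 2L]
      mem$e_sub <- hit[idx, 3L]; mem$e_del <- hit[idx, 4L]; mem$e_ins <- hit[idx, 5L]
      mem <- rbind(crow, mem)
    } else mem <- crow
    new_cluster(centers$bases[ci], mem)
  })
}

#' Center-star multiple alignment of a cluster
#'
#' Every member is pairwise-aligned to the center under the canonical
#' backtrace; pairwise gaps are merged position-stably ("once a gap, always a
#' gap"): for every inter-center slot the widest insertion observed across
#' members is allocated, members left-align their insertions in it, and all
#' rows are padded to a common length `l_align`. Removing all `-` from any
#' row reproduces that member exactly.
#'
#' @param cluster a `read_cluster`.
#' @return the cluster with an `alignment` element: list with `rows`
#'   (character vector of gapped strings, center first), `weights`
#'   (multiplicities), `l_align`.
#' @export
center_star_msa <- function(cluster) {
  center <- cluster$center
  mem <- cluster$members
  L <- nchar(center)
  n <- nrow(mem)
  # per member: aligned-to-center gapped pair
  pairs <- lapply(seq_len(n), function(i) {
    if (mem$bases[i] == center) {
      c(center, center)
    } else cpp_align_pair(center, mem$bases[i])
  })
  # slot s (0..L) = insertions occurring before center position s+1
  ins_width <- integer(L + 1L)
  parsed <- lapply(pairs, function(p) {
    ga <- strsplit(p[1], "", fixed = TRUE)[[1]]
    gb <- strsplit(p[2], "", fixed = TRUE)[[1]]
    pos <- 0L
    col_base <- character(L)     # member char at each center position
    slot_ins <- vector("list", L + 1L)
    for (k in seq_along(ga)) {
      if (ga[k] == "-") {
        slot_ins[[pos + 1L]] <- c(slot_ins[[pos + 1L]], gb[k])
      } else {
        pos <- pos + 1L
        col_base[pos] <- gb[k]
      }
    }
    w <- vapply(slot_ins, length, integer(1))
    list(col_base = col_base, slot_ins = slot_ins, w = w)
  })
  for (p in parsed) ins_width <- pmax(ins_width, p$w)

  center_chars <- strsplit(center, "", fixed = TRUE)[[1]]
  if (all(ins_width == 0L)) {
    # common case: no member inserts relative to the center
    center_row <- center
    rows <- vapply(parsed, function(p) paste(p$col_base, collapse = ""), "")
  } else {
    width <- L + sum(ins_width)
    # column index of center position s in the merged frame
    pos_col <- cumsum(ins_width[seq_len(L)]) + seq_len(L)
    build_row <- function(col_base, slot_ins) {
      row <- rep("-", width)
      row[pos_col] <- col_base
      for (s in which(ins_width > 0L)) {
        ins <- slot_ins[[s]]
        if (length(ins) > 0L) {
          start <- if (s == 1L) 1L else pos_col[s - 1L] + 1L
          row[start:(start + length(ins) - 1L)] <- ins
        }
      }
      paste(row, collapse = "")
    }
    center_row <- build_row(center_chars, rep(list(character(0)), L + 1L))
    rows <- vapply(parsed, function(p) build_row(p$col_base, p$slot_ins), "")
  }

  # the center sequence is already present as a member row in stage 1/2
  # clusters; in stage-3 clusters the first member row *is* the center
  cluster$alignment <- list(rows = rows, weights = mem$count,
                            l_align = nchar(center_row),
                            center_row = center_row)
  cluster
}

#' @export
print.read_cluster <- function(x, ...) {
  cat("cluster: center", substr(x$center, 1, 24), "... size", x$size,
      "(", nrow(x$members), "unique )\n")
  invisible(x)
}
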