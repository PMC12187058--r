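# Synthetic merged-read channel. Emulates the two read populations produced
# by Illumina's chastity filter: pass-filter (PF) reads with low error rates
# and non-pass-filter (NPF) reads with a high substitution rate, plus the
# empirical run-length structure of error bursts, the merged-read length
# distribution, and the concentration of errors in a minority of "bad" reads.
# All per-class numbers default to the values measured on a real MiSeq run
# (substitution/deletion/insertion rates, run-length bins, length classes);
# the overdispersion mixture is the package's own generative choice.

LENGTH_CLASSES <- c("failure", "lt145", "145-151", "152", "153", "gt153")

#' Construct an error profile for one read class
#'
#' Rates are marginal per-base error probabilities; run-length distributions
#' are per-error-type masses over the bins `1`, `2`, `3-5`, `>=6` (realized
#' as uniform over 3..5 and 6 + geometric(1/2)). The overdispersion mixture
#' multiplies a "bad" fraction of reads' rates by `m_bad` and scales the rest
#' down so the marginal rates are preserved.
#'
#' @param sub_rate,del_rate,ins_rate marginal per-base error probabilities.
#' @param sub_runs,del_runs,ins_runs length-4 probability vectors over the
#'   run-length bins.
#' @param length_dist length-6 probability vector over the merged-read length
#'   classes `failure`, `<145`, `145-151`, `152`, `153`, `>153`.
#' @param f_bad fraction of reads carrying concentrated errors.
#' @param m_bad rate multiplier for those reads (requires `f_bad * m_bad < 1`).
#' @return an `error_profile` object.
#' @export
error_profile <- function(sub_rate, del_rate, ins_rate,
                          sub_runs, del_runs, ins_runs,
                          length_dist, f_bad = 0.05, m_bad = 15) {
  stopifnot(all(c(sub_rate, del_rate, ins_rate) >= 0),
            all(c(sub_rate, del_rate, ins_rate) <= 1),
            length(sub_runs) == 4L, length(del_runs) == 4L,
            length(ins_runs) == 4L, length(length_dist) == 6L,
            abs(sum(length_dist) - 1) < 1e-9,
            f_bad >= 0, f_bad < 1, m_bad >= 1, f_bad * m_bad < 1)
  norm <- function(p) p / sum(p)
  structure(list(sub_rate = sub_rate, del_rate = del_rate, ins_rate = ins_rate,
                 runs = list(sub = norm(sub_runs), del = norm(del_runs),
                             ins = norm(ins_runs)),
                 length_dist = setNames(length_dist, LENGTH_CLASSES),
                 f_bad = f_bad, m_bad = m_bad),
            class = "error_profile")
}

#' Default PF and NPF error profiles
#'
#' The per-class substitution/deletion/insertion rates, burst run-length
#' distributions, and merged-read length classes measured on the reference
#' MiSeq run.
#'
#' @return named list with elements `PF` and `NPF`, each an
#'   [error_profile()].
#' @export
default_profiles <- function() {
  list(
    PF = error_profile(
      sub_rate = 0.0009, del_rate = 0.0005, ins_rate = 0.0001,
      sub_runs = c(94.73, 3.71, 1.40, 0.17) / 100,
      del_runs = c(74.67, 12.12, 9.97, 3.23) / 100,
      ins_runs = c(98.62, 1.26, 0.11, 0.00) / 100,
      length_dist = c(8.94, 4.22, 2.80, 82.40, 1.01, 0.62) / 99.99),
    NPF = error_profile(
      sub_rate = 0.0384, del_rate = 0.0008, ins_rate = 0.0004,
      sub_runs = c(84.89, 11.91, 3.15, 0.06) / 100,
      del_runs = c(82.58, 10.13, 5.83, 1.46) / 100,
      ins_runs = c(97.37, 2.47, 0.17, 0.00) / 100,
      length_dist = c(35.98, 3.61, 1.89, 56.37, 0.65, 1.50) / 100)
  )
}

# mean realized run length for a bin distribution (geometric tail ratio 1/2)
mean_run_length <- function(runs) {
  sum(runs * c(1, 2, 4, 7))
}

draw_run_length <- function(runs) {
  bin <- sample.int(4L, 1L, prob = runs)
  switch(bin, 1L, 2L, sample(3:5, 1L), 6L + rgeom(1L, 0.5))
}

random_other_base <- function(b) {
  sample(setdiff(c("A", "C", "G", "T"), b), 1L)
}

#' Corrupt one oligo read through the error channel
#'
#' Error events land at uniformly random positions: for each error type, the
#' per-position event probability is the marginal base rate divided by the
#' mean run length, so that the realized per-base error rate matches the
#' profile. Each event expands to a run drawn from the type's run-length
#' distribution. Substitution runs replace each base with a uniformly random
#' different base; deletions remove a run; insertions insert uniformly random
#' bases. Events are applied right-to-left so recorded positions refer to the
#' clean oligo; the returned script replays exactly.
#'
#' @param oligo_bases clean ACGT string.
#' @param profile an [error_profile()].
#' @param multiplier per-read rate multiplier (overdispersion; default 1).
#' @return list with `bases` (the corrupted read) and `script` (data.frame
#'   of events: `pos`, `type`, `len`, `bases`).
#' @export
corrupt_read <- function(oligo_bases, profile, multiplier = 1) {
  L <- nchar(oligo_bases)
  events <- list()
  for (type in c("sub", "del", "ins")) {
    rate <- switch(type, sub = profile$sub_rate, del = profile$del_rate,
                   ins = profile$ins_rate)
    p_ev <- min(1, rate * multiplier / mean_run_length(profile$runs[[type]]))
    if (p_ev <= 0) next
    pos <- which(runif(L) < p_ev)
    for (p in pos) {
      events[[length(events) + 1L]] <-
        list(pos = p, type = type, len = draw_run_length(profile$runs[[type]]))
    }
  }
  if (length(events) == 0L) {
    return(list(bases = oligo_bases,
                script = data.frame(pos = integer(0), type = character(0),
                                    len = integer(0), bases = character(0),
                                    stringsAsFactors = FALSE)))
  }
  ord <- order(vapply(events, `[[`, 1L, "pos"),
               match(vapply(events, `[[`, "", "type"), c("sub", "del", "ins")),
               decreasing = TRUE)
  events <- events[ord]
  chars <- strsplit(oligo_bases, "", fixed = TRUE)[[1]]
  rec <- vector("list", length(events))
  for (e in seq_along(events)) {
    ev <- events[[e]]
    p <- ev$pos
    if (ev$type == "sub") {
      r <- min(ev$len, L - p + 1L)
      newb <- vapply(chars[p:(p + r - 1L)], random_other_base, "", USE.NAMES = FALSE)
      chars[p:(p + r - 1L)] <- newb
      rec[[e]] <- data.frame(pos = p, type = "sub", len = r,
                             bases = paste(newb, collapse = ""),
                             stringsAsFactors = FALSE)
    } else if (ev$type == "del") {
      r <- min(ev$len, length(chars) - p + 1L)
      if (r < 1L) next
      chars <- chars[-(p:(p + r - 1L))]
      rec[[e]] <- data.frame(pos = p, type = "del", len = r, bases = "",
                             stringsAsFactors = FALSE)
    } else {
      ins <- sample(c("A", "C", "G", "T"), ev$len, replace = TRUE)
      chars <- append(chars, ins, after = p - 1L)
      rec[[e]] <- data.frame(pos = p, type = "ins", len = ev$len,
                             bases = paste(ins, collapse = ""),
                             stringsAsFactors = FALSE)
    }
  }
  rec <- rec[!vapply(rec, is.null, logical(1))]
  script <- if (length(rec)) do.call(rbind, rec) else
    data.frame(pos = integer(0), type = character(0), len = integer(0),
               bases = character(0), stringsAsFactors = FALSE)
  list(bases = paste(chars, collapse = ""), script = script)
}

#' Replay an error script
#'
#' Applies a [corrupt_read()] script to the clean oligo; the result must
#' equal the simulated read (the script is an audit trail).
#'
#' @param oligo_bases clean ACGT string.
#' @param script script data.frame (rows already in application order:
#'   rightmost position first).
#' @return the reconstructed read string.
#' @export
replay_script <- function(oligo_bases, script) {
  chars <- strsplit(oligo_bases, "", fixed = TRUE)[[1]]
  for (e in seq_len(nrow(script))) {
    p <- script$pos[e]
    r <- script$len[e]
    switch(script$type[e],
      sub = { chars[p:(p + r - 1L)] <- strsplit(script$bases[e], "")[[1]] },
      del = { chars <- chars[-(p:(p + r - 1L))] },
      ins = { chars <- append(chars, strsplit(script$bases[e], "")[[1]],
                              after = p - 1L) },
      trunc = { chars <- chars[seq_len(r)] })
  }
  paste(chars, collapse = "")
}

# Force a corrupted read into a target length class. Returns list(bases,
# script) or NULL for the merge-failure class.
realize_length_class <- function(oligo_bases, profile, multiplier, class) {
  if (class == "failure") return(NULL)
  l0 <- nchar(oligo_bases)
  if (class == "152") {
    for (try in 1:30) {
      cr <- corrupt_read(oligo_bases, profile, multiplier)
      if (nchar(cr$bases) == l0) return(cr)
    }
    # fall back: substitutions only
    p2 <- profile; p2$del_rate <- 0; p2$ins_rate <- 0
    return(corrupt_read(oligo_bases, p2, multiplier))
  }
  target <- switch(class,
    "lt145"   = sample(100:144, 1L),
    "145-151" = sample(145:151, 1L),
    "153"     = 153L,
    "gt153"   = 154L + rgeom(1L, 0.5))
  cr <- corrupt_read(oligo_bases, profile, multiplier)
  len <- nchar(cr$bases)
  if (class == "lt145") {
    if (len > target) {
      # truncation acts on the already-corrupted read, so it replays last
      cr$script <- rbind(cr$script,
                         data.frame(pos = NA_integer_, type = "trunc",
                                    len = target, bases = "",
                                    stringsAsFactors = FALSE))
      cr$bases <- substr(cr$bases, 1L, target)
    }
    return(cr)
  }
  delta <- target - len
  if (delta == 0L) return(cr)
  chars <- strsplit(cr$bases, "", fixed = TRUE)[[1]]
  if (delta < 0L) {
    r <- -delta
    p <- sample.int(length(chars) - r + 1L, 1L)
    chars <- chars[-(p:(p + r - 1L))]
    extra <- data.frame(pos = p, type = "del", len = r, bases = "",
                        stringsAsFactors = FALSE)
  } else {
    ins <- sample(c("A", "C", "G", "T"), delta, replace = TRUE)
    p <- sample.int(length(chars) + 1L, 1L)
    chars <- append(chars, ins, after = p - 1L)
    extra <- data.frame(pos = p, type = "ins", len = delta,
                        bases = paste(ins, collapse = ""),
                        stringsAsFactors = FALSE)
  }
  # the adjustment acts on the already-corrupted read, so it must replay
  # after the original script rows
  cr$script <- rbind(cr$script, extra)
  cr$bases <- paste(chars, collapse = "")
  cr
}

#' Simulate a merged-read set from designed oligos
#'
#' Each attempted read draws a source oligo uniformly, a PF/NPF class by
#' `pf_fraction`, a length class from the class profile, and an
#' overdispersion multiplier; merge failures are dropped (counted in the
#' `n_failed` attribute). Deterministic under `rng_seed`.
#'
#' @param oligos an `oligo_set` (or any data.frame with a `bases` column).
#' @param n_reads number of attempted reads (failures included).
#' @param profiles named list `PF`/`NPF` of [error_profile()]s.
#' @param pf_fraction fraction of attempted reads that are PF
#'   (default 0.894, the reference run's PF share).
#' @param rng_seed integer seed.
#' @param adapter_tail_fraction fraction of emitted reads whose tail is
#'   contaminated with an adapter prefix (>= 7 nt) to exercise trimming.
#' @param adapters adapter list (see [default_adapters()]).
#' @return a `read_set`: data.frame with `id`, `bases`, `pf_class`,
#'   `true_oligo`; attributes `scripts` (list keyed by id), `n_failed`,
#'   `n_attempted`.
#' @export
simulate_readset <- function(oligos, n_reads, profiles = default_profiles(),
                             pf_fraction = 0.894, rng_seed = 1L,
                             adapter_tail_fraction = 0,
                             adapters = default_adapters()) {
  stopifnot(n_reads >= 1L, nrow(oligos) >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  src <- sample.int(nrow(oligos), n_reads, replace = TRUE)
  cls <- ifelse(runif(n_reads) < pf_fraction, "PF", "NPF")
  ids <- character(n_reads)
  bases <- character(n_reads)
  scripts <- vector("list", n_reads)
  keep <- logical(n_reads)
  n_failed <- 0L
  for (i in seq_len(n_reads)) {
    pr <- profiles[[cls[i]]]
    lclass <- sample(LENGTH_CLASSES, 1L, prob = pr$length_dist)
    mult <- if (runif(1) < pr$f_bad) pr$m_bad else
      (1 - pr$f_bad * pr$m_bad) / (1 - pr$f_bad)
    cr <- realize_length_class(oligos$bases[src[i]], pr, mult, lclass)
    if (is.null(cr)) { n_failed <- n_failed + 1L; next }
    keep[i] <- TRUE
    ids[i] <- sprintf("read%06d", i)
    bases[i] <- cr$bases
    scripts[[i]] <- cr$script
  }
  out <- data.frame(id = ids[keep], bases = bases[keep],
                    pf_class = cls[keep], true_oligo = src[keep],
                    stringsAsFactors = FALSE)
  if (adapter_tail_fraction > 0 && nrow(out) > 0L) {
    hit <- which(runif(nrow(out)) < adapter_tail_fraction)
    for (i in hit) {
      n_tail <- sample(7:nchar(adapters$tail), 1L)
      out$bases[i] <- paste0(out$bases[i], substr(adapters$tail, 1L, n_tail))
    }
  }
  structure(out, scripts = setNames(scripts[keep], ids[keep]),
            n_failed = n_failed, n_attempted = n_reads,
            class = c("read_set", "data.frame"))
}

#' Write / read a read set as FASTQ
#'
#' The description carries the PF/NPF class and (for simulated reads) the
#' source oligo; the quality line is a constant placeholder because the
#' workflow never uses qualities.
#'
#' @param reads a `read_set` (or data.frame with `id`, `bases`, `pf_class`,
#'   optionally `true_oligo`).
#' @param path file path.
#' @return `read_reads_fastq()` returns a data.frame with `id`, `bases`,
#'   `pf_class`, `true_oligo` (NA when absent from the description).
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  prov <- if (!is.null(reads$true_oligo)) sprintf(" oligo=%d", reads$true_oligo) else ""
  names(x) <- sprintf("%s class=%s%s", reads$id, reads$pf_class, prov)
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$bases)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(x)
  id <- sub("^(\\S+).*", "\\1", nm)
  cls <- ifelse(grepl("class=NPF", nm), "NPF",
                ifelse(grepl("class=PF", nm), "PF", NA_character_))
  oligo <- suppressWarnings(as.integer(sub(".*oligo=(\\d+).*", "\\1", nm)))
  oligo[!grepl("oligo=", nm)] <- NA_integer_
  data.frame(id = id, bases = as.character(x), pf_class = cls,
             true_oligo = oligo, stringsAsFactors = FALSE)
}
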