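# Orchestration: the three-stage workflow producing the error-free sequence
# sets S1/S2/S3, the outer erasure decode, end-to-end recovery, and the
# random-sampling experiment driver measuring reading cost (the minimum
# number of sampled reads needed for perfect recovery).

#' Stage 1: exact clustering of original-length reads
#'
#' Identical original-length reads (PF and NPF pooled) form clusters whose
#' trivial consensus is the read itself; consensus sequences are sorted by
#' cluster size and pushed through error detection. Passing sequences are S1
#' (deduplicated); the reads behind failing sequences become the EDOL input
#' to stage 2.
#'
#' @param pools a `read_pools` from [triage()].
#' @param params [rs_params()].
#' @return list with `S1` (character vector in size order), `R_EDOL`
#'   (data.frame of reads), and `counters`.
#' @export
run_stage1 <- function(pools, params = rs_params()) {
  orig <- rbind(pools$error_free, pools$edol)
  if (nrow(orig) == 0L) {
    return(list(S1 = character(0), R_EDOL = orig,
                counters = list(clusters = 0L, error_free = 0L, error_clusters = 0L)))
  }
  clusters <- stage1_cluster(orig$bases)
  seqs <- vapply(clusters, `[[`, "", "center")
  pass <- detect_sequences(seqs, params)
  S1 <- seqs[pass]
  edol_seqs <- seqs[!pass]
  R_EDOL <- orig[orig$bases %in% edol_seqs, , drop = FALSE]
  list(S1 = S1, R_EDOL = R_EDOL,
       counters = list(clusters = length(clusters),
                       error_free = sum(pass),
                       error_clusters = sum(!pass)))
}

#' Stage 2: sphere clustering + CAPMB on EDOL reads
#'
#' Sphere-clusters the residual EDOL reads at radius `tau_e`, aligns every
#' cluster of size two or larger, and runs CAPMB. Accepted consensus
#' sequences not already in S1 are S2, in cluster-size order; reads of
#' clusters that produced no accepted consensus (and all singletons) are the
#' residual EDOL set for stage 3.
#'
#' @param R_EDOL data.frame of EDOL reads (from [run_stage1()]).
#' @param S1 stage-1 sequences (for deduplication).
#' @param thresholds a [cluster_thresholds()].
#' @param detector inner-code callable (see [make_rs_detector()]).
#' @param l_origin original oligo length.
#' @param budgets CAPMB budgets (see [capmb()]).
#' @return list with `S2`, `RR_EDOL` (data.frame), and `counters`.
#' @export
run_stage2 <- function(R_EDOL, S1, thresholds = cluster_thresholds(),
                       detector = make_rs_detector(), l_origin = 152L,
                       budgets = list(max_null = 128L, max_bit = 1024L,
                                      max_split = 20L)) {
  empty <- list(S2 = character(0), RR_EDOL = R_EDOL,
                counters = list(clusters = 0L, clusters_ge2 = 0L,
                                corrected = 0L))
  if (is.null(R_EDOL) || nrow(R_EDOL) == 0L) return(empty)
  clusters <- sphere_cluster(R_EDOL$bases, thresholds$tau_e)
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  ord <- order(-sizes)
  consensus <- rep(NA_character_, length(clusters))
  n_ge2 <- 0L
  n_corr <- 0L
  for (i in ord) {
    if (sizes[i] < 2L) next
    n_ge2 <- n_ge2 + 1L
    res <- capmb(center_star_msa(clusters[[i]]), detector, l_origin, budgets)
    if (res$status == "error_free") {
      n_corr <- n_corr + 1L
      consensus[i] <- res$sequence
    }
  }
  accepted <- !is.na(consensus)
  S2 <- consensus[ord][accepted[ord]]
  S2 <- setdiff(unique(S2), S1)
  contributed <- unlist(lapply(clusters[accepted], function(cl) cl$members$bases))
  RR_EDOL <- R_EDOL[!(R_EDOL$bases %in% contributed), , drop = FALSE]
  list(S2 = S2, RR_EDOL = RR_EDOL,
       counters = list(clusters = length(clusters), clusters_ge2 = n_ge2,
                       corrected = n_corr))
}

#' Stage 3: length-adjusted clustering + CAPMB with abnormal-length reads
#'
#' Residual EDOL reads become centers; abnormal-length reads join them by the
#' adjusted edit distance. Clusters of size two or larger are aligned and run
#' through CAPMB; accepted sequences not in S1 or S2 are S3.
#'
#' @param RR_EDOL residual EDOL reads (data.frame).
#' @param R_AL abnormal-length reads (data.frame, e.g. `pools$al`).
#' @param S12 union of S1 and S2 (for deduplication).
#' @inheritParams run_stage2
#' @return list with `S3` and `counters`.
#' @export
run_stage3 <- function(RR_EDOL, R_AL, S12, thresholds = cluster_thresholds(),
                       detector = make_rs_detector(), l_origin = 152L,
                       budgets = list(max_null = 128L, max_bit = 1024L,
                                      max_split = 20L)) {
  empty <- list(S3 = character(0),
                counters = list(clusters = 0L, clusters_ge2 = 0L,
                                corrected = 0L))
  if (is.null(RR_EDOL) || nrow(RR_EDOL) == 0L) return(empty)
  al_bases <- if (is.null(R_AL)) character(0) else R_AL$bases
  clusters <- stage3_cluster(RR_EDOL$bases, al_bases, thresholds)
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  ord <- order(-sizes)
  consensus <- rep(NA_character_, length(clusters))
  n_ge2 <- 0L
  n_corr <- 0L
  for (i in ord) {
    if (sizes[i] < 2L) next
    n_ge2 <- n_ge2 + 1L
    res <- capmb(center_star_msa(clusters[[i]]), detector, l_origin, budgets)
    if (res$status == "error_free") {
      n_corr <- n_corr + 1L
      consensus[i] <- res$sequence
    }
  }
  accepted <- !is.na(consensus)
  S3 <- consensus[ord][accepted[ord]]
  S3 <- setdiff(unique(S3), S12)
  list(S3 = S3,
       counters = list(clusters = length(clusters), clusters_ge2 = n_ge2,
                       corrected = n_corr))
}

#' Outer erasure decode from error-free sequences
#'
#' Sequences are fed in stage order (S1, then S2, then S3), parsed to
#' (seed, payload) droplets, deduplicated (first occurrence wins), and
#' peel-decoded. On full recovery the segments are concatenated and truncated
#' to the original byte length.
#'
#' @param S1,S2,S3 character vectors of error-free 152-nt sequences.
#' @param config the [lt_config()] used at encode time.
#' @param n_bytes original file length in bytes.
#' @param params [rs_params()].
#' @return list with `bytes` (raw, or `NULL` when recovery is partial),
#'   `recovered` (logical), `n_unresolved`.
#' @export
decode_sequences <- function(S1, S2 = character(0), S3 = character(0),
                             config, n_bytes, params = rs_params()) {
  seqs <- c(S1, S2, S3)
  seqs <- seqs[!duplicated(seqs)]
  if (length(seqs) == 0L) {
    return(list(bytes = NULL, recovered = FALSE, n_unresolved = config$K))
  }
  parsed <- parse_sequences(seqs, params)
  keep <- !duplicated(parsed$seeds)
  dec <- peel_decode(parsed$seeds[keep],
                     parsed$payloads[keep, , drop = FALSE], config)
  if (length(dec$unresolved) > 0L) {
    return(list(bytes = NULL, recovered = FALSE,
                n_unresolved = length(dec$unresolved)))
  }
  bits <- as.vector(t(dec$recovered))
  bytes <- bits_to_bytes(bits)[seq_len(n_bytes)]
  list(bytes = bytes, recovered = TRUE, n_unresolved = 0L)
}

#' End-to-end recovery from a read set
#'
#' Runs triage and the selected workflow, then the outer decode.
#'
#' @param reads data.frame of merged reads (`id`, `bases`, `pf_class`).
#' @param config the encode-time [lt_config()].
#' @param n_bytes original file length.
#' @param scenario `"full_workflow"` (stages 1-3), or `"stage1_only"`
#'   (conventional exact-clustering analysis).
#' @param thresholds a [cluster_thresholds()].
#' @param l_origin,target_window triage parameters.
#' @param params [rs_params()].
#' @param budgets CAPMB budgets.
#' @param trim logical: trim adapter tails first.
#' @return list with `recovered`, `bytes`, `n_unresolved`, `stages`
#'   (per-stage sequence sets and counters).
#' @export
recover_reads <- function(reads, config, n_bytes,
                          scenario = c("full_workflow", "stage1_only"),
                          thresholds = cluster_thresholds(),
                          l_origin = 152L, target_window = c(145L, 153L),
                          params = rs_params(),
                          budgets = list(max_null = 128L, max_bit = 1024L,
                                         max_split = 20L),
                          trim = FALSE) {
  scenario <- match.arg(scenario)
  if (trim) reads$bases <- trim_adapter_tail(reads$bases)
  pools <- triage(reads, l_origin, target_window, params)
  st1 <- run_stage1(pools, params)
  detector <- make_rs_detector(params)
  if (scenario == "stage1_only") {
    dec <- decode_sequences(st1$S1, config = config, n_bytes = n_bytes,
                            params = params)
    return(c(dec, list(stages = list(S1 = st1$S1, counters1 = st1$counters))))
  }
  st2 <- run_stage2(st1$R_EDOL, st1$S1, thresholds, detector, l_origin, budgets)
  st3 <- run_stage3(st2$RR_EDOL, pools$al, c(st1$S1, st2$S2), thresholds,
                    detector, l_origin, budgets)
  dec <- decode_sequences(st1$S1, st2$S2, st3$S3, config = config,
                          n_bytes = n_bytes, params = params)
  c(dec, list(stages = list(S1 = st1$S1, S2 = st2$S2, S3 = st3$S3,
                            counters1 = st1$counters,
                            counters2 = st2$counters,
                            counters3 = st3$counters)))
}

# stratified sample of N reads preserving PF/NPF proportions; deterministic
# in (rng_seed, N) so different scenarios see the identical sample
sample_reads <- function(reads, n, rng_seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed %% 2147483647L)
  n <- min(n, nrow(reads))
  pf <- which(reads$pf_class == "PF")
  npf <- which(reads$pf_class != "PF")
  n_pf <- round(n * length(pf) / nrow(reads))
  n_pf <- min(max(n_pf, n - length(npf)), length(pf), n)
  idx <- c(sample(pf, n_pf), sample(npf, n - n_pf))
  reads[sort(idx), , drop = FALSE]
}

#' Random-sampling reading-cost experiment
#'
#' For each candidate sample size N (ascending grid), draws a stratified
#' sample of N reads (identical across scenarios for a given N) and records
#' whether each scenario's workflow achieves perfect recovery. The reading
#' cost of a scenario is the smallest N on the grid with success; the gain of
#' scenario s against the baseline (the first scenario listed) is
#' `(N_base - N_s) / N_base * 100`.
#'
#' @param reads full read set (data.frame).
#' @param config encode-time [lt_config()].
#' @param n_bytes original file length.
#' @param grid increasing integer vector of sample sizes.
#' @param scenarios named list: scenario name -> list(scenario =
#'   "stage1_only"/"full_workflow", classes = c("PF") or c("PF","NPF")).
#' @param rng_seed integer seed for the sampling draws.
#' @param ... passed to [recover_reads()].
#' @return data.frame with one row per scenario: `scenario`, `min_reads`
#'   (NA when never recovered on the grid), `recovered`, `gain_percent`.
#' @export
sampling_experiment <- function(reads, config, n_bytes, grid,
                                scenarios = list(
                                  stage1_only_PF_NPF =
                                    list(scenario = "stage1_only",
                                         classes = c("PF", "NPF")),
                                  full_workflow_PF_NPF =
                                    list(scenario = "full_workflow",
                                         classes = c("PF", "NPF"))),
                                rng_seed = 1L, ...) {
  grid <- sort(unique(as.integer(grid)))
  min_reads <- setNames(rep(NA_integer_, length(scenarios)), names(scenarios))
  for (n in grid) {
    if (all(!is.na(min_reads))) break
    smp <- sample_reads(reads, n, rng_seed + n)
    for (sc in names(scenarios)) {
      if (!is.na(min_reads[[sc]])) next
      sub <- smp[smp$pf_class %in% scenarios[[sc]]$classes, , drop = FALSE]
      res <- recover_reads(sub, config, n_bytes,
                           scenario = scenarios[[sc]]$scenario, ...)
      if (res$recovered) min_reads[[sc]] <- n
    }
  }
  base <- min_reads[[1L]]
  gain <- if (is.na(base)) rep(NA_real_, length(min_reads)) else
    (base - min_reads) / base * 100
  data.frame(scenario = names(scenarios),
             min_reads = as.integer(min_reads),
             recovered = !is.na(min_reads),
             gain_percent = as.numeric(gain),
             stringsAsFactors = FALSE, row.names = NULL)
}
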