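# Read hygiene before clustering: optional last-base deletion for raw-cycle
# reads, exact suffix adapter trimming, and triage of reads into the four
# pools the workflow consumes: error-free, EDOL (error-detected original
# length), AL (abnormal length inside the target window), discarded.

#' Delete the unstable last base of a raw-cycle read
#'
#' Basecalls from the final sequencing cycle are unreliable; raw-cycle mode
#' drops one base from every read. Off for simulator-emitted merged reads.
#'
#' @param bases read string(s), each of length >= 2.
#' @return string(s) shortened by one base.
#' @export
delete_last_base <- function(bases) {
  n <- nchar(bases)
  if (any(n < 2L)) stop("reads must have length >= 2")
  substr(bases, 1L, n - 1L)
}

#' Trim an adapter tail from a read
#'
#' If the read's suffix exactly matches a prefix of the adapter of length at
#' least `min_match`, that suffix is removed (the longest such match wins);
#' shorter matches and non-matches leave the read unchanged. Idempotent.
#'
#' @param bases read string(s).
#' @param adapter adapter sequence whose prefix may contaminate read tails.
#' @param min_match minimum match length to trim (default 7).
#' @return trimmed read string(s).
#' @export
trim_adapter_tail <- function(bases, adapter = default_adapters()$tail,
                              min_match = 7L) {
  stopifnot(nchar(adapter) >= 1L)
  vapply(bases, function(b) {
    L <- nchar(b)
    top <- min(nchar(adapter), L - 1L)
    if (top >= min_match) {
      for (m in top:min_match) {   # longest match wins
        if (substr(b, L - m + 1L, L) == substr(adapter, 1L, m))
          return(substr(b, 1L, L - m))
      }
    }
    b
  }, "", USE.NAMES = FALSE)
}

#' Triage reads into workflow pools
#'
#' Partition: reads of the original length that pass RS detection are
#' `error_free`; original-length reads failing detection are `edol`; reads
#' inside the target length window but of a different length are `al`;
#' everything else (including non-ACGT records) is `discarded`. Detection is
#' run only on original-length reads.
#'
#' @param reads data.frame with at least `id`, `bases`, `pf_class`.
#' @param l_origin original oligo length (default 152).
#' @param target_window inclusive length window for usable reads
#'   (default `c(145, 153)`).
#' @param params [rs_params()] of the inner code.
#' @return a `read_pools` list with data.frames `error_free`, `edol`, `al`,
#'   `discarded`.
#' @export
triage <- function(reads, l_origin = 152L, target_window = c(145L, 153L),
                   params = rs_params()) {
  stopifnot(target_window[1] <= l_origin, l_origin <= target_window[2])
  valid <- grepl("^[ACGT]+$", reads$bases)
  len <- nchar(reads$bases)
  pool <- rep("discarded", nrow(reads))
  in_window <- valid & len >= target_window[1] & len <= target_window[2]
  pool[in_window & len != l_origin] <- "al"
  orig <- which(valid & len == l_origin)
  if (length(orig) > 0L) {
    pass <- detect_sequences(reads$bases[orig], params)
    pool[orig[pass]] <- "error_free"
    pool[orig[!pass]] <- "edol"
  }
  out <- lapply(c(error_free = "error_free", edol = "edol", al = "al",
                  discarded = "discarded"),
                function(p) reads[pool == p, , drop = FALSE])
  structure(out, class = "read_pools")
}

#' @export
print.read_pools <- function(x, ...) {
  cat("read pools:",
      nrow(x$error_free), "error-free,",
      nrow(x$edol), "EDOL,",
      nrow(x$al), "AL,",
      nrow(x$discarded), "discarded\n")
  invisible(x)
}
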