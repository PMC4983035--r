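#' Parameters for the clustered-acidic window scan
#'
#' The detection criterion for a clustered-acidic C-terminal (Cter) domain: a
#' stretch of `window` consecutive residues in which at least
#' `min_fraction` are acidic (Asp or Glu by default), searched within the
#' last `tail_len` residues of the protein. With the defaults (window 10,
#' fraction 0.8) a window qualifies when it holds 8 or more D/E residues —
#' the comparison is inclusive. `tail_len` bounds "the C-terminus": the
#' published criterion restricts the search to the C-terminal region without
#' fixing its extent, so the region length is an explicit, overridable
#' parameter (default 50, which comfortably covers a 25-residue terminal
#' domain); `tail_len = "all"` scans the whole sequence.
#'
#' @param window window length in residues (default 10).
#' @param min_fraction minimum acidic fraction in a qualifying window,
#'   inclusive (default 0.8).
#' @param acidic residues counted as acidic (default `c("D", "E")`). `X` never
#'   counts as acidic.
#' @param tail_len length of the C-terminal search region, or `"all"`.
#' @return an `acidic_scan_params` list.
#' @export
acidic_scan_params <- function(window = 10L, min_fraction = 0.8,
                               acidic = c("D", "E"), tail_len = 50L) {
  window <- as.integer(window)
  stopifnot(length(window) == 1L, window >= 1L,
            length(min_fraction) == 1L, min_fraction > 0, min_fraction <= 1,
            is.character(acidic), length(acidic) >= 1L)
  if (identical(tail_len, "all")) {
    tail_len <- Inf
  } else {
    tail_len <- as.numeric(tail_len)
    stopifnot(length(tail_len) == 1L, tail_len >= 1)
    if (is.finite(tail_len) && window > tail_len) {
      stop("window must not exceed tail_len", call. = FALSE)
    }
  }
  if ("X" %in% acidic) stop("X cannot be counted as acidic", call. = FALSE)
  structure(list(window = window, min_fraction = min_fraction,
                 acidic = toupper(acidic), tail_len = tail_len),
            class = "acidic_scan_params")
}

#' Scan a sequence for clustered-acidic windows
#'
#' Every length-`window` substring of the search region (the last `tail_len`
#' residues) whose acidic fraction is at least `min_fraction` is reported, in
#' position order, with 1-based inclusive coordinates on the full sequence.
#' Sequences shorter than the window return an empty table with a warning.
#'
#' @param seq a single-row [protein_records()] data.frame or a residue string.
#' @param params an [acidic_scan_params()] object.
#' @return data.frame with columns `seq_id`, `start`, `end`, `acidic_count`,
#'   `fraction`.
#' @export
#' @examples
#' scan_acidic_windows("DEDEEGEEDEE", acidic_scan_params(tail_len = "all"))
scan_acidic_windows <- function(seq, params = acidic_scan_params()) {
  p <- as_seq_pair(seq, "seq")
  stopifnot(inherits(params, "acidic_scan_params"))
  L <- nchar(p$seq)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), acidic_count = integer(0),
                      fraction = numeric(0))
  if (L < params$window) {
    warning(sprintf("sequence '%s' (%d aa) shorter than window (%d); no scan",
                    p$id, L, params$window), call. = FALSE)
    return(empty)
  }
  region_start <- if (is.finite(params$tail_len)) {
    max(1L, L - as.integer(params$tail_len) + 1L)
  } else 1L
  chars <- strsplit(p$seq, "", fixed = TRUE)[[1]]
  is_acidic <- as.integer(chars %in% params$acidic)
  starts <- seq.int(region_start, L - params$window + 1L)
  if (length(starts) == 0L) return(empty)
  ## rolling window count of acidic residues
  cs <- c(0L, cumsum(is_acidic))
  counts <- cs[starts + params$window] - cs[starts]
  frac <- counts / params$window
  keep <- frac >= params$min_fraction
  data.frame(seq_id = rep(p$id, sum(keep)),
             start = starts[keep],
             end = starts[keep] + params$window - 1L,
             acidic_count = counts[keep],
             fraction = frac[keep])
}

#' Call Cter presence for one sequence
#'
#' A sequence is Cter-positive when the scan of its C-terminal region yields
#' at least one qualifying window. The best hit maximizes the acidic
#' fraction, with ties broken by the rightmost start.
#'
#' @inheritParams scan_acidic_windows
#' @return a `cter_call`: list with `seq_id`, `positive`, `n_hits`,
#'   `best_hit` (one-row data.frame or `NULL`) and `hits`.
#' @export
call_cter <- function(seq, params = acidic_scan_params()) {
  p <- as_seq_pair(seq, "seq")
  hits <- scan_acidic_windows(seq, params)
  best <- NULL
  if (nrow(hits) > 0L) {
    o <- order(hits$fraction, hits$start, decreasing = TRUE)
    best <- hits[o[1L], , drop = FALSE]
    rownames(best) <- NULL
  }
  structure(list(seq_id = p$id, positive = nrow(hits) >= 1L,
                 n_hits = nrow(hits), best_hit = best, hits = hits),
            class = "cter_call")
}

#' Classify every sequence of a family for Cter presence
#'
#' @param records a [protein_records()] data.frame.
#' @param params an [acidic_scan_params()] object.
#' @return data.frame with one row per record: `seq_id`, `positive`,
#'   `n_hits`, `best_start`, `best_end`, `best_fraction`; the counts of
#'   positive/negative calls are attached as attribute `summary`.
#' @export
classify_family <- function(records, params = acidic_scan_params()) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id)) {
    stop("duplicate sequence ids in family", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    cc <- call_cter(records[i, ], params)
    data.frame(seq_id = cc$seq_id,
               positive = cc$positive,
               n_hits = cc$n_hits,
               best_start = if (cc$positive) cc$best_hit$start else NA_integer_,
               best_end = if (cc$positive) cc$best_hit$end else NA_integer_,
               best_fraction = if (cc$positive) cc$best_hit$fraction else NA_real_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), positive = logical(0),
               n_hits = integer(0), best_start = integer(0),
               best_end = integer(0), best_fraction = numeric(0))
  attr(out, "summary") <- c(positive = sum(out$positive),
                            negative = sum(!out$positive))
  out
}
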