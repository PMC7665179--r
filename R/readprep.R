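#' Detect a terminal polyA / polyT tail
#'
#' Finds the longest terminal run — a 3' run of A or a 5' run of T — in
#' which non-matching bases make up at most `max_mismatch_frac` of the run,
#' the run extending to the sequence end and beginning with the tail base
#' (so a run never opens on a mismatch). Real tails carry sequencing
#' errors, hence the mismatch-tolerant definition. If the best qualifying
#' run is shorter than `min_tail` the report is `"none"`; when both ends
#' qualify the longer run wins, with ties going to the 3' end.
#'
#' @param seq non-empty nucleotide string.
#' @param min_tail minimum reportable run length in bp.
#' @param max_mismatch_frac tolerated fraction of non-A (non-T) bases.
#' @return list with `side` (`"three_prime"`, `"five_prime"` or `"none"`),
#'   `base` (`"A"`, `"T"` or `NA`), `length` and `trimmed_seq`.
#' @export
detect_tail <- function(seq, min_tail = 10L, max_mismatch_frac = 0.1) {
  if (!nzchar(seq)) stop("detect_tail: empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  # longest suffix run of `base` with tolerated mismatches, opening on `base`
  best_run <- function(x, base) {
    is_base <- rev(x) == base
    mism <- cumsum(!is_base)
    ok <- which(is_base & mism <= max_mismatch_frac * seq_len(length(x)))
    if (length(ok)) max(ok) else 0L
  }
  len3 <- best_run(ch, "A")
  len5 <- best_run(rev(ch), "T")
  if (max(len3, len5) < min_tail)
    return(list(side = "none", base = NA_character_, length = 0L,
                trimmed_seq = seq))
  if (len3 >= len5)
    list(side = "three_prime", base = "A", length = len3,
         trimmed_seq = substr(seq, 1L, n - len3))
  else
    list(side = "five_prime", base = "T", length = len5,
         trimmed_seq = substr(seq, len5 + 1L, n))
}

#' Trim polyA / polyT tails from records
#'
#' Applies [detect_tail()] repeatedly to every record until no terminal run
#' remains (a single removal can expose a shorter terminal run, so iterating
#' is what makes trimming idempotent). Records whose trimmed length falls
#' below `min_length` are dropped and counted. The per-read log records the
#' first (longest) detected run.
#'
#' @param records record data frame.
#' @param min_tail,max_mismatch_frac passed to [detect_tail()].
#' @param min_length drop floor for trimmed sequences, in bp.
#' @return list with `records` (trimmed, survivors only), `log` (read_id,
#'   side, base, length, trimmed_length, dropped) and `n_dropped`.
#' @export
trim_polya <- function(records, min_tail = 10L, max_mismatch_frac = 0.1,
                       min_length = 20L) {
  n <- nrow(records)
  log <- data.frame(read_id = records$id,
                    side = "none", base = NA_character_, length = 0L,
                    trimmed_length = nchar(records$seq), dropped = FALSE,
                    stringsAsFactors = FALSE)
  out <- records
  for (i in seq_len(n)) {
    s <- records$seq[i]
    first <- NULL
    lead <- 0L
    repeat {
      rep_i <- detect_tail(s, min_tail, max_mismatch_frac)
      if (rep_i$side == "none") break
      if (is.null(first)) first <- rep_i
      if (rep_i$side == "five_prime") lead <- lead + rep_i$length
      s <- rep_i$trimmed_seq
      if (!nzchar(s)) break
    }
    if (!is.null(first)) {
      log$side[i] <- first$side
      log$base[i] <- first$base
      log$length[i] <- first$length
    }
    log$trimmed_length[i] <- nchar(s)
    out$seq[i] <- s
    if (!is.na(out$qual[i]))
      out$qual[i] <- substr(records$qual[i], lead + 1L, lead + nchar(s))
  }
  log$dropped <- log$trimmed_length < min_length
  list(records = out[!log$dropped, , drop = FALSE],
       log = log, n_dropped = sum(log$dropped))
}
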