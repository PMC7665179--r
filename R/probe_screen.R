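#' Half-probe word set
#'
#' The selection rule for candidate satellite transcripts is an exact match
#' to at least half of a probe. This enumerates every distinct contiguous
#' probe substring of length `w = ceiling(frac * probe length)` together
#' with its reverse complement, labelled by strand and probe offset
#' (0-based half-open coordinates). The near-periodic probes collapse to
#' far fewer distinct words than windows.
#'
#' @param probe a probe list as returned by [dyz1_probe()].
#' @param frac fraction of the probe that must match exactly (0 < frac <= 1).
#' @return data frame with columns `word`, `strand` (`"plus"` for
#'   probe-strand words, `"minus"` for reverse complements), `p_start`,
#'   `p_end`.
#' @export
half_probe_set <- function(probe, frac = 0.5) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  L <- nchar(probe$seq)
  if (L < 2) stop("probe shorter than 2 bases")
  w <- ceiling(frac * L)
  starts <- seq_len(L - w + 1L)
  words <- substring(probe$seq, starts, starts + w - 1L)
  plus <- data.frame(word = words, strand = "plus",
                     p_start = starts - 1L, p_end = starts - 1L + w,
                     stringsAsFactors = FALSE)
  minus <- transform(plus, word = revcomp(words), strand = "minus")
  out <- rbind(plus, minus)
  out[!duplicated(out[c("word", "strand", "p_start")]), , drop = FALSE]
}

#' Screen transcripts for half-probe matches
#'
#' A transcript passes iff at least one half-probe word occurs in it
#' exactly, on either strand. All maximal matches are reported: word hits
#' lying on one alignment diagonal (plus strand: constant `t_start -
#' p_start`; minus strand: constant `t_start + p_start`) are merged into
#' maximal runs, so the transcript span always equals the probe span.
#' Reports are ordered by transcript input order, then position, then
#' strand.
#'
#' @param transcripts record data frame.
#' @param probe a probe list (see [dyz1_probe()]).
#' @param frac passed to [half_probe_set()].
#' @return list with `matches` (transcript_id, probe, strand, t_start,
#'   t_end, p_start, p_end, match_len; 0-based half-open), `pass`
#'   (logical named by transcript id, in input order) and `word_length`.
#' @export
screen_probe <- function(transcripts, probe, frac = 0.5) {
  words <- half_probe_set(probe, frac)
  w <- nchar(words$word[1])
  pass <- setNames(logical(nrow(transcripts)), transcripts$id)
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    tseq <- transcripts$seq[i]
    hits <- NULL
    for (uw in unique(words$word)) {
      tpos <- find_all(tseq, uw) - 1L      # 0-based
      if (!length(tpos)) next
      meta <- words[words$word == uw, , drop = FALSE]
      hits <- rbind(hits, merge(data.frame(t_start = tpos), meta))
    }
    if (is.null(hits) || !nrow(hits)) next
    pass[i] <- TRUE
    hits$diag <- ifelse(hits$strand == "plus",
                        hits$t_start - hits$p_start,
                        hits$t_start + hits$p_start)
    merged <- do.call(rbind, lapply(
      split(hits, list(hits$strand, hits$diag), drop = TRUE),
      function(h) {
        h <- h[order(h$t_start), , drop = FALSE]
        run <- cumsum(c(1L, diff(h$t_start) != 1L))
        do.call(rbind, lapply(split(h, run), function(r) {
          data.frame(transcript_id = transcripts$id[i],
                     probe = probe$name,
                     strand = r$strand[1],
                     t_start = min(r$t_start),
                     t_end = max(r$t_start) + w,
                     p_start = min(r$p_start),
                     p_end = max(r$p_start) + w,
                     match_len = max(r$t_start) - min(r$t_start) + w,
                     stringsAsFactors = FALSE)
        }))
      }))
    merged <- merged[order(merged$t_start, merged$strand), , drop = FALSE]
    rows[[length(rows) + 1L]] <- merged
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), probe = character(),
               strand = character(), t_start = integer(), t_end = integer(),
               p_start = integer(), p_end = integer(), match_len = integer(),
               stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, pass = pass, word_length = w)
}
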