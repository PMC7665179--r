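#' Anchor a read to a transcript
#'
#' Ungapped seed-and-extend anchoring: the read (both orientations) is
#' seeded on the transcript by exact shared k-mers and each candidate
#' diagonal is scored by its matching bases. The single best anchoring is
#' returned, ties going to the leftmost transcript position and then to the
#' plus strand — deterministic behaviour matters because satellite monomers
#' make multi-anchoring routine.
#'
#' @param read,transcript one-row record data frames or plain strings.
#' @param k seed k-mer length (read must be at least `k` long).
#' @return `NULL` when no shared k-mer exists, else a list with `position`
#'   (0-based transcript offset of the first read base, possibly negative),
#'   `strand` (`"plus"`/`"minus"`), `matches`, `left_overhang` and
#'   `right_overhang` (read bases extending past the transcript ends, in
#'   transcript orientation).
#' @export
anchor_read <- function(read, transcript, k = 15L) {
  rseq <- if (is.data.frame(read)) read$seq[1] else normalize_seq(read)
  tseq <- if (is.data.frame(transcript)) transcript$seq[1] else
    normalize_seq(transcript)
  if (nchar(rseq) < k) stop("read shorter than k")
  a <- anchor_reads_cpp(tseq, rseq, k)
  if (!a$anchored[1]) return(NULL)
  oriented <- if (a$strand[1] < 0) revcomp(rseq) else rseq
  o <- a$offset[1]
  rl <- nchar(oriented); tl <- nchar(tseq)
  list(position = o,
       strand = if (a$strand[1] < 0) "minus" else "plus",
       matches = a$matches[1],
       left_overhang = if (o < 0) substr(oriented, 1L, -o) else "",
       right_overhang = if (o + rl > tl)
         substr(oriented, tl - o + 1L, rl) else "")
}

#' Verify polyadenylation of a transcript
#'
#' Assembly and trimming strip polyA tails, so tails must be recovered from
#' the untrimmed reads: reads are re-anchored to the candidate transcript
#' and a read supports polyadenylation when its overhang past a transcript
#' end is a sufficiently long, sufficiently pure adenine run — an A-run past
#' the 3' end, or (the molecule may be represented by its reverse
#' complement) a T-run past the 5' end. Internal A-runs never count; only
#' overhangs do. This is the pipeline's guard against genomic-DNA
#' contamination.
#'
#' @param transcript one-row record data frame or string.
#' @param reads record data frame of untrimmed reads.
#' @param min_reads supporting reads required for a positive verdict
#'   (default 2, so a single chimeric read cannot confer polyA status).
#' @param min_tail minimum overhang tail length in bp.
#' @param tail_purity minimum A (resp. T) fraction of the overhang.
#' @param k anchoring seed length.
#' @return list with `transcript_id`, `n_support_reads`, `max_tail_len`,
#'   `verdict`.
#' @export
verify_polya <- function(transcript, reads, min_reads = 2L, min_tail = 10L,
                         tail_purity = 0.9, k = 15L) {
  tseq <- if (is.data.frame(transcript)) transcript$seq[1] else
    normalize_seq(transcript)
  tid <- if (is.data.frame(transcript)) transcript$id[1] else "transcript"
  keep <- nchar(reads$seq) >= k
  a <- anchor_reads_cpp(tseq, reads$seq[keep], k)
  tl <- nchar(tseq)
  n_support <- 0L
  max_tail <- 0L
  base_frac <- function(s, b) {
    if (!nzchar(s)) return(0)
    lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))) / nchar(s)
  }
  seqs <- reads$seq[keep]
  for (i in which(a$anchored)) {
    oriented <- if (a$strand[i] < 0) revcomp(seqs[i]) else seqs[i]
    o <- a$offset[i]
    rl <- nchar(oriented)
    right <- if (o + rl > tl) substr(oriented, tl - o + 1L, rl) else ""
    left <- if (o < 0) substr(oriented, 1L, -o) else ""
    tail_len <- 0L
    if (nchar(right) >= min_tail && base_frac(right, "A") >= tail_purity)
      tail_len <- nchar(right)
    if (nchar(left) >= min_tail && base_frac(left, "T") >= tail_purity)
      tail_len <- max(tail_len, nchar(left))
    if (tail_len > 0L) {
      n_support <- n_support + 1L
      max_tail <- max(max_tail, tail_len)
    }
  }
  list(transcript_id = tid, n_support_reads = n_support,
       max_tail_len = max_tail,
       verdict = n_support >= min_reads)
}

#' Verify polyadenylation for a set of transcripts
#'
#' Convenience wrapper applying [verify_polya()] to every transcript.
#'
#' @param transcripts record data frame.
#' @param reads untrimmed read records.
#' @param ... passed to [verify_polya()].
#' @return data frame with one row per transcript.
#' @export
verify_polya_all <- function(transcripts, reads, ...) {
  do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i) {
    as.data.frame(verify_polya(transcripts[i, , drop = FALSE], reads, ...),
                  stringsAsFactors = FALSE)
  }))
}
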