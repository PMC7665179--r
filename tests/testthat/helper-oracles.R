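# Independent oracles used across the suite. They deliberately avoid the
# package's own data structures and algorithms.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Brute-force global alignment: top-down recursion maximizing the tuple
# (score, matches, -columns) lexicographically; identity = matches/columns.
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  tuple_max <- function(xs) {
    best <- xs[[1]]
    for (x in xs[-1]) {
      if (x[1] > best[1] ||
          (x[1] == best[1] && (x[2] > best[2] ||
                               (x[2] == best[2] && x[3] > best[3]))))
        best <- x
    }
    best
  }
  rec <- function(i, j) {
    key <- paste0(i, "_", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    r <- if (i > length(A) && j > length(B)) c(0, 0, 0) else {
      cand <- list()
      if (i <= length(A) && j <= length(B)) {
        m <- A[i] == B[j]
        cand <- c(cand, list(rec(i + 1, j + 1) +
                               c(if (m) 1 else -1, if (m) 1 else 0, -1)))
      }
      if (i <= length(A)) cand <- c(cand, list(rec(i + 1, j) + c(-1, 0, -1)))
      if (j <= length(B)) cand <- c(cand, list(rec(i, j + 1) + c(-1, 0, -1)))
      tuple_max(cand)
    }
    memo[[key]] <- r
    r
  }
  v <- rec(1, 1)
  v[2] / (-v[3])
}

# Quadratic motif scan (overlapping occurrences, one strand).
oracle_motif_count <- function(seq, motif) {
  n <- nchar(seq); w <- nchar(motif)
  if (n < w) return(0L)
  sum(vapply(1:(n - w + 1),
             function(i) substr(seq, i, i + w - 1) == motif, logical(1)))
}

# Naive half-probe screen: scan every transcript position against every
# probe window of length w, on both strands.
oracle_screen <- function(tseq, probe_seq, w) {
  L <- nchar(probe_seq)
  rc <- rc_oracle(probe_seq)
  for (j in 1:(L - w + 1)) {
    if (grepl(substr(probe_seq, j, j + w - 1), tseq, fixed = TRUE)) return(TRUE)
    if (grepl(substr(rc, j, j + w - 1), tseq, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# Reference Ct tables built from the published group means and SDs
# (triplicates symmetric around the mean reproduce both exactly).
ct_fixture <- function() {
  tri <- function(mean, sd) mean + c(-1, 0, 1) * sd
  rows <- function(sample, group, gene, ct)
    data.frame(sample_id = sample, group = group, gene = gene, ct = ct)
  rbind(
    rows("oo1", "oocyte", "GAPDH", tri(36.7, 0.75)),
    rows("cu1", "cumulus", "GAPDH", tri(27.2, 0.4)),
    rows("oo1", "oocyte", "ACTB", tri(28.2, 0.3)),
    rows("cu1", "cumulus", "ACTB", tri(26.5, 1.1)))
}
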