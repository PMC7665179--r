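#' Count motif occurrences
#'
#' Overlapping occurrences of a motif in a sequence and, when
#' `both_strands`, of its reverse complement (a palindromic motif is
#' counted once). Overlap counting is the simplest well-defined convention
#' for tandem repeats.
#'
#' @param seq nucleotide string.
#' @param motif motif of length >= 2.
#' @param both_strands also count the reverse complement.
#' @return integer count.
#' @export
count_motif <- function(seq, motif, both_strands = TRUE) {
  if (nchar(motif) < 2) stop("motif must be at least 2 bases")
  seq <- normalize_seq(seq)
  motif <- normalize_seq(motif)
  n <- length(find_all(seq, motif))
  if (both_strands) {
    rc <- revcomp(motif)
    if (rc != motif) n <- n + length(find_all(seq, rc))
  }
  n
}

#' Call the transcribed strand of a satellite sequence
#'
#' HS2/HS3 can be transcribed from either chain; the given strand of a
#' sequence is called `"ATTCC"` when same-strand ATTCC pentamers outnumber
#' GGAAT pentamers by at least `margin`-fold (and symmetrically for
#' `"GGAAT"`), else `"ambiguous"`. Reverse-complementing a sequence swaps
#' the call, because the complement of ATTCC is GGAAT.
#'
#' @param seq nucleotide string of length >= 25.
#' @param margin fold-excess required for a call.
#' @return `"ATTCC"`, `"GGAAT"` or `"ambiguous"`.
#' @export
strand_call <- function(seq, margin = 2.0) {
  if (nchar(seq) < 25) stop("strand_call: sequence shorter than 25 bases")
  a <- count_motif(seq, "ATTCC", both_strands = FALSE)
  g <- count_motif(seq, "GGAAT", both_strands = FALSE)
  if (a == 0 && g == 0) return("ambiguous")
  if (a >= margin * g && a > g) return("ATTCC")
  if (g >= margin * a && g > a) return("GGAAT")
  "ambiguous"
}

# positions (0-based) covered by ATTCC/GGAAT pentamer hits with <= 1 mismatch
pentamer_coverage <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cov <- logical(n)
  if (n < 5) return(cov)
  starts <- seq_len(n - 4L)
  for (pat in c("ATTCC", "GGAAT")) {
    p <- strsplit(pat, "")[[1]]
    mism <- integer(length(starts))
    for (o in 0:4) mism <- mism + (ch[starts + o] != p[o + 1L])
    hit <- starts[mism <= 1L]
    for (o in 0:4) cov[hit + o] <- TRUE
  }
  cov
}

#' Segment a sequence into satellite blocks
#'
#' Sliding-window density segmentation standing in for repeat-library
#' masking: every base covered by an ATTCC or GGAAT pentamer hit (allowing
#' one mismatch per pentamer) counts as satellite; windows whose covered
#' fraction reaches `density_floor` are merged into maximal runs, and runs
#' shorter than `min_block` are dropped. Coordinates are 0-based half-open.
#'
#' @param seq nucleotide string of length >= `window`.
#' @param window window size in bp.
#' @param density_floor minimum covered fraction for a window to qualify.
#' @param min_block minimum reported block length in bp.
#' @return data frame with `start`, `end`, `density` (covered fraction of
#'   the block), possibly empty; blocks are sorted and non-overlapping.
#' @export
segment_blocks <- function(seq, window = 50L, density_floor = 0.5,
                           min_block = 100L) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < window) stop("segment_blocks: sequence shorter than window")
  cov <- pentamer_coverage(seq)
  cs <- cumsum(c(0L, cov))
  starts <- seq_len(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  ok <- frac >= density_floor
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0),
                                  density = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  blocks <- do.call(rbind, lapply(which(r$values), function(k) {
    s <- begs[k] - 1L               # 0-based block start
    e <- ends[k] - 1L + window      # 0-based half-open end
    data.frame(start = s, end = e,
               density = (cs[e + 1L] - cs[s + 1L]) / (e - s))
  }))
  blocks <- blocks[blocks$end - blocks$start >= min_block, , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' In-silico PCR
#'
#' Exact-match PCR product prediction: every occurrence of the forward
#' primer on the given strand is paired with every downstream occurrence of
#' the reverse complement of the reverse primer, products longer than
#' `max_product` being discarded. The product begins with the forward
#' primer and ends with the reverse complement of the reverse primer.
#'
#' @param seq template nucleotide string.
#' @param fwd,rev primer sequences (>= 15 bp).
#' @param max_product maximum reported product length in bp.
#' @param seq_id template id stored in the result.
#' @return data frame with `seq_id`, `fwd_start`, `rev_end` (0-based
#'   half-open), `length`, `product`, sorted by start; possibly empty.
#' @export
in_silico_pcr <- function(seq, fwd, rev, max_product = 2000L,
                          seq_id = "template") {
  if (nchar(fwd) < 15 || nchar(rev) < 15) stop("primers must be >= 15 bp")
  seq <- normalize_seq(seq)
  fwd <- normalize_seq(fwd); rev <- normalize_seq(rev)
  f_pos <- find_all(seq, fwd) - 1L
  r_rc <- revcomp(rev)
  r_pos <- find_all(seq, r_rc) - 1L
  out <- data.frame(seq_id = character(0), fwd_start = integer(0),
                    rev_end = integer(0), length = integer(0),
                    product = character(0), stringsAsFactors = FALSE)
  for (f in f_pos) {
    for (rp in r_pos) {
      e <- rp + nchar(r_rc)
      if (rp < f + nchar(fwd)) next           # reverse site must be downstream
      if (e - f > max_product) next
      out <- rbind(out, data.frame(
        seq_id = seq_id, fwd_start = f, rev_end = e, length = e - f,
        product = substr(seq, f + 1L, e), stringsAsFactors = FALSE))
    }
  }
  out[order(out$fwd_start, out$rev_end), , drop = FALSE]
}

#' Repeat annotation of sequences
#'
#' Per-sequence motif profile: ATTCC and GGAAT pentamer counts on the given
#' strand, HS3 decanucleotide (CAACCCGAGT) and GATGAT hexamer counts on
#' either strand, the strand call and the satellite block segmentation.
#' Family labels are limited to "HS2/HS3-like"; finer subfamily calls would
#' need a curated repeat library.
#'
#' @param records record data frame.
#' @param margin passed to [strand_call()].
#' @param ... passed to [segment_blocks()].
#' @return list with `annotations` (one row per sequence: seq_id,
#'   attcc_count, ggaat_count, decanucleotide_count, gatgat_count,
#'   strand_call, n_blocks, block_bp) and `blocks` (seq_id, start, end,
#'   density, name).
#' @export
annotate_repeats <- function(records, margin = 2.0, ...) {
  ann <- NULL; blk <- NULL
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    b <- segment_blocks(s, ...)
    ann <- rbind(ann, data.frame(
      seq_id = records$id[i],
      attcc_count = count_motif(s, "ATTCC", both_strands = FALSE),
      ggaat_count = count_motif(s, "GGAAT", both_strands = FALSE),
      decanucleotide_count = count_motif(s, "CAACCCGAGT"),
      gatgat_count = count_motif(s, "GATGAT"),
      strand_call = if (nchar(s) >= 25) strand_call(s, margin) else "ambiguous",
      n_blocks = nrow(b), block_bp = sum(b$end - b$start),
      stringsAsFactors = FALSE))
    if (nrow(b))
      blk <- rbind(blk, cbind(data.frame(seq_id = records$id[i]), b,
                              data.frame(name = "HS2/HS3-like")))
  }
  list(annotations = ann,
       blocks = blk %||% data.frame(seq_id = character(0), start = integer(0),
                                    end = integer(0), density = numeric(0),
                                    name = character(0)))
}

#' Write satellite blocks as BED
#'
#' 0-based half-open BED with the family label as name and the block
#' density (scaled to 0-1000) as score.
#'
#' @param blocks `blocks` data frame from [annotate_repeats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$seq_id, start = blocks$start,
                    end = blocks$end, name = blocks$name,
                    score = round(1000 * blocks$density))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
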