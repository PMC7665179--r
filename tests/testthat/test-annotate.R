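test_that("count_motif counts overlapping hits and both strands", {
  expect_equal(count_motif(dyz1_probe()$seq, "ATTCC", both_strands = FALSE), 9L)
  expect_equal(count_motif("AAAA", "AA", both_strands = FALSE), 3L)
  # palindrome-safe: revcomp(AT) == AT must not double count
  expect_equal(count_motif("ATAT", "AT"), 2L)
  expect_error(count_motif("ACGT", "A"), "at least 2")
})

test_that("count_motif equals a naive quadratic scan on random instances", {
  set.seed(71)
  for (i in 1:30) {
    s <- rand_seq(sample(50:200, 1))
    m <- rand_seq(sample(2:6, 1))
    expect_equal(count_motif(s, m, both_strands = FALSE),
                 oracle_motif_count(s, m), info = paste(s, m))
    expect_equal(count_motif(s, m, both_strands = TRUE),
                 oracle_motif_count(s, m) +
                   if (rc_oracle(m) == m) 0L else oracle_motif_count(s, rc_oracle(m)),
                 info = paste(s, m))
  }
})

test_that("GATGAT occurs in exactly one published transcript", {
  t1 <- published_transcripts()
  counts <- vapply(t1$seq, count_motif, integer(1), motif = "GATGAT")
  expect_equal(unname(counts > 0),
               t1$id == "SRR6350575")
})

test_that("strand calls match the probes' declared repeats and swap under rc", {
  expect_equal(strand_call(dyz1_probe()$seq), "ATTCC")
  expect_equal(strand_call(pct14_probe()$seq), "GGAAT")
  expect_equal(strand_call(revcomp(dyz1_probe()$seq)), "GGAAT")
  expect_equal(strand_call(revcomp(pct14_probe()$seq)), "ATTCC")
  set.seed(72)
  expect_equal(strand_call(rand_seq(60)), "ambiguous")
  expect_error(strand_call("ACGTACGT"), "shorter")
})

test_that("segment_blocks finds planted satellite blocks and nothing else", {
  pure <- strrep("ATTCC", 100)
  b <- segment_blocks(pure)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 0L)
  expect_equal(b$end, nchar(pure))

  set.seed(73)
  b0 <- segment_blocks(rand_seq(1000))
  expect_equal(nrow(b0), 0L)

  chimera <- paste0(strrep("ATTCC", 40), rand_seq(300), strrep("GGAAT", 40))
  bc <- segment_blocks(chimera)
  expect_equal(nrow(bc), 2L)
  expect_lte(abs(bc$start[1] - 0), 50)
  expect_lte(abs(bc$end[1] - 200), 50)
  expect_lte(abs(bc$start[2] - 500), 50)
  expect_lte(abs(bc$end[2] - 700), 50)
  expect_error(segment_blocks("ATTCC"), "shorter than window")
})

test_that("in_silico_pcr amplifies the published transcript exactly once", {
  t1 <- published_transcripts()
  p <- qpcr_primers()
  amps <- in_silico_pcr(t1$seq[t1$id == "SRR6350575"], p$hs_fwd, p$hs_rev,
                        seq_id = "SRR6350575")
  expect_equal(nrow(amps), 1L)
  expect_true(startsWith(amps$product, p$hs_fwd))
  expect_true(endsWith(amps$product, revcomp(p$hs_rev)))
  # brute-force oracle for the product span
  s <- t1$seq[t1$id == "SRR6350575"]
  f <- regexpr(p$hs_fwd, s, fixed = TRUE)
  r <- regexpr(revcomp(p$hs_rev), s, fixed = TRUE)
  expect_equal(amps$length,
               as.integer(r) + attr(r, "match.length") - as.integer(f))

  for (id in setdiff(t1$id, "SRR6350575"))
    expect_equal(nrow(in_silico_pcr(t1$seq[t1$id == id], p$hs_fwd, p$hs_rev)),
                 0L)
})

test_that("pcr returns nothing without a downstream reverse site", {
  p <- qpcr_primers()
  template <- paste0("GCGC", p$hs_fwd, strrep("AT", 40))
  expect_equal(nrow(in_silico_pcr(template, p$hs_fwd, p$hs_rev)), 0L)
  expect_error(in_silico_pcr("ACGT", "ACGTACGT", "ACGTACGT"), ">= 15")
})

test_that("annotate_repeats summarizes motifs, strand and blocks per record", {
  cfg <- sim_config(seed = 74, family = "HS3_GATGAT", unit_divergence = 0.02)
  set.seed(74)
  arr <- make_array(cfg, 500, "gat")
  set.seed(75)
  recs <- rbind(arr, seq_records("noise", rand_seq(400)))
  ann <- annotate_repeats(recs)
  a <- ann$annotations
  expect_equal(a$seq_id, c("gat", "noise"))
  expect_gt(a$gatgat_count[1], 0)
  expect_gt(a$decanucleotide_count[1], 0)
  expect_equal(a$strand_call[1], "ATTCC")
  expect_gt(a$n_blocks[1], 0)
  expect_equal(a$n_blocks[2], 0)
  # BED export is 0-based half-open with the family label
  bed <- tempfile(fileext = ".bed")
  write_blocks_bed(ann$blocks, bed)
  lines <- read.delim(bed, header = FALSE)
  expect_equal(nrow(lines), nrow(ann$blocks))
  expect_true(all(lines$V4 == "HS2/HS3-like"))
})
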