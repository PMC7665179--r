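test_that("HS3like arrays are pentamer-dense with periodic decanucleotides", {
  cfg <- sim_config(seed = 3, family = "HS3like", unit_divergence = 0)
  set.seed(3)
  arr <- make_array(cfg, 500)
  expect_equal(nchar(arr$seq), 500L)
  n_deca <- count_motif(arr$seq, "CAACCCGAGT", both_strands = FALSE)
  expect_gte(count_motif(arr$seq, "ATTCC", both_strands = FALSE),
             floor((500 - 10 * n_deca) / 5))
  expect_gt(n_deca, 0)
})

test_that("HS3_GATGAT arrays contain the hexamer; HS2like arrays build", {
  cfg <- sim_config(seed = 4, family = "HS3_GATGAT")
  set.seed(4)
  arr <- make_array(cfg, 400)
  expect_gte(count_motif(arr$seq, "GATGAT", both_strands = FALSE), 1L)
  cfg2 <- sim_config(seed = 4, family = "HS2like")
  set.seed(4)
  arr2 <- make_array(cfg2, 400)
  expect_equal(nchar(arr2$seq), 400L)
  expect_error(make_array(cfg, 30), ">= 50")
})

test_that("array generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9)
  set.seed(9); a1 <- make_array(cfg, 350)
  set.seed(9); a2 <- make_array(cfg, 350)
  expect_identical(a1, a2)
})

test_that("make_transcript appends the tail and honours strand", {
  arr <- seq_records("x", "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC")
  expect_equal(make_transcript(arr, 0, "plus")$seq, arr$seq)
  minus <- make_transcript(arr, 20, "minus")
  expect_true(startsWith(minus$seq, strrep("T", 20)))
  expect_equal(nchar(make_transcript(arr, 33, "plus")$seq), nchar(arr$seq) + 33)
  expect_equal(make_transcript(arr, 20, "minus")$seq,
               revcomp(make_transcript(arr, 20, "plus")$seq))
})

test_that("error-free reads are exact substrings of a strand of the source", {
  cfg <- sim_config(seed = 6, read_error_rate = 0, n_reads = 200,
                    background_fraction = 0)
  set.seed(6)
  arr <- make_array(cfg, 400)
  tx <- make_transcript(arr, 30, "plus")
  rd <- simulate_reads(tx, data.frame(target_id = "array", true_tpm = 1e6), cfg)
  both <- paste(tx$seq, revcomp(tx$seq), sep = "NNN")
  expect_true(all(vapply(rd$seq, grepl, logical(1), x = both, fixed = TRUE)))
})

test_that("strand flips and abundance ratios follow the sampling model", {
  cfg <- sim_config(seed = 8, read_error_rate = 0, n_reads = 10000,
                    background_fraction = 0, strand_flip_prob = 0.5)
  set.seed(8)
  a <- make_array(cfg, 400, "t1")
  b <- make_array(cfg, 400, "t2")
  tx <- rbind(make_transcript(a, 0, "plus"), make_transcript(b, 0, "plus"))
  truth <- data.frame(target_id = c("t1", "t2"), true_tpm = c(9e5, 1e5))
  rd <- simulate_reads(tx, truth, cfg)
  flips <- grepl("\\|-\\|", rd$id)
  expect_lt(abs(mean(flips) - 0.5), 3 * sqrt(0.25 / 10000))
  n1 <- sum(grepl("\\|t1\\|", rd$id))
  expect_lt(abs(n1 / 10000 - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
})

test_that("truth tables normalize to one million TPM exactly", {
  cfg <- sim_config(seed = 12)
  sim <- simulate_transcriptome(cfg, n_satellite = 3, n_decoys = 2)
  expect_equal(sum(sim$truth$true_tpm), 1e6)
  expect_equal(nrow(sim$molecules), 3 + 2 + 1) # satellites + decoys + control
})

test_that("donor panels encode the designed increases and are reproducible", {
  cfg <- sim_config(seed = 5, n_reads = 300L)
  p1 <- make_donor_panel(n_donors = 4, ratios = c(2, 0.5, 1.5, 1),
                         config = cfg, n_satellite = 2, n_decoys = 1)
  expect_equal(sum(p1$donors$increase), 2L)
  expect_equal(p1$donors$expected_pct_mii[4], 100)
  expect_equal(nrow(p1$manifest), 8L)
  p2 <- make_donor_panel(n_donors = 4, ratios = c(2, 0.5, 1.5, 1),
                         config = cfg, n_satellite = 2, n_decoys = 1)
  expect_identical(p1$samples, p2$samples)
  # per-sample truth still normalizes
  for (tt in p1$truth) expect_equal(sum(tt$true_tpm), 1e6)
})

test_that("generated HS3like arrays satisfy the annotator's density floor", {
  cfg <- sim_config(seed = 21, family = "HS3like")
  set.seed(21)
  for (i in 1:5) {
    arr <- make_array(cfg, sample(300:640, 1))
    blocks <- segment_blocks(arr$seq)
    expect_gt(nrow(blocks), 0)
    expect_true(all(blocks$density >= 0.5))
  }
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(read_error_rate = 1.5), "probabilities")
  expect_error(sim_config(transcript_length_range = c(500, 300)), "min > max")
})
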