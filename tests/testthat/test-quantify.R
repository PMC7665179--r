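test_that("pseudoalignment produces the expected equivalence classes", {
  set.seed(61)
  shared <- rand_seq(120)
  t1 <- paste0(rand_seq(150), shared)
  t2 <- paste0(shared, rand_seq(150))
  targets <- seq_records(c("t1", "t2"), c(t1, t2))
  reads <- seq_records(
    c("unique1", "shared12", "stray"),
    c(substr(t1, 10, 109),      # unique to t1
      substr(shared, 5, 104),   # verbatim in both
      rand_seq(100)))
  pa <- pseudoalign(reads, targets)
  cls <- lapply(pa$read_class, function(ci)
    if (ci == 0) integer(0) else sort(pa$classes[[ci]]))
  expect_equal(cls[[1]], 1L)
  expect_equal(cls[[2]], c(1L, 2L))
  expect_equal(cls[[3]], integer(0))
  expect_equal(pa$n_unassigned, 1L)
})

test_that("pseudoalignment is strand agnostic", {
  set.seed(62)
  t1 <- rand_seq(300)
  targets <- seq_records("t1", t1)
  rd <- substr(t1, 50, 149)
  pa <- pseudoalign(seq_records(c("f", "r"), c(rd, revcomp(rd))), targets)
  expect_equal(pa$n_unassigned, 0L)
  expect_equal(pa$counts, 2L)
})

test_that("EM with singleton classes returns the raw counts", {
  est <- em_abundance(list(1L, 2L, 3L), c(30L, 10L, 5L), c(500, 500, 300))
  expect_equal(est$est_counts, c(30, 10, 5))
})

test_that("a fully shared class splits evenly between equal-length targets", {
  est <- em_abundance(list(c(1L, 2L)), 100L, c(400, 400))
  expect_equal(est$est_counts, c(50, 50))
})

test_that("EM conserves counts at the fixed point and along iterations", {
  set.seed(63)
  classes <- list(1L, 2L, c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L))
  counts <- c(40L, 25L, 30L, 20L, 15L)
  est <- em_abundance(classes, counts, c(600, 400, 350))
  expect_equal(sum(est$est_counts), sum(counts))
  expect_warning(
    one_iter <- em_abundance(classes, counts, c(600, 400, 350), max_iter = 1L),
    "did not converge")
  expect_equal(sum(one_iter$est_counts), sum(counts))
})

test_that("tpm follows its closed form", {
  expect_equal(tpm(10, 100), 1e6)
  # equal counts, lengths L and 2L: TPM ratio 2:1
  v <- tpm(c(20, 20), c(100, 200))
  expect_equal(v[1] / v[2], 2)
  expect_equal(sum(v), 1e6)
  expect_equal(tpm(c(0, 0), c(100, 200)), c(0, 0))
  # two equal-length targets with unique counts 30 and 10
  expect_equal(tpm(c(30, 10), c(480, 480)), c(750000, 250000))
})

test_that("total_reference_tpm sums the named targets and checks presence", {
  tab <- data.frame(target_id = c("X60726.1", "S90110.1", "X82942.1"),
                    tpm = c(10, 5, 0))
  expect_equal(total_reference_tpm(tab, tab$target_id), 15)
  expect_equal(total_reference_tpm(tab, character(0)), 0)
  expect_error(total_reference_tpm(tab, c("missing1", "missing2")),
               "missing1")
})

test_that("compare_donors arithmetic and pairing rules hold", {
  mk <- function(sat, ctl) data.frame(target_id = c("sat", "ACTB"),
                                      tpm = c(sat, ctl))
  tables <- list(gv1 = mk(4, 50), mii1 = mk(6, 50),
                 gv2 = mk(5, 50), mii2 = mk(5, 50))
  manifest <- data.frame(donor_id = c("d1", "d1", "d2", "d2"),
                         stage = c("GV", "MII", "GV", "MII"),
                         sample_id = c("gv1", "mii1", "gv2", "mii2"))
  cmp <- compare_donors(tables, manifest, "sat", "ACTB")
  expect_equal(cmp$donors$pct_mii, c(150, 100))
  expect_equal(cmp$donors$increase, c(TRUE, FALSE))
  expect_equal(cmp$n_increase, 1L)
  expect_equal(cmp$control$cv, 0)

  bad <- manifest[-2, ]
  expect_error(compare_donors(tables, bad, "sat", "ACTB"), "exactly one")
})

test_that("the negative control is flagged only above its floor", {
  mk <- function(neg) data.frame(target_id = c("sat", "ACTB", "HBA1"),
                                 tpm = c(10, 50, neg))
  manifest <- data.frame(donor_id = "d1", stage = c("GV", "MII"),
                         sample_id = c("a", "b"))
  quiet <- compare_donors(list(a = mk(0.1), b = mk(0.2)), manifest,
                          "sat", "ACTB", negative_control_id = "HBA1")
  expect_false(quiet$negative_flagged)
  loud <- compare_donors(list(a = mk(8), b = mk(0.2)), manifest,
                         "sat", "ACTB", negative_control_id = "HBA1")
  expect_true(loud$negative_flagged)
})

test_that("EM equals the unique-assignment estimator on singleton classes", {
  set.seed(64)
  cfg <- sim_config(seed = 64, read_error_rate = 0, n_reads = 5000,
                    background_fraction = 0, strand_flip_prob = 0.5)
  # two unrelated random targets: every assigned read is target specific
  targets <- seq_records(c("u1", "u2"), c(rand_seq(500), rand_seq(700)))
  truth <- data.frame(target_id = c("u1", "u2"), true_tpm = c(7e5, 3e5))
  set.seed(64)
  reads <- simulate_reads(targets, truth, cfg)
  pa <- pseudoalign(reads, targets)
  expect_true(all(lengths(pa$classes) == 1L))
  tab <- quantify_sample(targets, reads)
  per_target <- tapply(pa$counts, unlist(pa$classes), sum)
  expect_equal(tab$est_counts, as.numeric(per_target[as.character(1:2)]))
})
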