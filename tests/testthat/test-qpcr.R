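# per-sample target Ct jitter is symmetric around zero, so group means (and
# hence ddCt and fold) stay exact while per-sample dCt values vary
flat_ct <- function(oo_target, cu_target, oo_ref = 28, cu_ref = 28,
                    n_samples = 3) {
  jit <- 0.1 * (seq_len(n_samples) - (n_samples + 1) / 2)
  rows <- list()
  for (i in seq_len(n_samples)) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = c(sprintf("oo%d", i), sprintf("oo%d", i),
                    sprintf("cu%d", i), sprintf("cu%d", i)),
      group = c("oocyte", "oocyte", "cumulus", "cumulus"),
      gene = c("HS", "REF", "HS", "REF"),
      ct = c(oo_target + jit[i], oo_ref, cu_target + 2 * jit[i], cu_ref))
  }
  do.call(rbind, rows)
}

test_that("ddCt identities: equal dCt gives fold 1; -3 cycles give fold 8", {
  ct <- flat_ct(oo_target = 30, cu_target = 30)
  r <- delta_delta_ct(ct, "HS", "REF", "oocyte", "cumulus")
  expect_equal(r$fold, 1.0)
  expect_equal(r$ddct, 0)

  ct3 <- flat_ct(oo_target = 27, cu_target = 30)
  r3 <- delta_delta_ct(ct3, "HS", "REF", "oocyte", "cumulus")
  expect_equal(r3$fold, 8.0)
})

test_that("published reference Cts with equal target Cts give fold 2^1.7", {
  # beta-actin: 28.2 in oocytes vs 26.5 in cumulus; hypothetical equal
  # target Cts in both groups
  ct <- flat_ct(oo_target = 30, cu_target = 30, oo_ref = 28.2, cu_ref = 26.5)
  r <- delta_delta_ct(ct, "HS", "REF", "oocyte", "cumulus")
  expect_equal(r$fold, 2^(28.2 - 26.5), tolerance = 1e-10)
  expect_equal(round(r$fold, 2), 3.25)
})

test_that("fold reciprocity and monotonicity hold", {
  ct <- flat_ct(oo_target = 26.4, cu_target = 31.9, oo_ref = 27.3,
                cu_ref = 28.8)
  fwd <- delta_delta_ct(ct, "HS", "REF", "oocyte", "cumulus")
  bwd <- delta_delta_ct(ct, "HS", "REF", "cumulus", "oocyte")
  expect_equal(fwd$fold * bwd$fold, 1.0)
  lower <- flat_ct(oo_target = 25.4, cu_target = 31.9, oo_ref = 27.3,
                   cu_ref = 28.8)
  expect_gt(delta_delta_ct(lower, "HS", "REF", "oocyte", "cumulus")$fold,
            fwd$fold)
})

test_that("the two-group test uses per-sample dCt units", {
  ct <- flat_ct(oo_target = 27, cu_target = 30, n_samples = 3)
  r <- delta_delta_ct(ct, "HS", "REF", "oocyte", "cumulus")
  expect_false(is.na(r$p_value))
  expect_equal(r$group_stats$n_samples, c(3L, 3L))
  one <- flat_ct(oo_target = 27, cu_target = 30, n_samples = 1)
  expect_true(is.na(delta_delta_ct(one, "HS", "REF", "oocyte",
                                   "cumulus")$p_value))
  expect_error(delta_delta_ct(ct, "HS", "GAPDH", "oocyte", "cumulus"),
               "missing")
})

test_that("reference stability flags the published GAPdH shift", {
  ct <- ct_fixture()
  gapdh <- reference_stability(ct, "GAPDH")
  expect_false(gapdh$stable)
  expect_equal(gapdh$delta, 36.7 - 27.2)
  actb <- reference_stability(ct, "ACTB")
  expect_true(actb$stable)
  expect_equal(actb$delta, 28.2 - 26.5, tolerance = 1e-10)
  # the fixture reproduces the published group means and SDs
  gs <- gapdh$group_stats
  expect_equal(sort(gs$mean), c(27.2, 36.7))
  expect_equal(sort(gs$sd), c(0.4, 0.75))
})

test_that("identical groups are trivially stable; Ct tables are validated", {
  ct <- flat_ct(oo_target = 30, cu_target = 30)
  r <- reference_stability(ct, "REF")
  expect_true(r$stable)
  expect_equal(r$delta, 0)
  bad <- data.frame(sample_id = "s", group = "g", gene = "x", ct = -1)
  expect_error(reference_stability(bad, "x"), "positive")
  fp <- tempfile(fileext = ".tsv")
  write.table(ct, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_ct_table(fp)), nrow(ct))
})
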