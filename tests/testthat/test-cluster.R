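diverge <- function(seq, rate) satseeker:::mutate_seq(seq, rate)

test_that("identical sequences form one cluster; distinct ones stay apart", {
  recs <- seq_records(sprintf("s%d", 1:5), rep(strrep("ATTCC", 20), 5))
  cl <- greedy_cluster(recs)
  expect_equal(nrow(cl$centroids), 1L)
  expect_equal(nrow(cl$members), 5L)

  set.seed(51)
  distinct <- seq_records(c("a", "b", "c"),
                          c(rand_seq(100), rand_seq(100), rand_seq(100)))
  expect_equal(nrow(greedy_cluster(distinct, threshold = 1.0)$centroids), 3L)
  expect_error(greedy_cluster(distinct[0, ]), "no sequences")
})

test_that("two planted families separate at T = 0.9 and match the oracle", {
  set.seed(52)
  mA <- rand_seq(300); mB <- rand_seq(300)
  expect_lt(global_identity(mA, mB), 0.75) # families are far apart
  recs <- seq_records(
    c(sprintf("A%d", 1:4), sprintf("B%d", 1:4)),
    c(vapply(1:4, function(i) diverge(mA, 0.03), character(1)),
      vapply(1:4, function(i) diverge(mB, 0.03), character(1))))
  cl <- greedy_cluster(recs, threshold = 0.90)
  expect_equal(nrow(cl$centroids), 2L)
  # all-pairs identity oracle: members co-cluster iff identity >= T to the
  # cluster's centroid
  for (r in seq_len(nrow(cl$members))) {
    cid <- cl$members$cluster_id[r]
    cent <- cl$centroids$seq[cl$centroids$cluster_id == cid]
    expect_gte(global_identity(cl$members$seq[r], cent), 0.90)
  }
  grp <- substr(cl$members$member_id, 1, 1)
  expect_equal(length(unique(tapply(cl$members$cluster_id, grp, unique))), 2L)
})

test_that("clustering is invariant to input order", {
  set.seed(53)
  m <- rand_seq(200)
  recs <- seq_records(sprintf("s%d", 1:6),
                      vapply(1:6, function(i) diverge(m, 0.05), character(1)))
  cl1 <- greedy_cluster(recs)
  cl2 <- greedy_cluster(recs[sample(6), ])
  expect_equal(cl1$members[order(cl1$members$member_id), ],
               cl2$members[order(cl2$members$member_id), ],
               ignore_attr = TRUE)
})

test_that("reverse-complement members join in reverse orientation", {
  set.seed(54)
  m <- rand_seq(250)
  recs <- seq_records(c("fwd1", "fwd2", "rc1"),
                      c(m, diverge(m, 0.02), revcomp(diverge(m, 0.02))))
  cl <- greedy_cluster(recs)
  expect_equal(nrow(cl$centroids), 1L)
  expect_equal(cl$members$orientation[cl$members$member_id == "rc1"], "minus")
})

test_that("consensus of hand-built clusters matches column majorities", {
  recs <- seq_records(c("a", "b", "c"),
                      c("ATTCCATTCC", "ATTCCATTCC", "ATTCCATGCC"))
  cl <- greedy_cluster(recs, threshold = 0.7)
  expect_equal(nrow(cl$centroids), 1L)
  expect_equal(build_consensus(cl)$seq, "ATTCCATTCC")

  recs2 <- seq_records(c("a", "b", "c", "d"),
                       c("AAAA", "AAAA", "AATA", "AAA"))
  cl2 <- greedy_cluster(recs2, threshold = 0.7)
  expect_equal(build_consensus(cl2)$seq, "AAAA")

  single <- greedy_cluster(seq_records("only", "ACGTACGTACGT"))
  expect_equal(build_consensus(single)$seq, "ACGTACGTACGT")
})

test_that("consensus recovers a 3%-diverged master at >= 99% identity", {
  set.seed(55)
  cfg <- sim_config(seed = 55, unit_divergence = 0.02)
  master <- make_array(cfg, 400, "master")
  recs <- do.call(rbind, lapply(1:8, function(i)
    seq_records(sprintf("m%d", i), diverge(master$seq, 0.03))))
  cl <- greedy_cluster(recs, threshold = 0.90)
  expect_equal(nrow(cl$centroids), 1L)
  cons <- build_consensus(cl)
  expect_gte(global_identity(cons$seq, master$seq), 0.99)
})
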