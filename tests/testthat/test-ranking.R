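# Worst-case ranks, tied-rank clustering, PPV, rank summaries.

test_that("worst-case rank counts everything scoring at least the target", {
  expect_equal(worst_case_rank(c(rep(1, 10), rep(0.2, 5)), target = 1), 10)
  expect_equal(worst_case_rank(c(3, 2, 1), target = 1), 1)
  expect_equal(worst_case_rank(c(5, 4, 4, 3), target = 2), 3)
  expect_equal(worst_case_rank(c(5, 4, 4, 3), target = 3), 3)
  expect_equal(worst_case_rank(c(1, 2), target = "b", ids = c("a", "b")), 1)
  expect_error(worst_case_rank(c(1, 2), target = "z", ids = c("a", "b")),
               "not present")
})

test_that("tied groups cluster by similarity, never across scores", {
  # three stereoisomer-like identical fingerprints tied at the top
  fp_a <- c(TRUE, TRUE, FALSE, FALSE)
  fp_b <- c(FALSE, FALSE, TRUE, TRUE)
  scores <- c(1, 1, 1, 0.5, 0.5)
  fps <- list(fp_a, fp_a, fp_a, fp_b, fp_b)
  cl <- cluster_tied(scores, fps)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:5])), 1)
  expect_false(cl[1] == cl[4])  # equal fingerprints, different scores

  # all pairwise dissimilar: singletons
  fps2 <- list(c(TRUE, rep(FALSE, 3)), c(FALSE, TRUE, FALSE, FALSE),
               c(FALSE, FALSE, TRUE, FALSE))
  cl2 <- cluster_tied(c(1, 1, 1), fps2)
  expect_equal(length(unique(cl2)), 3)

  # threshold 1.0 with distinct fingerprints: singletons
  fps3 <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
               c(TRUE, TRUE, TRUE))
  cl3 <- cluster_tied(c(2, 2, 2), fps3, threshold = 1.0)
  expect_equal(length(unique(cl3)), 3)
})

test_that("clustering is invariant to order within a tied group", {
  set.seed(9)
  fps <- lapply(1:6, function(i) runif(32) > 0.5)
  scores <- c(1, 1, 1, 1, 0, 0)
  cl <- cluster_tied(scores, fps, threshold = 0.4)
  perm <- c(4, 2, 1, 3, 6, 5)
  cl_p <- cluster_tied(scores[perm], fps[perm], threshold = 0.4)
  # same partition: co-membership must agree under the permutation
  co <- function(cl) outer(cl, cl, "==")
  expect_equal(co(cl_p), co(cl)[perm, perm])
})

test_that("cluster rank reproduces the 8-tied-to-5-clusters pattern", {
  # tied block of 8 at the top (target inside) collapsing to 5 clusters
  scores <- c(rep(1, 8), 0.7, 0.4)
  clusters <- c(1, 1, 2, 2, 3, 4, 5, 5, 6, 7)
  expect_equal(worst_case_rank(scores, target = 8), 8)
  expect_equal(cluster_rank(scores, clusters, target = 8), 5)
  # no ties: cluster rank equals worst-case rank
  s2 <- c(3, 2, 1)
  expect_equal(cluster_rank(s2, 1:3, target = 2), 2)
  expect_equal(worst_case_rank(s2, target = 2), 2)
  # everything tied in one cluster
  expect_equal(cluster_rank(rep(1, 4), rep(1, 4), target = 3), 1)
})

test_that("cluster rank never exceeds worst-case rank", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    scores <- sample(round(runif(5), 2), n, replace = TRUE)
    fps <- lapply(seq_len(n), function(i) runif(64) > 0.6)
    cl <- cluster_tied(scores, fps, threshold = 0.5)
    for (t in seq_len(n)) {
      expect_lte(cluster_rank(scores, cl, t), worst_case_rank(scores, t))
    }
  }
})

test_that("ppv is the matched fraction with guarded edges", {
  expect_equal(ppv(0, 100), 0)
  expect_equal(ppv(28, 1000), 0.028)
  expect_equal(ppv(5, 5), 1)
  expect_equal(ppv(0, 0), 0)
  expect_error(ppv(6, 5))
  # anti-monotone in the total at fixed matches
  expect_gt(ppv(10, 100), ppv(10, 200))
})

test_that("rank summaries use standard definitions", {
  s <- rank_summary(c(1, 1, 1))
  expect_equal(s$median, 1)
  expect_equal(s$mean, 1)
  s2 <- rank_summary(c(1, 2, 3, 100))
  expect_equal(s2$median, 2.5)
  expect_equal(s2$q75, unname(quantile(c(1, 2, 3, 100), 0.75)))
  expect_equal(s2$sd, sd(c(1, 2, 3, 100)))
  s3 <- rank_summary(7)
  expect_equal(s3$mean, 7)
  expect_true(is.na(s3$sd))
})
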