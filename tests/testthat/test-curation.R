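test_that("the SN filter applies the published thresholds strictly", {
  cfg <- tiny_config(n = 6, seed = 61)
  recs <- make_dataset(cfg)

  r <- recs[[1]]
  r$deg_Mg_50C[5] <- 25                       # max >= 20
  flagged <- apply_sn_filter(list(r))[[1]]
  expect_identical(flagged$SN_filter, 0L)

  r <- recs[[2]]                              # healthy synthetic record
  flagged <- apply_sn_filter(list(r))[[1]]
  expect_identical(flagged$SN_filter,
                   brute_filter_flag(r, filter_policy()))

  r <- recs[[3]]
  r$reactivity_error <- abs(r$reactivity)     # mu = sigma -> SN exactly 1
  flagged <- apply_sn_filter(list(r))[[1]]
  expect_identical(flagged$SN_filter, 0L)     # strict >
  expect_equal(flagged$signal_to_noise, 1.0)

  r <- recs[[4]]
  r$deg_pH10 <- NULL
  expect_identical(apply_sn_filter(list(r))[[1]]$SN_filter,
                   brute_filter_flag(r, filter_policy()))
  r$reactivity_error <- NULL
  expect_error(apply_sn_filter(list(r)), "error array")
})

test_that("filter flags equal a brute-force policy re-evaluation on 200 records", {
  cfg <- tiny_config(n = 200, seed = 62, fail_fraction = 0.3)
  recs <- make_dataset(cfg)
  pol <- filter_policy()
  flags <- vapply(apply_sn_filter(recs, pol), function(r) r$SN_filter, 0L)
  brute <- vapply(recs, brute_filter_flag, 0L, policy = pol)
  expect_identical(flags, brute)
  expect_true(any(flags == 0L) && any(flags == 1L))
})

test_that("identical sequences cluster together and a zero cut isolates distinct ones", {
  cl <- cluster_sequences(c(a = "ACGUACGU", b = "ACGUACGU"))
  expect_equal(unname(cl$labels["a"]), unname(cl$labels["b"]))
  expect_equal(unname(cl$sizes["a"]), 2L)

  seqs <- c(x = "ACGUACGUAA", y = "GGGGCCCCAA", z = "AUAUAUAUGG")
  cl0 <- cluster_sequences(seqs, cut = 0)
  expect_equal(length(unique(cl0$labels)), 3L)
})

test_that("well-separated blocks are recovered as two clusters", {
  set.seed(63)
  base1 <- generate_sequences(1, length = 40, prefix = NULL)[[1]]
  base2 <- generate_sequences(1, length = 40, prefix = NULL, gc_content = 0.9)[[1]]
  mutate <- function(s, k) {
    cc <- strsplit(s, "")[[1]]
    pos <- sample(length(cc), k)
    for (p in pos) cc[p] <- sample(setdiff(c("A", "C", "G", "U"), cc[p]), 1)
    paste(cc, collapse = "")
  }
  seqs <- c(vapply(1:3, function(i) mutate(base1, 2), ""),
            vapply(1:3, function(i) mutate(base2, 2), ""))
  names(seqs) <- paste0("s", 1:6)
  cl <- cluster_sequences(seqs, cut = 0.5)
  expect_equal(length(unique(cl$labels)), 2L)
  expect_equal(length(unique(cl$labels[1:3])), 1L)
  expect_equal(length(unique(cl$labels[4:6])), 1L)

  # brute-force check of the distances driving the merge decision
  D <- rnadeg:::sequence_distance_matrix(seqs)
  expect_lt(max(D[1:3, 1:3]), 0.25)
  expect_gt(min(D[1:3, 4:6]), 0.5)
})

test_that("small clusters are swept wholly into the private test set", {
  labels <- c(a = 1L, b = 2L, c = 2L, d = 3L, e = 3L, f = 3L,
              g = 4L, h = 4L, i = 4L, j = 4L, k = 4L,
              l = 5L, m = 5L, n = 5L, o = 5L, p = 5L)
  cl <- list(labels = labels)
  asg <- assign_splits(cl, list(private_test = 6, public_test = 4), seed = 1)
  small_ids <- c("a", "b", "c", "d", "e", "f")
  expect_setequal(asg$id[asg$split == "private_test"], small_ids)
  expect_equal(sum(asg$split == "public_test"), 4L)
  expect_equal(sum(asg$split == "train"), 6L)

  # top-up draws one member per randomly selected larger cluster
  asg2 <- assign_splits(cl, list(private_test = 8, public_test = 4), seed = 1)
  extra <- setdiff(asg2$id[asg2$split == "private_test"], small_ids)
  expect_equal(length(extra), 2L)
  expect_equal(length(unique(labels[extra])), 2L)
})

test_that("splits partition the ids and respect feasibility", {
  labels <- stats::setNames(rep(1:4, each = 5), paste0("r", 1:20))
  cl <- list(labels = labels)
  asg <- assign_splits(cl, list(private_test = 0, public_test = 8), seed = 2)
  expect_equal(sum(asg$split == "private_test"), 0L)
  expect_equal(anyDuplicated(asg$id), 0L)
  expect_setequal(asg$id, names(labels))

  expect_error(assign_splits(cl, list(private_test = 5, public_test = 1)),
               "at most 4 achievable")
  small <- list(labels = c(x = 1L, y = 2L))
  expect_error(assign_splits(small, list(private_test = 1, public_test = 0)),
               "forced")
})

test_that("split assignment is reproducible and seed-sensitive only in the random part", {
  labels <- stats::setNames(rep(1:6, each = 4), paste0("r", 1:24))
  cl <- list(labels = labels)
  t1 <- assign_splits(cl, list(private_test = 3, public_test = 6), seed = 7)
  t2 <- assign_splits(cl, list(private_test = 3, public_test = 6), seed = 7)
  expect_identical(t1, t2)
  t3 <- assign_splits(cl, list(private_test = 3, public_test = 6), seed = 8)
  expect_false(identical(t1$split, t3$split))
})

test_that("no training sequence shares a cluster with a quarantined private member", {
  cfg <- tiny_config(n = 40, seed = 64, duplicate_rate = 0.3)
  recs <- make_dataset(cfg)
  seqs <- stats::setNames(vapply(recs, function(r) r$sequence, ""),
                          vapply(recs, function(r) r$id, ""))
  cl <- cluster_sequences(seqs, cut = 0.5)
  n_small <- sum(table(cl$labels)[as.character(cl$labels)] <= 3)
  asg <- assign_splits(cl, list(private_test = n_small,
                                public_test = floor((40 - n_small) / 2)),
                       seed = 3)
  sizes <- stats::setNames(asg$cluster_size, asg$id)
  small_clusters <- unique(asg$cluster[asg$cluster_size <= 3])
  in_small <- asg$cluster %in% small_clusters
  expect_true(all(asg$split[in_small] == "private_test"))
  expect_false(any(asg$split[!in_small] == "private_test" &
                     asg$cluster_size[!in_small] <= 3))
  train_clusters <- unique(asg$cluster[asg$split == "train"])
  expect_length(intersect(train_clusters, small_clusters), 0)
})
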