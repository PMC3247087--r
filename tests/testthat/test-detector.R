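test_that("partition_blocks tiles the feature indices", {
  expect_length(partition_blocks(2000, 5), 400)
  expect_equal(partition_blocks(7, 7), list(1:7))
  b <- partition_blocks(23, 5)
  expect_equal(lengths(b), c(5L, 5L, 5L, 5L, 3L))
  expect_setequal(unlist(b), 1:23)
  # shuffled partition still tiles, and is seed-reproducible
  bs <- partition_blocks(23, 5, shuffle = TRUE, seed = 2)
  expect_setequal(unlist(bs), 1:23)
  expect_identical(bs, partition_blocks(23, 5, shuffle = TRUE, seed = 2))
  expect_false(identical(bs, b))
})

test_that("fit counts follow the blockwise arithmetic", {
  cf <- count_fits(2000, 5)
  expect_equal(cf$n_blocks, 400L)
  expect_equal(cf$blockwise_fits, 79800)
  expect_equal(cf$exhaustive_fits, 1999000)
  expect_equal(count_fits(2, 1), list(n_blocks = 2L, blockwise_fits = 1,
                                      exhaustive_fits = 1))
  # enumerate-and-count oracle at p = 17, bsize = 4
  nb <- length(partition_blocks(17, 4))
  expect_equal(count_fits(17, 4)$blockwise_fits, nrow(t(utils::combn(nb, 2))))
  # blockwise never exceeds exhaustive; equality only at bsize = 1
  for (p in c(2, 9, 30)) {
    for (bs in 1:4) {
      cf <- count_fits(p, bs)
      if (bs == 1) expect_equal(cf$blockwise_fits, cf$exhaustive_fits)
      else expect_lt(cf$blockwise_fits, cf$exhaustive_fits)
    }
  }
})

test_that("configs violating the peaking protection rule are rejected", {
  expect_error(block_search_config(bsize = 6, p_star = 10), "p_star")
  expect_error(block_search_config(bsize = 8, p_star = 15), "p_star")
  expect_s3_class(block_search_config(bsize = 7, p_star = 15),
                  "block_search_config")
})

test_that("ranking block matchings surfaces the signal block", {
  # planted pair at columns 1-2 of p = 50; any matching with block 1
  # carries the signal
  hits <- 0L
  for (s in 1:20) {
    d <- planted_dataset("linear", p = 50, seed = s)
    cfg <- block_search_config(bsize = 5, seed = s)
    rk <- rank_block_matchings(d, cfg)
    expect_equal(rk$n_fits, count_fits(50, 5)$blockwise_fits)
    top <- rk$matchings[1, ]
    hits <- hits + (top$block_a == 1L || top$block_b == 1L)
    # noise-only matchings sit at a high error
    expect_gt(utils::tail(rk$matchings$cv_error, 1), 0.35)
    # ranking is sorted
    expect_false(is.unsorted(rk$matchings$cv_error))
  }
  expect_gte(hits, 19L)
})

test_that("an all-noise dataset yields no separable ranking structure", {
  d <- simulate_noise_only(40, 40, 30, seed = 77)
  rk <- rank_block_matchings(d, block_search_config(bsize = 5, seed = 77))
  e <- rk$matchings$cv_error
  # as a population, the ranked errors are indistinguishable from the CV
  # errors of independently drawn pure-noise chunks of the same size
  ref <- vapply(seq_along(e), function(s) {
    dn <- simulate_noise_only(40, 40, 10, seed = 7000 + s)
    cv_error(dn$X, dn$y, seed = 7000 + s)$error_rate
  }, numeric(1))
  expect_gt(overlap_measure(e, ref)$overlap, 0.4)
  expect_gt(min(e), 0.2)
})

test_that("heat matrices are symmetric and match direct recomputation", {
  d <- planted_dataset("xor", p = 20, seed = 6)
  cfg <- block_search_config(bsize = 5, seed = 6)
  hm <- pairwise_heatmatrix(d, 1:10, cfg)
  expect_true(isSymmetric(hm$errors))
  expect_true(all(hm$errors >= 0 & hm$errors <= 1))
  # brute-force re-computation oracle with the same folds
  folds <- make_folds(d$y, 10, seed = 6)
  direct <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    cols <- unique(c(i, j))
    direct[i, j] <- qdadetect:::qda_cv_rate(d$X[, cols, drop = FALSE],
                                            d$y, folds, 10)
  }
  expect_equal(unname(hm$errors), direct)
  # planted pair is the matrix minimum (isolated hot spot)
  off <- hm$errors; diag(off) <- NA
  hot <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(sort(unname(hot)), c(1L, 2L))

  # a 2-feature subset reduces to a single cv_error
  hm2 <- pairwise_heatmatrix(d, c(3L, 9L), cfg)
  expect_equal(hm2$errors[1, 2],
               cv_error(d$X[, c(3, 9)], d$y, seed = 6)$error_rate)
})

test_that("detect_interactions runs the two stages coherently", {
  d <- planted_dataset("circular", p = 40, seed = 15)
  cfg <- block_search_config(bsize = 5, seed = 15, top_m = 4)
  det <- detect_interactions(d, cfg)
  # sorted output, planted pair on top
  expect_false(is.unsorted(det$pairs$cv_error))
  expect_equal(det$pairs$col_i[1], 1L)
  expect_equal(det$pairs$col_j[1], 2L)
  # the reported top error is the minimum over every pair scored in the
  # top matchings (exhaustive rescan)
  folds <- make_folds(d$y, 10, seed = 15)
  rescan <- min(vapply(seq_len(nrow(det$pairs)), function(r) {
    qdadetect:::qda_cv_rate(
      d$X[, c(det$pairs$col_i[r], det$pairs$col_j[r])], d$y, folds, 10)
  }, numeric(1)))
  expect_equal(det$pairs$cv_error[1], rescan)
  # pairs are unique
  expect_false(anyDuplicated(det$pairs[, c("col_i", "col_j")]) > 0)
  # determinism end to end
  det2 <- detect_interactions(d, cfg)
  expect_identical(det$pairs, det2$pairs)
})

test_that("a single-matching search collapses to the heat matrix", {
  d <- planted_dataset("linear", p = 10, seed = 8)
  cfg <- block_search_config(bsize = 5, seed = 8)
  det <- detect_interactions(d, cfg)
  hm <- pairwise_heatmatrix(d, 1:10, cfg)
  # same pairs, same errors, sorted
  expect_equal(nrow(det$pairs), choose(10, 2))
  for (r in c(1L, 10L, 45L)) {
    expect_equal(det$pairs$cv_error[r],
                 hm$errors[det$pairs$col_i[r], det$pairs$col_j[r]])
  }
})

test_that("importance screening removes exactly the top-ranked features", {
  d <- simulate_noise_only(20, 20, 30, seed = 44)
  imp <- withr::with_seed(45, runif(30))
  out <- screen_by_importance(d, imp, n_remove = 10)
  expect_equal(ncol(out$screened$X), 20L)
  # sort-oracle agreement
  expect_setequal(out$removed,
                  d$feature_ids[order(imp, decreasing = TRUE)[1:10]])
  # identity at n_remove = 0
  out0 <- screen_by_importance(d, imp, 0)
  expect_identical(out0$screened, d)
  expect_error(screen_by_importance(d, imp, 30), "at least one")
  # ties broken by column order
  out_t <- screen_by_importance(d, rep(1, 30), 3)
  expect_equal(out_t$removed, d$feature_ids[1:3])
})

test_that("duplicate columns are dropped idempotently", {
  d <- simulate_noise_only(10, 10, 6, seed = 50)
  X <- d$X
  X[, 5] <- X[, 2]                     # plant a duplicate
  dd <- labeled_dataset(X, d$y, feature_ids = d$feature_ids)
  out <- drop_duplicate_features(dd)
  expect_equal(ncol(out$X), 5L)
  expect_false("noise_0005" %in% out$feature_ids)
  expect_true("noise_0002" %in% out$feature_ids)   # first occurrence kept
  expect_identical(drop_duplicate_features(out), out)
})
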