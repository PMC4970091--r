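test_that("patch extraction crops, replicates edges, and validates centres", {
  gray <- matrix(seq(0, 1, length.out = 200 * 200), 200, 200)
  p <- extract_patch(gray, c(100, 100))
  expect_equal(dim(p), c(40, 40))
  expect_equal(p[20, 20], gray[101, 101])  # centre pixel at offset 19
  # corner centre: replication fills out-of-bounds area
  p0 <- extract_patch(gray, c(0, 0))
  expect_equal(dim(p0), c(40, 40))
  expect_true(all(p0[1:20, 1] == gray[1, 1]))
  expect_error(extract_patch(gray, c(-1, 5)), "outside")
  expect_error(extract_patch(gray, c(5, 200)), "outside")
  # constant image -> constant patch
  expect_true(all(extract_patch(matrix(0.3, 60, 60), c(30, 30)) == 0.3))
})

test_that("Harris finds no keypoints on constant patches and finds square corners", {
  expect_equal(nrow(harris_keypoints(matrix(0.5, 40, 40))), 0)

  patch <- matrix(0, 40, 40)
  patch[13:28, 13:28] <- 1   # high-contrast square, corners at 12 & 27
  kps <- harris_keypoints(patch)
  expect_gte(nrow(kps), 4)
  corners <- rbind(c(12, 12), c(12, 27), c(27, 12), c(27, 27))
  for (r in seq_len(4)) {
    d <- sqrt((kps$x - corners[r, 1])^2 + (kps$y - corners[r, 2])^2)
    expect_lte(min(d), 1.5)
  }
  # no keypoint along the straight edges far from corners
  mid_edge <- sqrt((kps$x - 20)^2 + (kps$y - 12)^2)
  expect_gte(min(mid_edge), 3)
})

test_that("Harris keypoints shift with a translated pattern", {
  set.seed(8)
  base <- matrix(0, 60, 60)
  base[20:26, 20:26] <- matrix(runif(49), 7, 7)
  k1 <- harris_keypoints(base)
  shifted <- phenonode:::shift_mat(base, -5L, -7L)
  k2 <- harris_keypoints(shifted)
  expect_equal(nrow(k1), nrow(k2))
  ord1 <- order(k1$y, k1$x); ord2 <- order(k2$y, k2$x)
  expect_equal(k2$x[ord2], k1$x[ord1] + 7)
  expect_equal(k2$y[ord2], k1$y[ord1] + 5)
})

test_that("descriptors meet the format contract and are deterministic", {
  set.seed(12)
  patch <- matrix(runif(1600), 40, 40)
  kps <- harris_keypoints(patch)
  expect_gt(nrow(kps), 0)
  d <- sift_descriptors(patch, kps)
  expect_equal(ncol(d), 128)
  expect_equal(nrow(d), nrow(kps))
  expect_true(all(is.finite(d)))
  expect_true(all(d >= 0))
  norms <- sqrt(rowSums(d^2))
  expect_true(all(norms <= 1 + 1e-9))
  expect_true(all(abs(norms - 1) < 1e-9))   # gradient-bearing patches
  expect_identical(d, sift_descriptors(patch, kps))
  expect_equal(nrow(sift_descriptors(patch, kps[0, ])), 0)
})

test_that("vocabulary recovers well-separated descriptor blobs", {
  set.seed(30)
  centers <- matrix(runif(10 * 128), 10)
  centers <- centers / sqrt(rowSums(centers^2))
  descs <- do.call(rbind, lapply(1:10, function(i) {
    matrix(rep(centers[i, ], each = 30), 30) +
      matrix(rnorm(30 * 128, 0, 0.002), 30)
  }))
  truth <- rep(1:10, each = 30)
  vocab <- build_vocabulary(descs, k = 10, seed = 4)
  expect_equal(nrow(vocab$centers), 10)
  expect_false(anyNA(vocab$centers))
  # one centroid per blob: nearest-centre assignment matches blob id
  d2 <- as.matrix(dist(rbind(vocab$centers, descs)))[-(1:10), 1:10]
  assign <- max.col(-d2)
  expect_equal(length(unique(assign[truth == 1])), 1)
  tab <- table(truth, assign)
  expect_true(all(apply(tab > 0, 1, sum) == 1))
  expect_equal(max.col(tab) %in% 1:10, rep(TRUE, 10))
  # exactly k descriptors -> the centroids are the descriptors
  v2 <- build_vocabulary(centers, k = 10, seed = 1)
  reord <- apply(as.matrix(dist(rbind(v2$centers, centers)))[-(1:10), 1:10],
                 1, which.min)
  expect_equal(sort(unname(reord)), 1:10)
  expect_equal(v2$centers[reord, ], centers, tolerance = 1e-12,
               ignore_attr = TRUE)
  # determinism
  v3 <- build_vocabulary(descs, k = 10, seed = 4)
  expect_identical(vocab$centers, v3$centers)
  expect_error(build_vocabulary(descs[1:5, ], k = 10), "at least")
})

test_that("histogram encoding matches exhaustive nearest-centroid counting", {
  set.seed(31)
  vocab <- build_vocabulary(matrix(runif(40 * 128), 40), k = 10, seed = 2)
  for (rep in 1:5) {
    descs <- matrix(runif(200 * 128), 200)
    enc <- encode_histogram(descs, vocab)
    expect_false(enc$empty)
    expect_equal(sum(enc$hist), 1, tolerance = 1e-9)
    counts <- integer(10)
    for (i in 1:200) {
      d2 <- colSums((t(vocab$centers) - descs[i, ])^2)
      counts[which.min(d2)] <- counts[which.min(d2)] + 1L
    }
    expect_equal(enc$hist, counts / 200)
  }
  # one descriptor equal to centroid 3 -> one-hot at bin 3
  enc3 <- encode_histogram(vocab$centers[3, , drop = FALSE], vocab)
  expect_equal(enc3$hist, c(0, 0, 1, rep(0, 7)))
  # empty descriptor set -> empty flag and zero vector
  enc0 <- encode_histogram(matrix(numeric(0), 0, 128), vocab)
  expect_true(enc0$empty)
  expect_equal(enc0$hist, numeric(10))
})

test_that("patch classifier separates, nulls out on shuffled labels, and is deterministic", {
  set.seed(40)
  n <- 120
  hist_node <- t(replicate(n, { h <- c(runif(5, 1, 2), runif(5, 0, 0.1));
                                h / sum(h) }))
  hist_non <- t(replicate(n, { h <- c(runif(5, 0, 0.1), runif(5, 1, 2));
                               h / sum(h) }))
  X <- rbind(hist_node, hist_non)
  y <- rep(c("node", "non_node"), each = n)
  clf <- train_patch_classifier(X, y, n_trees = 200, seed = 9)
  expect_identical(predict(clf, X), y)
  expect_gte(clf$oob_accuracy, 0.95)
  # permutation null: shuffled labels give chance-level OOB accuracy
  set.seed(41)
  clf_null <- train_patch_classifier(X, sample(y), n_trees = 200, seed = 9)
  expect_lt(abs(clf_null$oob_accuracy - 0.5), 0.15)
  # determinism under a fixed seed
  clf2 <- train_patch_classifier(X, y, n_trees = 200, seed = 9)
  expect_identical(predict(clf2, X), predict(clf, X))
  expect_error(train_patch_classifier(X, rep("node", 2 * n)), "both classes")
})

test_that("candidate classification applies the empty-patch rule and statuses", {
  seq1 <- small_sequence()
  models <- small_models()
  # a candidate on a perfectly flat image: no keypoints -> non-node by
  # rule, without consulting the classifier
  flat <- matrix(0.5, 120, 120)
  cflat <- data.frame(x = 60L, y = 60L, status = "active",
                      reason = NA_character_)
  oflat <- classify_candidates(flat, cflat, models$vocab,
                               models$classifier)
  expect_identical(oflat$status, "removed_bovw")
  expect_match(oflat$reason, "no keypoints")
  # a candidate at a true node on a rendered frame is accepted
  gray <- phenonode:::to_gray(seq1$frames[[1]])
  cands <- data.frame(x = round(seq1$gt$nodes[[1]]$x[1]),
                      y = round(seq1$gt$nodes[[1]]$y[1]),
                      status = "active", reason = NA_character_)
  out <- classify_candidates(gray, cands, models$vocab, models$classifier)
  expect_identical(out$status, "accepted")
  # reported location is the candidate pixel itself
  expect_identical(out$x, cands$x)
  expect_identical(out$y, cands$y)
})
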