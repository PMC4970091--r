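test_that("degenerate clustering inputs are handled", {
  cl <- cluster_by_y(300)
  expect_equal(cl$n, 1)
  expect_equal(cl$assignment, 1L)
  expect_equal(cl$mean_y, 300)
  expect_error(cluster_by_y(numeric(0)), "no detections")
})

test_that("well-separated groups are recovered and match the exhaustive oracle", {
  set.seed(1)
  # 30 nodes in 3 groups at y ~ 500, 300, 100
  y3 <- c(rnorm(10, 500, 2), rnorm(10, 300, 2), rnorm(10, 100, 2))
  cl3 <- cluster_by_y(y3)
  expect_equal(cl3$n, 3)
  expect_true(same_partition(cl3$assignment, rep(1:3, each = 10)))
  # 2 groups at y ~ 400 and 100
  y2 <- c(rnorm(10, 400, 2), rnorm(10, 100, 2))
  cl2 <- cluster_by_y(y2)
  expect_equal(cl2$n, 2)
  expect_true(same_partition(cl2$assignment, rep(1:2, each = 10)))
  # exhaustive exemplar-subset oracle on <= 12-point subsamples
  for (seed in 1:4) {
    set.seed(seed)
    ys <- as.vector(sapply(c(450, 280, 120), function(m) m + rnorm(4, 0, 2)))
    S <- -outer(ys, ys, function(a, b) (a - b)^2)
    diag(S) <- stats::median(S[row(S) != col(S)])
    opt <- exhaustive_exemplars(S)
    cl <- cluster_by_y(ys)
    expect_equal(cl$n, length(opt$exemplars))
    expect_true(same_partition(cl$assignment, opt$assignment))
  }
})

test_that("order assignment sorts by decreasing mean y with time tie-break", {
  cl <- structure(list(n = 3, assignment = c(1L, 2L, 3L),
                       exemplars = 1:3, mean_y = c(250, 480, 90)),
                  class = "node_clustering")
  expect_equal(assign_orders(cl), c(2L, 1L, 3L))
  # single cluster -> order 1
  cl1 <- structure(list(n = 1, assignment = c(1L, 1L), exemplars = 1L,
                        mean_y = 300), class = "node_clustering")
  expect_equal(assign_orders(cl1), 1L)
  # exact tie in mean y: older cluster (smaller min t) gets lower order
  clt <- structure(list(n = 2, assignment = c(1L, 2L), exemplars = 1:2,
                        mean_y = c(200, 200)), class = "node_clustering")
  expect_equal(assign_orders(clt, t = c(50, 10)), c(2L, 1L))
  expect_equal(assign_orders(clt, t = c(10, 50)), c(1L, 2L))
})

test_that("order assignment is invariant to cluster relabelling", {
  set.seed(2)
  y <- c(rnorm(8, 450, 2), rnorm(8, 250, 2), rnorm(8, 80, 2))
  cl <- cluster_by_y(y)
  ord <- assign_orders(cl)
  # permute cluster ids
  perm <- sample(cl$n)
  clp <- cl
  clp$assignment <- perm[cl$assignment]
  clp$mean_y <- cl$mean_y[order(perm)]
  ordp <- assign_orders(clp)
  expect_equal(ordp[perm], ord)
})

test_that("node lines recover exact and noisy linear tracks", {
  t0 <- 1404158400
  # constant track
  nodes_c <- data.frame(t = t0 + (0:4) * 7200, y = rep(300, 5))
  cl_c <- cluster_by_y(nodes_c$y)
  ln_c <- fit_node_lines(nodes_c, cl_c)
  expect_equal(ln_c$slope, 0, tolerance = 1e-12)
  expect_equal(ln_c$intercept, 300, tolerance = 1e-9)
  expect_equal(ln_c$appearance_time, t0)
  # exact linear track y = 500 - 0.0005 (t - t0)
  tt <- t0 + seq(0, 6e5, length.out = 30)
  nodes_l <- data.frame(t = tt, y = 500 - 5e-4 * (tt - t0))
  ln_l <- fit_node_lines(nodes_l, cluster_by_y(nodes_l$y,
                                               preference = -1e9))
  expect_equal(nrow(ln_l), 1)
  expect_equal(ln_l$slope, -5e-4, tolerance = 1e-12)
  expect_equal(ln_l$intercept + ln_l$slope * t0, 500, tolerance = 1e-6)
  # noisy track matches the closed-form OLS oracle; holdout within 3 sigma
  set.seed(3)
  yy <- 500 - 5e-4 * (tt - t0) + rnorm(30, 0, 3)
  fitidx <- 1:25
  nodes_n <- data.frame(t = tt[fitidx], y = yy[fitidx])
  ln_n <- fit_node_lines(nodes_n, cluster_by_y(nodes_n$y,
                                               preference = -1e9))
  ref <- ols_closed_form(nodes_n$t, nodes_n$y)
  expect_equal(ln_n$slope, unname(ref["slope"]), tolerance = 1e-9)
  expect_equal(ln_n$intercept, unname(ref["intercept"]), tolerance = 1e-6)
  pred_hold <- node_y_at(ln_n, 1, tt[26:30])
  truth_hold <- 500 - 5e-4 * (tt[26:30] - t0)
  expect_true(all(abs(pred_hold - truth_hold) <= 9))
})

test_that("node_y_at is linear and exact on members of exact tracks", {
  lines <- data.frame(order = 1L, slope = 0, intercept = 300,
                      appearance_time = 0, n_members = 5L)
  class(lines) <- c("node_lines", "data.frame")
  expect_equal(node_y_at(lines, 1, c(-1e9, 0, 1e9)), rep(300, 3))
  lines2 <- data.frame(order = 1L, slope = -2e-4, intercept = 500,
                       appearance_time = 0, n_members = 5L)
  class(lines2) <- c("node_lines", "data.frame")
  t1 <- 1000; t2 <- 5000
  mid <- node_y_at(lines2, 1, (t1 + t2) / 2)
  expect_equal(mid, mean(node_y_at(lines2, 1, c(t1, t2))))
  expect_error(node_y_at(lines2, 3, 0), "no node line")
})

test_that("cluster count matches the true node count on separated tracks", {
  # separation >= 5x within-track spread
  for (n_tracks in 3:5) {
    d <- simulate_detections(n_tracks, n_frames = 30, gap_px = 60,
                             spread_px = 3, drift_px = 10,
                             seed = 100 + n_tracks)
    cl <- cluster_by_y(d$y)
    expect_equal(cl$n, n_tracks)
    expect_true(same_partition(cl$assignment, d$track))
  }
})

test_that("false-positive injection moves node lines by less than separation/4", {
  gap <- 60
  d <- simulate_detections(4, n_frames = 40, gap_px = gap, spread_px = 3,
                           drift_px = 10, fp_rate = 0.1 * 4, seed = 55)
  clean <- d[d$track > 0, ]
  cl0 <- cluster_by_y(clean$y)
  ln0 <- fit_node_lines(data.frame(t = clean$t, y = clean$y), cl0)
  cl1 <- cluster_by_y(d$y)
  ln1 <- fit_node_lines(data.frame(t = d$t, y = d$y), cl1)
  expect_equal(nrow(ln1), 4)
  tt <- sort(unique(clean$t))
  for (o in 1:4) {
    expect_true(all(abs(node_y_at(ln0, o, tt) - node_y_at(ln1, o, tt))
                    <= gap / 4))
  }
})

test_that("deleting a contiguous block of one node's detections barely moves its line", {
  # noiseless linear tracks; the gap is interpolated by the regression
  d <- simulate_detections(4, n_frames = 40, gap_px = 60, spread_px = 0,
                           drift_px = 12, detect_rate = 1, seed = 77)
  tt <- sort(unique(d$t))
  hole <- tt[17:24]                       # contiguous middle 20%
  thin <- d[!(d$track == 2 & d$t %in% hole), ]
  ln_full <- fit_node_lines(data.frame(t = d$t, y = d$y),
                            cluster_by_y(d$y))
  ln_thin <- fit_node_lines(data.frame(t = thin$t, y = thin$y),
                            cluster_by_y(thin$y))
  for (o in 1:4) {
    expect_true(all(abs(node_y_at(ln_full, o, tt) -
                          node_y_at(ln_thin, o, tt)) <= 2))
  }
})
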