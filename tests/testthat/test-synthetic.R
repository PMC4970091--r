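test_that("the spec validates its inputs", {
  expect_error(seedling_spec(n_nodes = 1), "n_nodes")
  expect_error(seedling_spec(collar_radius = 10), "collar_radius")
  expect_error(seedling_spec(colors = list(stem = c(0.5, 0.5, 0.5),
                                           leaf = c(0.52, 0.5, 0.5),
                                           background = c(0.9, 0.9, 0.9),
                                           sigma = 0.05)), "10 sigma")
  # a spec that grows past the canvas is refused at render time
  tall <- seedling_spec(height = 200, n_nodes = 5,
                        initial_internodes_mm = c(40, 40, 40, 40),
                        elongation_mm_day = c(3, 3, 3, 3))
  expect_error(render_sequence(tall), "outgrows")
})

test_that("capture cadence is five per night at two-hour spacing", {
  spec <- seedling_spec(nights = 3)
  expect_equal(length(spec$timestamps), 15)
  within_night <- diff(spec$timestamps[1:5])
  expect_equal(within_night, rep(7200, 4))
  expect_equal(spec$timestamps[6] - spec$timestamps[5], 16 * 3600)
})

test_that("node geometry follows the configured linear growth exactly", {
  spec <- seedling_spec(n_nodes = 4, seed = 5)
  t0 <- spec$timestamps[1]
  np0 <- node_positions(spec, t0)
  np2 <- node_positions(spec, t0 + 2 * 86400)
  # order 1 has the largest y in every frame
  expect_true(all(diff(np0$y) < 0))
  l0 <- -diff(np0$y) * spec$mm_per_px
  expect_equal(l0, spec$initial_internodes_mm, tolerance = 1e-12)
  l2 <- -diff(np2$y) * spec$mm_per_px
  expect_equal(l2, spec$initial_internodes_mm + 2 * spec$elongation_mm_day,
               tolerance = 1e-12)
  # zero elongation keeps node centres identical across frames
  frozen <- seedling_spec(n_nodes = 3, elongation_mm_day = c(0, 0))
  a <- node_positions(frozen, frozen$timestamps[1])
  b <- node_positions(frozen, frozen$timestamps[10])
  expect_equal(a$y, b$y)
  expect_equal(a$x, b$x)
})

test_that("rendering is deterministic and ground truth is exact", {
  spec <- seedling_spec(width = 200, height = 360, n_nodes = 3, nights = 2,
                        base_x = 90, seed = 99)
  s1 <- render_sequence(spec)
  s2 <- render_sequence(spec)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$gt, s2$gt)
  # GT internode lengths follow the linear law at every timestamp
  days <- (s1$timestamps - s1$timestamps[1]) / 86400
  for (p in seq_len(spec$n_nodes - 1)) {
    expect_equal(s1$gt$internode_mm[, p],
                 spec$initial_internodes_mm[p] +
                   spec$elongation_mm_day[p] * days,
                 tolerance = 1e-12)
  }
  # telescoping: sum of internodes = (y1 - yn) * mm_per_px per frame
  for (fi in c(1, 5, 10)) {
    nd <- s1$gt$nodes[[fi]]
    expect_equal(sum(s1$gt$internode_mm[fi, ]),
                 (max(nd$y) - min(nd$y)) * spec$mm_per_px,
                 tolerance = 1e-9)
  }
  # class maps match the rendered classes structurally
  cm <- s1$gt$class_maps[[1]]
  expect_true(all(cm %in% 1:3))
  expect_gt(sum(cm == 2L), 500)   # stem present
  expect_gt(sum(cm == 3L), 500)   # leaves present
  # rectangles cover the node centres and respect the size range
  r1 <- s1$gt$rects[[1]]
  expect_true(all(r1$width >= 28 & r1$width <= 80))
  expect_true(all(r1$height >= 28 & r1$height <= 82))
  nd1 <- s1$gt$nodes[[1]]
  expect_true(all(nd1$x >= r1$x_min & nd1$x <= r1$x_min + r1$width))
  expect_true(all(nd1$y >= r1$y_min & nd1$y <= r1$y_min + r1$height))
})

test_that("shifting all capture times shifts nothing but the time axis", {
  base <- seedling_spec(width = 200, height = 360, n_nodes = 3, nights = 2,
                        base_x = 90, seed = 31)
  shifted <- base
  shifted$timestamps <- base$timestamps + 123456
  shifted$appearance_times <- base$appearance_times + 123456
  s1 <- render_sequence(base)
  s2 <- render_sequence(shifted)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$gt$internode_mm, s2$gt$internode_mm)
  expect_equal(s2$timestamps, s1$timestamps + 123456)
})

test_that("staggered appearance times hide late nodes and gate their traces", {
  spec <- seedling_spec(width = 220, height = 400, n_nodes = 4, nights = 2,
                        base_x = 100, seed = 13)
  spec$appearance_times[4] <- spec$timestamps[6]
  s <- render_sequence(spec)
  expect_equal(nrow(s$gt$nodes[[1]]), 3)
  expect_equal(nrow(s$gt$nodes[[6]]), 4)
  expect_equal(nrow(s$gt$rects[[5]]), 3)
})

test_that("pixel training sets are stratified, labelled correctly and reproducible", {
  s <- small_sequence()
  ts <- make_pixel_training_set(s, counts = c(stem = 100, leaf = 100,
                                              background = 100), seed = 3)
  expect_equal(nrow(ts$features), 300)
  expect_equal(as.vector(table(ts$labels)), c(100, 100, 100))
  expect_identical(colnames(ts$features), color_feature_names())
  ts2 <- make_pixel_training_set(s, counts = c(stem = 100, leaf = 100,
                                               background = 100), seed = 3)
  expect_identical(ts$features, ts2$features)
  # sampled labels separate in colour space the way the classes do:
  # a tree trained on the sample classifies it almost perfectly
  tr <- train_dtsm(ts$features, ts$labels)
  expect_gte(mean(predict(tr, ts$features) == ts$labels), 0.98)
})

test_that("patch training sets respect centring and exclusion rules", {
  s <- small_sequence()
  ps <- make_patch_training_set(s, n_node = 30, n_non_node = 40, seed = 5)
  expect_equal(sum(ps$labels == "node"), 30)
  expect_equal(sum(ps$labels == "non_node"), 40)
  expect_true(all(vapply(ps$patches, function(p) all(dim(p) == c(40, 40)),
                         TRUE)))
  for (i in which(ps$labels == "node")) {
    fi <- ps$centers$frame[i]
    nd <- s$gt$nodes[[fi]]
    d <- sqrt((nd$x - ps$centers$x[i])^2 + (nd$y - ps$centers$y[i])^2)
    expect_lte(min(d), sqrt(2) * 3 + 1)
  }
  for (i in which(ps$labels == "non_node")) {
    fi <- ps$centers$frame[i]
    nd <- s$gt$nodes[[fi]]
    d <- sqrt((nd$x - ps$centers$x[i])^2 + (nd$y - ps$centers$y[i])^2)
    expect_gte(min(d), 30)
  }
})

test_that("simulated detection sets have the declared track structure", {
  d <- simulate_detections(4, n_frames = 30, gap_px = 60, spread_px = 3,
                           drift_px = 10, detect_rate = 1, seed = 8)
  expect_equal(sort(unique(d$track)), 1:4)
  sds <- tapply(d$y, d$track, sd)
  gaps <- abs(diff(sort(tapply(d$y, d$track, mean))))
  expect_true(all(gaps >= 5 * max(sds)))
  d2 <- simulate_detections(4, n_frames = 30, seed = 8)
  d1 <- simulate_detections(4, n_frames = 30, seed = 8)
  expect_identical(d1, d2)
})
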