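# Synthetic seedling sequences with exact ground truth.
#
# The renderer emulates what the measurement pipeline assumes about its
# subject: a near-vertical stem imaged nightly at fixed intervals, whose
# internodes elongate linearly in time; nodes are stem/petiole junctions
# carrying textured leaves; the three pixel classes have well-separated
# colour distributions. Every frame comes with its exact class map, node
# centres, annotation rectangles and internode lengths in millimetres.

#' Specification of a synthetic seedling sequence
#'
#' @param width,height Image size in pixels (default 640 x 480).
#' @param n_nodes Number of main-stem nodes (2..6, default 4).
#' @param nights Number of nights imaged (default 8).
#' @param captures_per_night Captures per night (default 5, at 8 p.m.,
#'   10 p.m., midnight, 2 a.m. and 4 a.m.).
#' @param start_time UNIX time of the first day, 00:00 (default
#'   1404158400).
#' @param initial_internodes_mm Internode lengths (mm) at the first
#'   capture, one per adjacent node pair, lowest pair first.
#' @param elongation_mm_day Linear elongation rate (mm/day) per
#'   internode.
#' @param hypocotyl_mm Constant base-to-first-node distance (mm).
#' @param appearance_times Optional UNIX times at which each node
#'   becomes visible (default: all visible from the first capture).
#' @param base_x,base_y Stem base pixel (defaults: horizontal centre,
#'   30 px above the bottom edge).
#' @param stem_tilt Horizontal drift of the stem centreline, px of x per
#'   px of y (default 0.05).
#' @param curvature Quadratic bend of the centreline (default 0; the
#'   straight stem matches the linear main-stem model).
#' @param stem_width Stem band width in px (default 7).
#' @param colors List with `stem`, `leaf`, `background` mean RGB in
#'   \[0,1\] and `sigma`, the per-channel Gaussian spread.
#' @param leaf_axes Leaf ellipse semi-axes in px (default c(20, 13)).
#' @param leaf_texture Leaf brightness texture amplitude (default 0.2).
#' @param collar_radius,collar_texture Radius (px) and texture amplitude
#'   of the small textured collar (axillary bud) at each node.
#' @param rect_size_range Side-length range the annotation rectangles
#'   are drawn from (default 30..56 px, within typical hand-annotation
#'   sizes and below the internode spacing).
#' @param mm_per_px Scale calibration (default 0.41).
#' @param seed Integer RNG seed; the rendering is deterministic given
#'   the seed.
#' @return Object of class `"seedling_spec"`.
#' @export
seedling_spec <- function(width = 640, height = 480, n_nodes = 4,
                          nights = 8, captures_per_night = 5,
                          start_time = 1404158400,
                          initial_internodes_mm = NULL,
                          elongation_mm_day = NULL,
                          hypocotyl_mm = 30,
                          appearance_times = NULL,
                          base_x = NULL, base_y = NULL,
                          stem_tilt = 0.05, curvature = 0,
                          stem_width = 7,
                          colors = list(
                            stem = c(0.45, 0.30, 0.25),
                            leaf = c(0.20, 0.55, 0.20),
                            background = c(0.85, 0.85, 0.88),
                            sigma = 0.02),
                          leaf_axes = c(20, 13), leaf_texture = 0.2,
                          collar_radius = 3, collar_texture = 0.15,
                          rect_size_range = c(30, 56),
                          mm_per_px = 0.41, seed = 1L) {
  stopifnot(n_nodes >= 2, n_nodes <= 6, mm_per_px > 0, stem_width >= 3)
  # the collar is a texture marker, not a silhouette feature: keep it
  # inside the stem band so it cannot deform the skeleton
  stopifnot(collar_radius <= stem_width / 2)
  if (is.null(initial_internodes_mm)) {
    initial_internodes_mm <- c(25, 20, 15, 12, 10)[seq_len(n_nodes - 1)]
  }
  if (is.null(elongation_mm_day)) {
    elongation_mm_day <- c(0.30, 0.35, 0.40, 0.45, 0.50)[seq_len(n_nodes - 1)]
  }
  stopifnot(length(initial_internodes_mm) == n_nodes - 1,
            length(elongation_mm_day) == n_nodes - 1,
            all(elongation_mm_day >= 0))
  # hours after local midnight of each capture within a night
  hours <- c(20, 22, 24, 26, 28)[seq_len(captures_per_night)]
  timestamps <- as.numeric(outer(hours * 3600,
                                 start_time + (seq_len(nights) - 1) * 86400,
                                 "+"))
  timestamps <- sort(timestamps)
  if (is.null(appearance_times)) {
    appearance_times <- rep(timestamps[1], n_nodes)
  }
  stopifnot(length(appearance_times) == n_nodes)
  # colour classes must be clearly separable for the pixel classifier
  mu <- rbind(colors$stem, colors$leaf, colors$background)
  dmin <- min(dist(mu))
  if (dmin < 10 * colors$sigma) {
    stop("class colour means are closer than 10 sigma; pixels would not ",
         "be separable", call. = FALSE)
  }
  structure(list(
    width = width, height = height, n_nodes = n_nodes,
    timestamps = timestamps,
    initial_internodes_mm = initial_internodes_mm,
    elongation_mm_day = elongation_mm_day,
    hypocotyl_mm = hypocotyl_mm,
    appearance_times = appearance_times,
    base_x = base_x %||% (width / 2), base_y = base_y %||% (height - 30),
    stem_tilt = stem_tilt, curvature = curvature, stem_width = stem_width,
    colors = colors, leaf_axes = leaf_axes, leaf_texture = leaf_texture,
    collar_radius = collar_radius, collar_texture = collar_texture,
    rect_size_range = rect_size_range,
    mm_per_px = mm_per_px, seed = as.integer(seed)),
    class = "seedling_spec")
}

#' True node geometry of a synthetic seedling at one time
#'
#' @param spec A `"seedling_spec"`.
#' @param t UNIX time.
#' @return Data frame with `order`, `x`, `y` (pixel centres, floats),
#'   `visible`, and the exact internode lengths are recoverable as
#'   `diff(-y) * mm_per_px`.
#' @export
node_positions <- function(spec, t) {
  days <- (t - spec$timestamps[1]) / 86400
  l_mm <- spec$initial_internodes_mm + spec$elongation_mm_day * days
  y <- numeric(spec$n_nodes)
  y[1] <- spec$base_y - spec$hypocotyl_mm / spec$mm_per_px
  for (i in seq_len(spec$n_nodes - 1)) {
    y[i + 1] <- y[i] - l_mm[i] / spec$mm_per_px
  }
  x <- stem_center_x(spec, y)
  data.frame(order = seq_len(spec$n_nodes), x = x, y = y,
             visible = t >= spec$appearance_times)
}

# Stem centreline x as a function of y (pixels).
#' @noRd
stem_center_x <- function(spec, y) {
  dy <- spec$base_y - y
  spec$base_x + spec$stem_tilt * dy + spec$curvature * dy^2 / 1000
}

# Squared distance from grid points to a segment P-Q.
#' @noRd
segment_dist2 <- function(xg, yg, p, q) {
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  len2 <- vx^2 + vy^2
  tt <- ((xg - p[1]) * vx + (yg - p[2]) * vy) / max(len2, 1e-9)
  tt <- clamp(tt, 0, 1)
  (xg - (p[1] + tt * vx))^2 + (yg - (p[2] + tt * vy))^2
}

#' Render a synthetic seedling sequence with ground truth
#'
#' Draws, for every capture time, a tilted stem band whose node
#' positions follow the configured linear internode growth, a petiole
#' and a textured leaf blob per visible node, and a small textured
#' collar at each junction; adds Gaussian pixel noise. Deterministic
#' given `spec$seed`.
#'
#' @param spec A `"seedling_spec"`.
#' @return List with `frames` (list of `H x W x 3` arrays in \[0,1\]),
#'   `timestamps`, and `gt`: `class_maps` (list of integer matrices,
#'   levels background/stem/leaf), `nodes` (list of per-frame node
#'   data frames), `rects` (list of per-frame rectangle data frames
#'   with `x_min`, `y_min`, `width`, `height`, `order`), and
#'   `internode_mm` (frames x pairs matrix of exact lengths).
#' @export
render_sequence <- function(spec) {
  stopifnot(inherits(spec, "seedling_spec"))
  h <- spec$height; w <- spec$width
  set.seed(spec$seed)
  # annotation rectangle sizes, fixed per node for the whole sequence
  rw <- sample(seq(spec$rect_size_range[1], spec$rect_size_range[2]),
               spec$n_nodes, replace = TRUE)
  rh <- sample(seq(spec$rect_size_range[1], spec$rect_size_range[2]),
               spec$n_nodes, replace = TRUE)
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), w), h, w)
  leaf_tex <- spec$leaf_texture * sin(2 * pi * xg / 6.5) *
    sin(2 * pi * yg / 5.3)
  collar_tex <- spec$collar_texture *
    (((xg %/% 2 + yg %/% 2) %% 2) * 2 - 1)
  frames <- vector("list", length(spec$timestamps))
  class_maps <- vector("list", length(spec$timestamps))
  nodes_l <- vector("list", length(spec$timestamps))
  rects_l <- vector("list", length(spec$timestamps))
  n_pairs <- spec$n_nodes - 1
  internode_mm <- matrix(NA_real_, length(spec$timestamps), n_pairs)
  for (fi in seq_along(spec$timestamps)) {
    t <- spec$timestamps[fi]
    np <- node_positions(spec, t)
    vis <- np[np$visible, , drop = FALSE]
    if (nrow(vis) == 0) stop("no visible nodes at frame ", fi, call. = FALSE)
    y_top <- min(vis$y) - 25
    if (y_top < 5) stop("spec outgrows canvas", call. = FALSE)
    cx <- stem_center_x(spec, yg)
    stem <- yg <= spec$base_y & yg >= y_top &
      abs(xg - cx) <= spec$stem_width / 2
    leaf <- matrix(FALSE, h, w)
    collar <- matrix(FALSE, h, w)
    for (ri in seq_len(nrow(vis))) {
      p <- c(vis$x[ri], vis$y[ri])
      side <- if (vis$order[ri] %% 2 == 1) 1 else -1
      q <- p + c(side * 38, -10)
      stem <- stem | segment_dist2(xg, yg, p, q) <= 2.5^2
      lc <- q + c(side * 12, -4)
      leaf <- leaf | ((xg - lc[1]) / spec$leaf_axes[1])^2 +
        ((yg - lc[2]) / spec$leaf_axes[2])^2 <= 1
      collar <- collar | (xg - p[1])^2 + (yg - p[2])^2 <=
        spec$collar_radius^2
    }
    leaf <- leaf & !stem & !collar
    cm <- matrix(1L, h, w)
    cm[leaf] <- 3L
    cm[stem | collar] <- 2L
    attr(cm, "levels") <- c("background", "stem", "leaf")
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$colors$background[ch], h, w)
      plane[leaf] <- spec$colors$leaf[ch] + leaf_tex[leaf]
      plane[stem | collar] <- spec$colors$stem[ch]
      plane[collar] <- spec$colors$stem[ch] + collar_tex[collar]
      plane <- plane + matrix(stats::rnorm(h * w, 0, spec$colors$sigma), h, w)
      img[, , ch] <- clamp(plane, 0, 1)
    }
    frames[[fi]] <- img
    class_maps[[fi]] <- cm
    nodes_l[[fi]] <- vis[, c("order", "x", "y")]
    rects_l[[fi]] <- data.frame(
      x_min = pmax(0, round(vis$x - rw[vis$order] / 2)),
      y_min = pmax(0, round(vis$y - rh[vis$order] / 2)),
      width = rw[vis$order], height = rh[vis$order],
      order = vis$order)
    days <- (t - spec$timestamps[1]) / 86400
    internode_mm[fi, ] <- spec$initial_internodes_mm +
      spec$elongation_mm_day * days
  }
  list(frames = frames, timestamps = spec$timestamps,
       gt = list(class_maps = class_maps, nodes = nodes_l,
                 rects = rects_l, internode_mm = internode_mm),
       spec = spec)
}

#' Stratified pixel training sample from a rendered sequence
#'
#' Samples labelled pixels uniformly over all frames, stratified by
#' class, and computes their colour features.
#'
#' @param sequence Result of [render_sequence()].
#' @param counts Named integer vector of samples per class (defaults
#'   25000 stem, 5000 leaf, 25000 background).
#' @param seed Integer seed.
#' @return List with `features` (n x 15 matrix) and `labels`.
#' @export
make_pixel_training_set <- function(sequence,
                                    counts = c(stem = 25000, leaf = 5000,
                                               background = 25000),
                                    seed = 1L) {
  set.seed(seed)
  n_frames <- length(sequence$frames)
  h <- dim(sequence$frames[[1]])[1]
  feats <- list(); labs <- list()
  for (cls in names(counts)) {
    code <- match(cls, c("background", "stem", "leaf"))
    # pool of (frame, linear index) pairs for this class
    pool <- lapply(seq_len(n_frames), function(fi) {
      which(sequence$gt$class_maps[[fi]] == code)
    })
    sizes <- lengths(pool)
    if (sum(sizes) == 0) stop("class absent from sequence: ", cls,
                              call. = FALSE)
    take <- min(counts[[cls]], sum(sizes))
    sel <- sample.int(sum(sizes), take)
    cum <- cumsum(sizes)
    fidx <- findInterval(sel - 1, c(0, cum[-length(cum)]))
    rgb <- matrix(0, take, 3)
    for (fi in unique(fidx)) {
      rows <- which(fidx == fi)
      lin <- pool[[fi]][sel[rows] - c(0, cum)[fi]]
      frame <- sequence$frames[[fi]]
      npx <- h * dim(frame)[2]
      rgb[rows, ] <- cbind(frame[lin], frame[lin + npx],
                           frame[lin + 2 * npx]) * 255
    }
    feats[[cls]] <- color_features(rgb)
    labs[[cls]] <- rep(cls, take)
  }
  list(features = do.call(rbind, feats), labels = unlist(labs, use.names = FALSE))
}

#' Labelled 40 x 40 patch training set from a rendered sequence
#'
#' Node patches are centred on ground-truth node centres with up to
#' 3 px of jitter; non-node patches are sampled on leaf and bare-stem
#' pixels at least `min_dist` px from any node centre.
#'
#' @param sequence Result of [render_sequence()].
#' @param n_node,n_non_node Number of patches per class (defaults 200
#'   and 250).
#' @param patch_size Patch side length (default 40).
#' @param min_dist Minimum distance of non-node patch centres from any
#'   node centre (default 30 px).
#' @param seed Integer seed.
#' @return List with `patches` (list of matrices), `labels`, `centers`
#'   (data frame `frame`, `x`, `y`).
#' @export
make_patch_training_set <- function(sequence, n_node = 200,
                                    n_non_node = 250, patch_size = 40,
                                    min_dist = 30, seed = 1L) {
  set.seed(seed)
  n_frames <- length(sequence$frames)
  h <- dim(sequence$frames[[1]])[1]
  w <- dim(sequence$frames[[1]])[2]
  grays <- lapply(sequence$frames, to_gray)
  patches <- list(); labels <- character(0)
  centers <- list()
  # node patches: cycle frames and nodes
  combos <- do.call(rbind, lapply(seq_len(n_frames), function(fi) {
    cbind(fi, seq_len(nrow(sequence$gt$nodes[[fi]])))
  }))
  if (nrow(combos) == 0) stop("no ground-truth nodes available", call. = FALSE)
  pick <- combos[sample.int(nrow(combos), n_node, replace = TRUE), ,
                 drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    fi <- pick[r, 1]
    nd <- sequence$gt$nodes[[fi]][pick[r, 2], ]
    cx <- clamp(round(nd$x) + sample(-3:3, 1), 0, w - 1)
    cy <- clamp(round(nd$y) + sample(-3:3, 1), 0, h - 1)
    patches[[length(patches) + 1L]] <-
      extract_patch(grays[[fi]], c(cx, cy), patch_size)
    labels <- c(labels, "node")
    centers[[length(centers) + 1L]] <- c(fi, cx, cy)
  }
  # non-node patches on leaves and bare stem
  got <- 0L; tries <- 0L
  while (got < n_non_node) {
    tries <- tries + 1L
    if (tries > 50L * n_non_node) {
      stop("could not find enough non-node patch locations", call. = FALSE)
    }
    fi <- sample.int(n_frames, 1)
    cmap <- sequence$gt$class_maps[[fi]]
    pool <- which(cmap != 1L)
    lin <- pool[sample.int(length(pool), 1)]
    cy <- (lin - 1L) %% h
    cx <- (lin - 1L) %/% h
    nd <- sequence$gt$nodes[[fi]]
    if (min(sqrt((nd$x - cx)^2 + (nd$y - cy)^2)) < min_dist) next
    patches[[length(patches) + 1L]] <-
      extract_patch(grays[[fi]], c(cx, cy), patch_size)
    labels <- c(labels, "non_node")
    centers[[length(centers) + 1L]] <- c(fi, cx, cy)
    got <- got + 1L
  }
  centers <- as.data.frame(do.call(rbind, centers))
  names(centers) <- c("frame", "x", "y")
  list(patches = patches, labels = labels, centers = centers)
}

#' Simulate node detection sets (no images)
#'
#' Generates time-series detections from parallel y-tracks with
#' Gaussian within-track scatter, optional linear drift (growth) and
#' optional uniform false positives between tracks -- the input regime
#' of the node-order clustering stage.
#'
#' @param n_tracks Number of node tracks (clusters).
#' @param n_frames Number of capture times (default 40).
#' @param y_base y of the lowest track at the first time (default 430).
#' @param gap_px Vertical gap between adjacent tracks (default 60).
#' @param spread_px Within-track Gaussian scatter (default 3).
#' @param drift_px Total upward drift of each track over the series
#'   (default 10).
#' @param detect_rate Probability a node is detected in a frame
#'   (default 0.9).
#' @param fp_rate Expected number of false positives per frame,
#'   uniform between the outer tracks (default 0).
#' @param seed Integer seed.
#' @return Data frame with `t`, `y`, `track` (0 = false positive).
#' @export
simulate_detections <- function(n_tracks, n_frames = 40, y_base = 430,
                                gap_px = 60, spread_px = 3, drift_px = 10,
                                detect_rate = 0.9, fp_rate = 0, seed = 1L) {
  set.seed(seed)
  tt <- 1404158400 + (seq_len(n_frames) - 1) * (86400 / 5)
  rows <- list()
  for (k in seq_len(n_tracks)) {
    y0 <- y_base - (k - 1) * gap_px
    present <- stats::runif(n_frames) < detect_rate
    drift <- drift_px * (seq_len(n_frames) - 1) / max(n_frames - 1, 1)
    y <- y0 - drift + stats::rnorm(n_frames, 0, spread_px)
    rows[[k]] <- data.frame(t = tt[present], y = y[present], track = k)
  }
  if (fp_rate > 0) {
    nfp <- stats::rpois(1, fp_rate * n_frames)
    if (nfp > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        t = sample(tt, nfp, replace = TRUE),
        y = stats::runif(nfp, y_base - (n_tracks - 1) * gap_px, y_base),
        track = 0L)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$t, out$y), , drop = FALSE]
}
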