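# Bag-of-visual-words patch classification: 40 x 40 patches around
# surviving candidates are described by SIFT-style descriptors at Harris
# corners, quantised against a k-means vocabulary (k = 10) and classified
# node / non-node by a random forest. A patch with no keypoints is a
# non-node by rule, without consulting the classifier.

#' Extract a square patch centred on a pixel
#'
#' @param gray Numeric matrix (grayscale image in \[0,1\]).
#' @param center Length-2 vector `c(x, y)`, 0-based; must lie inside the
#'   image.
#' @param size Patch side length in pixels (default 40). The centre pixel
#'   sits at offset `size/2` (0-based) in the patch.
#' @return `size x size` numeric matrix; regions outside the image are
#'   filled by replicating the nearest edge pixel.
#' @export
extract_patch <- function(gray, center, size = 40) {
  h <- nrow(gray); w <- ncol(gray)
  x <- center[1]; y <- center[2]
  if (x < 0 || y < 0 || x > w - 1 || y > h - 1) {
    stop("patch center outside image", call. = FALSE)
  }
  half_lo <- size %/% 2L - 1L + (size %% 2L)  # 19 for even size 40
  rows <- clamp((y + 1L) + (-half_lo):(size - 1L - half_lo), 1L, h)
  cols <- clamp((x + 1L) + (-half_lo):(size - 1L - half_lo), 1L, w)
  gray[rows, cols, drop = FALSE]
}

#' Harris corner keypoints
#'
#' Sobel gradients (aperture 3), structure tensor averaged over a
#' 2 x 2 block, response `det - k * trace^2` with k = 0.04. Keypoints are
#' positive local maxima (3 x 3 neighbourhood) whose response exceeds
#' `rel_threshold` times the maximum response in the patch; a 2-pixel
#' border is excluded.
#'
#' @param patch Numeric grayscale matrix.
#' @param k Harris sensitivity constant (default 0.04).
#' @param rel_threshold Relative response threshold (default 0.01).
#' @return Data frame with 0-based `x`, `y` and `response`, ordered by
#'   decreasing response. May have zero rows.
#' @export
harris_keypoints <- function(patch, k = 0.04, rel_threshold = 0.01) {
  sob_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ix <- conv3x3_replicate(patch, sob_x)
  iy <- conv3x3_replicate(patch, t(sob_x))
  # 2 x 2 block sum of the tensor entries (offsets 0..1)
  box2 <- function(m) {
    m + shift_mat(m, 1L, 0L) + shift_mat(m, 0L, 1L) + shift_mat(m, 1L, 1L)
  }
  sxx <- box2(ix * ix); syy <- box2(iy * iy); sxy <- box2(ix * iy)
  resp <- (sxx * syy - sxy * sxy) - k * (sxx + syy)^2
  mx <- max(resp)
  empty <- data.frame(x = integer(0), y = integer(0), response = numeric(0))
  if (mx <= 0) return(empty)
  is_max <- resp > rel_threshold * mx
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & resp >= shift_mat(resp, dr, dc, fill = -Inf)
  }
  # exclude the border affected by padding
  is_max[c(1:2, nrow(resp) - 1:0), ] <- FALSE
  is_max[, c(1:2, ncol(resp) - 1:0)] <- FALSE
  if (!any(is_max)) return(empty)
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L,
                    response = resp[is_max])
  out[order(-out$response, out$y, out$x), , drop = FALSE]
}

#' SIFT-style descriptors at given keypoints
#'
#' Describes a 16 x 16 pixel region around each keypoint at a fixed
#' scale (4-pixel histogram cells) and fixed orientation 0: gradient
#' magnitudes, Gaussian-weighted (sigma = 8), are accumulated into a
#' 4 x 4 grid of 8-bin orientation histograms, giving 128 dimensions.
#' The vector is L2-normalised, clipped at 0.2 and renormalised, as in
#' the standard SIFT descriptor. There is no scale-space detection:
#' keypoints come from the Harris detector.
#'
#' @param patch Numeric grayscale matrix.
#' @param keypoints Data frame with 0-based `x`, `y` inside the patch.
#' @return Numeric matrix `n x 128` (0 rows if no keypoints).
#' @export
sift_descriptors <- function(patch, keypoints) {
  if (NROW(keypoints) == 0) return(matrix(numeric(0), 0, 128))
  h <- nrow(patch); w <- ncol(patch)
  pad <- 9L
  rows <- clamp((1 - pad):(h + pad), 1L, h)
  cols <- clamp((1 - pad):(w + pad), 1L, w)
  pp <- patch[rows, cols]
  # central-difference gradients on the padded patch
  gx <- (shift_mat(pp, 0L, 1L) - shift_mat(pp, 0L, -1L)) / 2
  gy <- (shift_mat(pp, 1L, 0L) - shift_mat(pp, -1L, 0L)) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  obin <- pmin(floor(ang / (pi / 4)), 7)

  offs <- -8:7
  grid <- expand.grid(dy = offs, dx = offs)
  cell <- 4L * (grid$dx %/% 4L + 2L) + (grid$dy %/% 4L + 2L)  # 0..15
  wgt <- exp(-(grid$dx + 0.5)^2 / (2 * 64) - (grid$dy + 0.5)^2 / (2 * 64))

  out <- matrix(0, NROW(keypoints), 128)
  for (i in seq_len(NROW(keypoints))) {
    r0 <- keypoints$y[i] + 1L + pad
    c0 <- keypoints$x[i] + 1L + pad
    ridx <- r0 + grid$dy
    cidx <- c0 + grid$dx
    lin <- (cidx - 1L) * nrow(pp) + ridx
    contrib <- mag[lin] * wgt
    bin <- cell * 8L + obin[lin] + 1L      # 1..128
    v <- numeric(128)
    acc <- tapply(contrib, bin, sum)
    v[as.integer(names(acc))] <- acc
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      v <- pmin(v / nv, 0.2)
      nv2 <- sqrt(sum(v^2))
      if (nv2 > 0) v <- v / nv2
    }
    out[i, ] <- v
  }
  out
}

#' Descriptors for all Harris keypoints of a patch
#'
#' @param patch Numeric grayscale matrix.
#' @return List with `keypoints` (data frame) and `descriptors`
#'   (`n x 128` matrix).
#' @export
describe_patch <- function(patch) {
  kps <- harris_keypoints(patch)
  list(keypoints = kps, descriptors = sift_descriptors(patch, kps))
}

# k-means++ seeding.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- pool[sample.int(length(pool), 1L)]
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' Build a visual vocabulary by k-means
#'
#' k-means with k-means++ initialisation and multiple restarts; the run
#' with the lowest total within-cluster sum of squares wins.
#'
#' @param descriptors Numeric matrix `n x 128`, n >= k.
#' @param k Number of visual words (default 10).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @return Object of class `"bovw_vocab"`: list with `centers`
#'   (`k x 128`), `inertia`, `k`, `seed`.
#' @export
build_vocabulary <- function(descriptors, k = 10, seed = 1L, restarts = 10) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < k) {
    stop(sprintf("need at least k = %d descriptors, got %d", k,
                 nrow(descriptors)), call. = FALSE)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(descriptors, k)
    # duplicate descriptors can collapse initial centres; jitter-free
    # fallback: keep distinct rows only and fail over to another draw
    if (nrow(unique(init)) < k) next
    km <- suppressWarnings(
      stats::kmeans(descriptors, centers = init, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed: fewer than k distinct descriptors",
                          call. = FALSE)
  structure(list(centers = unname(best$centers), inertia = best$tot.withinss,
                 k = k, seed = seed),
            class = "bovw_vocab")
}

#' Encode descriptors as an L1-normalised visual-word histogram
#'
#' Each descriptor is assigned to its nearest centroid (Euclidean; ties
#' go to the lowest centroid index) and counts are L1-normalised. With
#' no descriptors the histogram is all zeros and `empty` is `TRUE` --
#' the hook for the rule that featureless patches are non-nodes.
#'
#' @param descriptors Numeric matrix `n x 128` (n may be 0).
#' @param vocab A `"bovw_vocab"`.
#' @return List with `hist` (length-k numeric) and `empty` (logical).
#' @export
encode_histogram <- function(descriptors, vocab) {
  stopifnot(inherits(vocab, "bovw_vocab"))
  k <- vocab$k
  if (NROW(descriptors) == 0) {
    return(list(hist = numeric(k), empty = TRUE))
  }
  descriptors <- as.matrix(descriptors)
  d2 <- outer(rowSums(descriptors^2), rep(1, k)) -
    2 * descriptors %*% t(vocab$centers) +
    outer(rep(1, nrow(descriptors)), rowSums(vocab$centers^2))
  assign <- max.col(-d2, ties.method = "first")
  counts <- tabulate(assign, nbins = k)
  list(hist = counts / sum(counts), empty = FALSE)
}

#' Train the node / non-node patch classifier
#'
#' Random forest on visual-word histograms. The out-of-bag error of the
#' fit is stored on the returned object.
#'
#' @param histograms Numeric matrix `n x k` of word histograms.
#' @param labels Character/factor vector with values `"node"` /
#'   `"non_node"`; both classes must be present.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Object of class `"patch_classifier"`.
#' @export
train_patch_classifier <- function(histograms, labels, n_trees = 500,
                                   seed = 1L) {
  histograms <- as.matrix(histograms)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("node", "non_node")),
            nrow(histograms) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train the patch classifier",
         call. = FALSE)
  }
  colnames(histograms) <- paste0("w", seq_len(ncol(histograms)))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = histograms, y = factor(labels, levels = c("node", "non_node")),
    ntree = n_trees)
  oob <- 1 - fit$err.rate[n_trees, "OOB"]
  structure(list(fit = fit, oob_accuracy = unname(oob), seed = seed),
            class = "patch_classifier")
}

#' @export
predict.patch_classifier <- function(object, histograms, ...) {
  histograms <- as.matrix(histograms)
  colnames(histograms) <- paste0("w", seq_len(ncol(histograms)))
  as.character(predict(object$fit, newdata = histograms))
}

#' Classify surviving candidates as node or non-node
#'
#' For every `"active"` candidate: extract the 40 x 40 patch centred on
#' it, detect Harris keypoints, describe them, encode the histogram and
#' consult the classifier. A patch with no keypoints is a non-node
#' without consulting the classifier. Accepted candidates get status
#' `"accepted"` (the detection location is the candidate pixel itself);
#' rejected ones get `"removed_bovw"`.
#'
#' @param gray Grayscale image matrix in \[0,1\].
#' @param cands Candidate data frame.
#' @param vocab A `"bovw_vocab"`.
#' @param classifier A `"patch_classifier"`.
#' @param patch_size Patch side length (default 40).
#' @return Candidate data frame with final statuses.
#' @export
classify_candidates <- function(gray, cands, vocab, classifier,
                                patch_size = 40) {
  if (nrow(cands) == 0) return(cands)
  for (i in which(cands$status == "active")) {
    patch <- extract_patch(gray, c(cands$x[i], cands$y[i]), patch_size)
    desc <- describe_patch(patch)
    enc <- encode_histogram(desc$descriptors, vocab)
    if (enc$empty) {
      cands$status[i] <- "removed_bovw"
      cands$reason[i] <- "no keypoints in patch"
      next
    }
    cls <- predict(classifier, matrix(enc$hist, 1))
    if (cls == "node") {
      cands$status[i] <- "accepted"
      cands$reason[i] <- "classified node"
    } else {
      cands$status[i] <- "removed_bovw"
      cands$reason[i] <- "classified non-node"
    }
  }
  cands
}
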