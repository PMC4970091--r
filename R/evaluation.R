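# Detection and length-estimation metrics: one-to-one detection/ground
# truth matching, recall, precision, relative error, and the
# leave-one-seedling-out protocol.

#' Match detections against ground-truth node rectangles
#'
#' A detection is a true positive if its centre lies inside an
#' as-yet-unmatched ground-truth rectangle (boundary inclusive).
#' Matching is greedy one-to-one by centre-to-centre distance, so two
#' detections inside one rectangle yield one TP and one FP. Leftover
#' detections are false positives; leftover rectangles false negatives.
#'
#' @param dets Data frame of detections with columns `x`, `y`.
#' @param gts Data frame of rectangles with columns `x_min`, `y_min`,
#'   `width`, `height` (and optionally `order`).
#' @return Object of class `"confusion"`: list with `tp`, `fp`, `fn`,
#'   plus `det_matched` / `gt_matched` (index of the partner, NA if
#'   unmatched).
#' @export
match_detections <- function(dets, gts) {
  nd <- NROW(dets); ng <- NROW(gts)
  det_matched <- rep(NA_integer_, nd)
  gt_matched <- rep(NA_integer_, ng)
  if (nd > 0 && ng > 0) {
    cx <- gts$x_min + gts$width / 2
    cy <- gts$y_min + gts$height / 2
    cand <- list()
    for (d in seq_len(nd)) {
      inside <- dets$x[d] >= gts$x_min & dets$x[d] <= gts$x_min + gts$width &
        dets$y[d] >= gts$y_min & dets$y[d] <= gts$y_min + gts$height
      for (g in which(inside)) {
        dist <- sqrt((dets$x[d] - cx[g])^2 + (dets$y[d] - cy[g])^2)
        cand[[length(cand) + 1L]] <- c(d = d, g = g, dist = dist)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, "dist"]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        d <- cand[r, "d"]; g <- cand[r, "g"]
        if (is.na(det_matched[d]) && is.na(gt_matched[g])) {
          det_matched[d] <- g
          gt_matched[g] <- d
        }
      }
    }
  }
  tp <- sum(!is.na(det_matched))
  structure(list(tp = tp, fp = nd - tp, fn = ng - tp,
                 det_matched = det_matched, gt_matched = gt_matched),
            class = "confusion")
}

#' Combine confusion counts
#'
#' @param ... `"confusion"` objects.
#' @return A `"confusion"` object with summed counts (match indices
#'   dropped).
#' @export
combine_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) && !inherits(cs[[1]], "confusion")) {
    cs <- cs[[1]]
  }
  structure(list(tp = sum(vapply(cs, `[[`, 0, "tp")),
                 fp = sum(vapply(cs, `[[`, 0, "fp")),
                 fn = sum(vapply(cs, `[[`, 0, "fn")),
                 det_matched = NULL, gt_matched = NULL),
            class = "confusion")
}

#' Recall: TP / (TP + FN)
#'
#' @param conf A `"confusion"` object.
#' @return Fraction in \[0,1\].
#' @export
recall <- function(conf) {
  if (conf$tp + conf$fn == 0) {
    stop("recall undefined: no ground-truth nodes", call. = FALSE)
  }
  conf$tp / (conf$tp + conf$fn)
}

#' Precision: TP / (TP + FP)
#'
#' @param conf A `"confusion"` object.
#' @return Fraction in \[0,1\].
#' @export
precision <- function(conf) {
  if (conf$tp + conf$fp == 0) {
    stop("precision undefined: no detections", call. = FALSE)
  }
  conf$tp / (conf$tp + conf$fp)
}

#' Relative error of an internode length series (percent)
#'
#' `|sum(predicted) - sum(observed)| / sum(observed) * 100`. Because the
#' ratio of sums equals the ratio of means when both series have the
#' same length, mean lengths are equally valid inputs.
#'
#' @param observed Numeric vector of observed lengths (mm).
#' @param predicted Numeric vector of predicted lengths (mm), same
#'   length.
#' @return Percentage >= 0.
#' @export
relative_error <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  so <- sum(observed)
  if (so <= 0) stop("relative error undefined: observed sum is not positive",
                    call. = FALSE)
  abs(sum(predicted) - so) / so * 100
}

#' Leave-one-seedling-out cross validation
#'
#' For each fold, the segmentation tree and the patch classifier are
#' trained on one seedling's sequence and evaluated on all the others,
#' so with three seedlings each is tested exactly twice. Detection
#' metrics are aggregated per node order and overall; internode length
#' estimates are compared with ground truth by relative error.
#'
#' @param seedlings List of seedling sequences, each as returned by
#'   [render_sequence()] (elements `frames`, `timestamps`, `gt`).
#' @param config Pipeline configuration from [pipeline_config()].
#' @return List with `detection` (data frame: `fold`, `test_seedling`,
#'   `node_order`, `recall`, `precision`, `n_nodes`), `internode`
#'   (data frame: `fold`, `test_seedling`, `pair`, `observed_mm`,
#'   `estimated_mm`, `relative_error`), and `overall` (list with pooled
#'   `recall`, `precision`, `max_relative_error`, `mean_relative_error`).
#' @export
leave_one_seedling_out <- function(seedlings, config = pipeline_config()) {
  if (length(seedlings) < 2L) stop("need at least two seedlings",
                                   call. = FALSE)
  names(seedlings) <- names(seedlings) %||%
    LETTERS[seq_along(seedlings)]
  det_rows <- list(); int_rows <- list()
  pooled <- list()
  for (f in seq_along(seedlings)) {
    train <- seedlings[[f]]
    models <- train_pipeline(train, config)
    for (s in setdiff(seq_along(seedlings), f)) {
      test <- seedlings[[s]]
      det <- run_detection(models, test, config)
      ev <- evaluate_detection(det$detections, test$gt)
      ev$per_order$fold <- names(seedlings)[f]
      ev$per_order$test_seedling <- names(seedlings)[s]
      det_rows[[length(det_rows) + 1L]] <- ev$per_order
      pooled[[length(pooled) + 1L]] <- ev$overall
      trk <- run_tracking_and_measurement(det$detections, config)
      cmp <- compare_internodes(trk, test, config)
      if (nrow(cmp)) {
        cmp$fold <- names(seedlings)[f]
        cmp$test_seedling <- names(seedlings)[s]
        int_rows[[length(int_rows) + 1L]] <- cmp
      }
    }
  }
  detection <- do.call(rbind, det_rows)
  internode <- if (length(int_rows)) do.call(rbind, int_rows) else
    data.frame()
  total <- combine_confusion(pooled)
  list(detection = detection, internode = internode,
       overall = list(
         recall = recall(total), precision = precision(total),
         tp = total$tp, fp = total$fp, fn = total$fn,
         max_relative_error = if (nrow(internode))
           max(internode$relative_error) else NA_real_,
         mean_relative_error = if (nrow(internode))
           mean(internode$relative_error) else NA_real_))
}

#' Per-frame detection evaluation against ground-truth rectangles
#'
#' @param detections Data frame with `frame_id`, `x`, `y`.
#' @param gt Ground truth as produced by [render_sequence()] (uses
#'   `gt$rects`, a list of per-frame rectangle data frames with an
#'   `order` column).
#' @return List with `per_order` (data frame: `node_order` including
#'   `"All"`, `recall`, `precision`, `n_nodes`) and `overall` (a
#'   `"confusion"`).
#' @export
evaluate_detection <- function(detections, gt) {
  confs <- list()
  order_tp <- list(); order_n <- list()
  for (fi in seq_along(gt$rects)) {
    rects <- gt$rects[[fi]]
    dets <- detections[detections$frame_id == fi, , drop = FALSE]
    m <- match_detections(dets, rects)
    confs[[fi]] <- m
    for (o in unique(rects$order)) {
      sel <- which(rects$order == o)
      key <- as.character(o)
      order_tp[[key]] <- (order_tp[[key]] %||% 0) +
        sum(!is.na(m$gt_matched[sel]))
      order_n[[key]] <- (order_n[[key]] %||% 0) + length(sel)
    }
  }
  total <- combine_confusion(confs)
  orders <- sort(as.integer(names(order_n)))
  per_order <- data.frame(
    node_order = c(as.character(orders), "All"),
    recall = c(vapply(as.character(orders),
                      function(k) order_tp[[k]] / order_n[[k]], 0),
               recall(total)),
    precision = c(rep(NA_real_, length(orders)), precision(total)),
    n_nodes = c(vapply(as.character(orders),
                       function(k) order_n[[k]], 0), total$tp + total$fn),
    row.names = NULL)
  list(per_order = per_order, overall = total)
}

#' Compare estimated internode lengths with ground truth
#'
#' Ground-truth lengths are averaged over the same capture times used by
#' the estimate for each pair, then compared by [relative_error()].
#' Estimated node orders are aligned to ground-truth orders by cluster
#' mean y, i.e. pair "1-2" is compared with the ground-truth pair
#' "1-2".
#'
#' @param tracking Result of [run_tracking_and_measurement()].
#' @param seedling A rendered sequence (for `gt$internode_mm` and
#'   `timestamps`).
#' @param config Pipeline configuration.
#' @return Data frame: `pair`, `observed_mm`, `estimated_mm`,
#'   `relative_error`.
#' @export
compare_internodes <- function(tracking, seedling,
                               config = pipeline_config()) {
  est <- tracking$internode$series
  if (is.null(est) || nrow(est) == 0) return(data.frame())
  gt_mm <- seedling$gt$internode_mm   # frames x pairs matrix
  ts <- seedling$timestamps
  rows <- list()
  for (p in unique(est$pair)) {
    i <- as.integer(sub("-.*", "", p))
    if (i > ncol(gt_mm)) next
    sub <- est[est$pair == p, , drop = FALSE]
    fidx <- match(round(sub$timestamp), round(ts))
    if (anyNA(fidx)) next
    obs <- gt_mm[fidx, i]
    rows[[length(rows) + 1L]] <- data.frame(
      pair = p, observed_mm = mean(obs), estimated_mm = mean(sub$length_mm),
      relative_error = relative_error(obs, sub$length_mm))
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
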