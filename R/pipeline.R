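# Pipeline orchestration: train models, run per-frame node detection
# (segmentation -> thinning -> branch points -> main-stem filter ->
# BoVW), then track node orders over time and measure internodes.

#' Pipeline configuration
#'
#' All stage parameters in one place. Defaults are the method's
#' operating values: 50 px main-stem distance threshold, k = 10 visual
#' words, damping 0.5, 0.41 mm/pixel, 40 x 40 patches.
#'
#' @param seg_max_depth,seg_min_leaf Segmentation tree depth cap and
#'   minimum leaf size.
#' @param pixel_counts Training pixels per class for the segmentation
#'   tree.
#' @param patch_size Patch side length (px).
#' @param n_node_patches,n_non_node_patches Training patch counts.
#' @param k Visual vocabulary size.
#' @param n_trees Random-forest size.
#' @param mainstem_threshold Distance threshold from the main-stem line
#'   (px).
#' @param mainstem_filter,bovw_filter Logical stage toggles (both
#'   `TRUE`; disabling both reproduces the raw-candidate condition).
#' @param damping,preference,max_iter,conv_window Affinity-propagation
#'   controls (`preference = NULL` means the median similarity).
#' @param mm_per_px Scale calibration.
#' @param seed Integer seed used for every stochastic stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seg_max_depth = 10, seg_min_leaf = 5,
                            pixel_counts = c(stem = 25000, leaf = 5000,
                                             background = 25000),
                            patch_size = 40,
                            n_node_patches = 200, n_non_node_patches = 250,
                            k = 10, n_trees = 500,
                            mainstem_threshold = 50,
                            mainstem_filter = TRUE, bovw_filter = TRUE,
                            damping = 0.5, preference = NULL,
                            max_iter = 1000, conv_window = 100,
                            mm_per_px = 0.41, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Train segmentation and patch-classification models on one sequence
#'
#' Builds the pixel training sample and the patch training sample from
#' the sequence's ground truth, fits the segmentation tree, the visual
#' vocabulary and the patch classifier. Training patches without
#' keypoints are dropped (at test time such patches are non-nodes by
#' rule).
#'
#' @param sequence Result of [render_sequence()] (or any object with
#'   `frames` and `gt` in the same layout).
#' @param config A [pipeline_config()].
#' @return List of class `"pipeline_models"`: `dtsm`, `vocab`,
#'   `classifier`.
#' @export
train_pipeline <- function(sequence, config = pipeline_config()) {
  px <- make_pixel_training_set(sequence, counts = config$pixel_counts,
                                seed = config$seed)
  dtsm <- train_dtsm(px$features, px$labels,
                     max_depth = config$seg_max_depth,
                     min_leaf = config$seg_min_leaf, seed = config$seed)
  ps <- make_patch_training_set(sequence, n_node = config$n_node_patches,
                                n_non_node = config$n_non_node_patches,
                                patch_size = config$patch_size,
                                seed = config$seed)
  descs <- list(); hists <- list(); labs <- character(0)
  per_patch <- lapply(ps$patches, describe_patch)
  all_desc <- do.call(rbind, lapply(per_patch, `[[`, "descriptors"))
  vocab <- build_vocabulary(all_desc, k = config$k, seed = config$seed)
  for (i in seq_along(per_patch)) {
    enc <- encode_histogram(per_patch[[i]]$descriptors, vocab)
    if (enc$empty) next
    hists[[length(hists) + 1L]] <- enc$hist
    labs <- c(labs, ps$labels[i])
  }
  classifier <- train_patch_classifier(do.call(rbind, hists), labs,
                                       n_trees = config$n_trees,
                                       seed = config$seed)
  structure(list(dtsm = dtsm, vocab = vocab, classifier = classifier),
            class = "pipeline_models")
}

#' Run node detection over an image sequence
#'
#' Per frame: pixel segmentation, stem mask, thinning, branch/cross
#' point candidates, main-stem distance filter, BoVW patch
#' classification. Frames whose stem mask is empty are skipped with a
#' warning. The per-stage candidate counts (the elimination funnel) are
#' logged per frame.
#'
#' @param models A `"pipeline_models"` from [train_pipeline()].
#' @param sequence List with `frames` (H x W x 3 arrays) and
#'   `timestamps`.
#' @param config A [pipeline_config()].
#' @return List with `detections` (data frame `frame_id`, `timestamp`,
#'   `x`, `y`), `funnel` (data frame `frame_id`, `n_candidates`,
#'   `n_after_mainstem`, `n_accepted`), `candidates` (per-frame
#'   candidate data frames with statuses and reasons).
#' @export
run_detection <- function(models, sequence, config = pipeline_config()) {
  stopifnot(inherits(models, "pipeline_models"))
  dets <- list(); funnel <- list(); cand_l <- list()
  for (fi in seq_along(sequence$frames)) {
    img <- sequence$frames[[fi]]
    ts <- sequence$timestamps[fi]
    cm <- segment_image(models$dtsm, img)
    mask <- stem_mask(cm)
    if (!any(mask)) {
      warning("frame ", fi, ": no stem pixels; skipped")
      next
    }
    skel <- skeletonize(mask)
    cands <- find_branch_points(skel)
    n0 <- nrow(cands)
    if (config$mainstem_filter && n0 > 0) {
      line <- tryCatch(fit_main_stem_line(select_main_component(mask)),
                       error = function(e) NULL)
      if (!is.null(line)) {
        cands <- filter_by_main_stem(cands, line,
                                     threshold = config$mainstem_threshold)
      }
    }
    n1 <- sum(cands$status == "active")
    if (config$bovw_filter && n1 > 0) {
      gray <- to_gray(img)
      cands <- classify_candidates(gray, cands, models$vocab,
                                   models$classifier,
                                   patch_size = config$patch_size)
    } else {
      act <- cands$status == "active"
      cands$status[act] <- "accepted"
      cands$reason[act] <- "bovw stage disabled"
    }
    acc <- cands[cands$status == "accepted", , drop = FALSE]
    if (nrow(acc)) {
      dets[[length(dets) + 1L]] <- data.frame(
        frame_id = fi, timestamp = ts, x = acc$x, y = acc$y)
    }
    funnel[[length(funnel) + 1L]] <- data.frame(
      frame_id = fi, n_candidates = n0, n_after_mainstem = n1,
      n_accepted = nrow(acc))
    cands$frame_id <- fi
    cand_l[[length(cand_l) + 1L]] <- cands
  }
  list(detections = if (length(dets)) do.call(rbind, dets) else
         data.frame(frame_id = integer(0), timestamp = numeric(0),
                    x = integer(0), y = integer(0)),
       funnel = do.call(rbind, funnel),
       candidates = cand_l)
}

#' Track node orders and measure internodes
#'
#' Clusters detections by y with affinity propagation, assigns node
#' orders (order 1 = largest mean y), fits per-order node lines against
#' capture time and derives the internode length series in mm.
#'
#' @param detections Data frame with `timestamp`, `x`, `y` (from
#'   [run_detection()] or a detections CSV).
#' @param config A [pipeline_config()].
#' @param capture_times Times at which internode lengths are evaluated
#'   (default: the sorted unique detection timestamps).
#' @return List with `clustering`, `lines` (a `"node_lines"` data
#'   frame), `tracks` (data frame `order`, `timestamp`, `y_fitted`),
#'   `internode` (list `series`, `summary`).
#' @export
run_tracking_and_measurement <- function(detections,
                                         config = pipeline_config(),
                                         capture_times = NULL) {
  stop_if_empty(detections, "no detections to track")
  detections <- detections[order(detections$timestamp, detections$y,
                                 detections$x), , drop = FALSE]
  nodes <- data.frame(t = detections$timestamp, y = detections$y)
  clustering <- cluster_by_y(nodes, damping = config$damping,
                             preference = config$preference,
                             max_iter = config$max_iter,
                             conv_window = config$conv_window)
  lines <- fit_node_lines(nodes, clustering)
  capture_times <- capture_times %||% sort(unique(detections$timestamp))
  tracks <- do.call(rbind, lapply(lines$order, function(o) {
    tt <- capture_times[capture_times >=
                          lines$appearance_time[lines$order == o]]
    if (!length(tt)) return(NULL)
    data.frame(order = o, timestamp = tt, y_fitted = node_y_at(lines, o, tt))
  }))
  internode <- suppressWarnings(
    internode_series(lines, capture_times, mm_per_px = config$mm_per_px))
  list(clustering = clustering, lines = lines, tracks = tracks,
       internode = internode)
}

#' Write per-frame candidate statuses to CSV
#'
#' One row per skeleton candidate with its final status
#' (`accepted` / `removed_mainstem` / `removed_bovw`) and reason --
#' the per-stage elimination record.
#'
#' @param detection Result of [run_detection()].
#' @param timestamps Capture times, parallel to the sequence frames.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_candidates_csv <- function(detection, timestamps, path) {
  cands <- do.call(rbind, detection$candidates)
  cands$timestamp <- timestamps[cands$frame_id]
  cands <- cands[, c("frame_id", "timestamp", "x", "y", "status", "reason")]
  utils::write.csv(cands, path, row.names = FALSE)
  invisible(path)
}

#' Write pipeline artifacts to disk
#'
#' Writes the detections, tracks and internode CSVs and the node-lines
#' JSON with fixed column order, so identical runs produce
#' byte-identical files.
#'
#' @param detections Data frame from [run_detection()].
#' @param tracking Result of [run_tracking_and_measurement()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(detections, tracking, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             tracks = file.path(dir, "tracks.csv"),
             internode = file.path(dir, "internode.csv"),
             internode_summary = file.path(dir, "internode_summary.csv"),
             node_lines = file.path(dir, "node_lines.json"))
  utils::write.csv(detections, paths["detections"], row.names = FALSE)
  utils::write.csv(tracking$tracks, paths["tracks"], row.names = FALSE)
  utils::write.csv(tracking$internode$series, paths["internode"],
                   row.names = FALSE)
  utils::write.csv(tracking$internode$summary, paths["internode_summary"],
                   row.names = FALSE)
  jsonlite::write_json(
    as.data.frame(tracking$lines), paths["node_lines"],
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
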