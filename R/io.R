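# Reading and writing sequences on disk: PNG frames plus a manifest CSV
# (frame_id, timestamp, path). Ground truth travels as JSON.

#' Write a rendered sequence to disk
#'
#' Emits one PNG per frame, a manifest CSV (`frame_id`, `timestamp`,
#' `path`) and, optionally, the ground truth as JSON (node centres,
#' rectangles and internode lengths; class maps are omitted from the
#' JSON for size and can be regenerated from the spec).
#'
#' @param sequence Result of [render_sequence()].
#' @param dir Output directory (created if absent).
#' @param ground_truth Write `ground_truth.json` as well (default TRUE).
#' @return Invisibly, the manifest path.
#' @export
write_sequence <- function(sequence, dir, ground_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(sequence$frames))
  for (fi in seq_along(sequence$frames)) {
    paths[fi] <- file.path(dir, sprintf("frame_%03d.png", fi))
    png::writePNG(sequence$frames[[fi]], paths[fi])
  }
  manifest <- data.frame(frame_id = seq_along(paths),
                         timestamp = sequence$timestamps,
                         path = basename(paths))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (ground_truth && !is.null(sequence$gt)) {
    gt <- list(
      nodes = lapply(sequence$gt$nodes, function(d) as.data.frame(d)),
      rects = lapply(sequence$gt$rects, function(d) as.data.frame(d)),
      internode_mm = sequence$gt$internode_mm)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(mpath)
}

#' Read an image sequence from a manifest
#'
#' @param manifest_path Path to a manifest CSV with columns `frame_id`,
#'   `timestamp`, `path` (paths relative to the manifest's directory or
#'   absolute).
#' @return List with `frames` (H x W x 3 arrays) and `timestamps`,
#'   ordered by `frame_id`.
#' @export
read_sequence <- function(manifest_path) {
  man <- utils::read.csv(manifest_path)
  stopifnot(all(c("frame_id", "timestamp", "path") %in% names(man)))
  man <- man[order(man$frame_id), , drop = FALSE]
  base <- dirname(manifest_path)
  frames <- lapply(man$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    img <- png::readPNG(full)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  list(frames = frames, timestamps = man$timestamp)
}

#' Bundled reference internode-length table
#'
#' Mean observed and estimated internode lengths (mm) per internode and
#' per seedling from a published glasshouse tomato-seedling imaging
#' study, used as worked examples for the relative-error metric.
#'
#' @return Data frame with columns `seedling`, `internode`,
#'   `observed_mm`, `estimated_mm`.
#' @export
reference_internode_means <- function() {
  utils::read.csv(system.file("extdata", "reference_internode_means.csv",
                              package = "phenonode"))
}
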