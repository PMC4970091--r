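# Internode length estimation from adjacent node lines, with pixel to
# millimetre conversion via a rig calibration factor (default
# 0.41 mm/pixel).

#' Internode length in pixels at a time point
#'
#' The y-axis distance between the node lines of orders `i` and `i + 1`:
#' `y_i(t) - y_{i+1}(t)`. Order `i` sits lower on the image (larger y),
#' so the value is expected positive; if the lines cross, a warning is
#' issued and the (negative) value is returned as-is.
#'
#' @param lines A `"node_lines"` data frame.
#' @param i Lower node order of the pair.
#' @param t Numeric vector of times (UNIX seconds); must not precede the
#'   appearance time of node `i + 1`.
#' @return Numeric vector of lengths in pixels.
#' @export
internode_length_px <- function(lines, i, t) {
  appear <- lines$appearance_time[lines$order == i + 1]
  if (length(appear) != 1L) stop("node lines ", i, " and ", i + 1,
                                 " not both present", call. = FALSE)
  if (any(t < appear)) {
    stop("internode ", i, "-", i + 1,
         " is undefined before node ", i + 1, " appeared", call. = FALSE)
  }
  len <- node_y_at(lines, i, t) - node_y_at(lines, i + 1, t)
  if (any(len < 0)) warning("node lines cross: negative internode length")
  len
}

#' Convert a pixel length to millimetres
#'
#' @param length_px Numeric vector of lengths in pixels.
#' @param mm_per_px Calibration factor (default 0.41 mm/pixel).
#' @return Numeric vector of lengths in mm.
#' @export
px_to_mm <- function(length_px, mm_per_px = 0.41) {
  stopifnot(is.numeric(mm_per_px), mm_per_px > 0)
  length_px * mm_per_px
}

#' Internode length series for all adjacent node pairs
#'
#' For each pair (i, i+1) of adjacent node orders, evaluates the
#' internode length at every capture time at or after the appearance of
#' node i+1, converts to millimetres, and summarises the mean length per
#' pair.
#'
#' @param lines A `"node_lines"` data frame with >= 2 rows.
#' @param capture_times Numeric vector of capture times (UNIX seconds).
#' @param mm_per_px Calibration factor (default 0.41).
#' @return List with `series` (data frame: `pair`, `timestamp`,
#'   `length_px`, `length_mm`) and `summary` (data frame: `pair`,
#'   `mean_mm`, `n_times`). Both empty (with a warning) if fewer than
#'   two node lines exist.
#' @export
internode_series <- function(lines, capture_times, mm_per_px = 0.41) {
  empty <- list(
    series = data.frame(pair = character(0), timestamp = numeric(0),
                        length_px = numeric(0), length_mm = numeric(0)),
    summary = data.frame(pair = character(0), mean_mm = numeric(0),
                         n_times = integer(0)))
  if (nrow(lines) < 2L) {
    warning("fewer than two node lines; no internodes to measure")
    return(empty)
  }
  orders <- sort(lines$order)
  out <- list()
  for (i in orders[-length(orders)]) {
    appear <- lines$appearance_time[lines$order == i + 1]
    tt <- capture_times[capture_times >= appear]
    if (!length(tt)) next
    px <- internode_length_px(lines, i, tt)
    out[[length(out) + 1L]] <- data.frame(
      pair = sprintf("%d-%d", i, i + 1), timestamp = tt,
      length_px = px, length_mm = px_to_mm(px, mm_per_px))
  }
  if (!length(out)) return(empty)
  series <- do.call(rbind, out)
  summary <- do.call(rbind, lapply(split(series, series$pair), function(d) {
    data.frame(pair = d$pair[1], mean_mm = mean(d$length_mm),
               n_times = nrow(d))
  }))
  summary <- summary[order(as.integer(sub("-.*", "", summary$pair))), ,
                     drop = FALSE]
  rownames(summary) <- NULL
  list(series = series, summary = summary)
}
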