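#' Select the connected stem component stretching furthest along y
#'
#' Among 8-connected foreground components, picks the one with the
#' largest bounding-box height (the main stem of a near-vertical
#' seedling); ties are broken by larger pixel area.
#'
#' @param mask Logical stem mask.
#' @return Logical mask containing only the selected component.
#' @export
select_main_component <- function(mask) {
  mask <- mask & TRUE
  if (!any(mask)) stop("no stem found", call. = FALSE)
  labs <- label_components(mask, connectivity = 8)
  ids <- sort(unique(labs[labs > 0L]))
  if (length(ids) == 1L) return(labs == ids)
  height <- area <- integer(length(ids))
  for (i in seq_along(ids)) {
    rows <- which(labs == ids[i], arr.ind = TRUE)[, 1]
    height[i] <- max(rows) - min(rows) + 1L
    area[i] <- length(rows)
  }
  best <- ids[order(-height, -area)[1]]
  labs == best
}

#' Fit the main-stem line
#'
#' Ordinary least squares of x on y over all foreground pixel centres:
#' `x(y) = slope * y + intercept`. Regressing x on y keeps the fit
#' well-defined for near-vertical stems. When x has zero variance
#' (a perfectly vertical strip) `r_squared` is defined as 1.
#'
#' @param component Logical mask of the main stem component.
#' @return Object of class `"main_stem_line"`: list with `slope`,
#'   `intercept` (pixels) and `r_squared`.
#' @export
fit_main_stem_line <- function(component) {
  idx <- which(component & TRUE, arr.ind = TRUE)
  stop_if_empty(idx, "no stem found")
  y <- idx[, 1] - 1
  x <- idx[, 2] - 1
  if (length(unique(y)) < 2L) {
    stop("stem component spans a single row; cannot fit x(y)", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, y), x)
  b <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
  ssr <- sum(fit$residuals^2)
  sst <- sum((x - mean(x))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(slope = a, intercept = b, r_squared = r2),
            class = "main_stem_line")
}

#' Predict the main-stem x position at given y
#'
#' @param line A `"main_stem_line"`.
#' @param y Numeric vector of y coordinates (pixels).
#' @return Numeric vector of x positions.
#' @export
main_stem_x_at <- function(line, y) {
  stopifnot(inherits(line, "main_stem_line"))
  line$slope * y + line$intercept
}

#' Remove candidates horizontally distant from the main-stem line
#'
#' A candidate at (x, y) is kept iff its horizontal distance
#' `|x - (slope * y + intercept)|` is at most `threshold` pixels
#' (boundary inclusive). Removed candidates get status
#' `"removed_mainstem"`. Only `"active"` candidates are touched.
#'
#' @param cands Candidate data frame (columns `x`, `y`, `status`, `reason`).
#' @param line A `"main_stem_line"`.
#' @param threshold Distance threshold in pixels (default 50).
#' @return The candidate data frame with updated statuses.
#' @export
filter_by_main_stem <- function(cands, line, threshold = 50) {
  stopifnot(threshold > 0)
  if (nrow(cands) == 0) return(cands)
  act <- cands$status == "active"
  d <- abs(cands$x - main_stem_x_at(line, cands$y))
  drop <- act & d > threshold
  cands$status[drop] <- "removed_mainstem"
  cands$reason[drop] <- sprintf(
    "horizontal distance %.1f px > %g px from main stem line", d[drop],
    threshold)
  cands
}
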