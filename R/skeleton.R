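#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning: alternating sub-iterations delete
#' boundary pixels that have 2..6 foreground 8-neighbours, exactly one
#' 0-to-1 transition around the neighbourhood, and satisfy the
#' directional conditions of the sub-iteration, until no pixel changes.
#' Connectivity (number of 8-connected components) is preserved.
#'
#' The original update rules can erase a small component outright (a
#' 2 x 2 square satisfies both sub-iterations simultaneously), so a
#' guard retains the first pixel of any component whose last pixels
#' would all be deleted in one sub-iteration, keeping the component
#' count exactly equal to the input's.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m == 1L)
  comp <- label_components(m == 1L, connectivity = 8)
  n_comp <- max(comp)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L & cond
      if (any(del)) {
        remaining <- tabulate(comp[m == 1L], nbins = n_comp)
        deleted <- tabulate(comp[del], nbins = n_comp)
        doomed <- which(deleted > 0L & deleted == remaining)
        for (k in doomed) {
          keep <- which(del & comp == k)[1]
          del[keep] <- FALSE
        }
        if (any(del)) {
          m[del] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Count of foreground 8-neighbours for every pixel.
#' @noRd
neighbor_count <- function(skel) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  shift_mat(m, -1L, 0L) + shift_mat(m, -1L, 1L) + shift_mat(m, 0L, 1L) +
    shift_mat(m, 1L, 1L) + shift_mat(m, 1L, 0L) + shift_mat(m, 1L, -1L) +
    shift_mat(m, 0L, -1L) + shift_mat(m, -1L, -1L)
}

# Rutovitz crossing number: 0->1 transitions in the circular sequence
# of 8-neighbours. 1 = endpoint, 2 = line, >= 3 = branch/cross point.
#' @noRd
crossing_number <- function(skel) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
  p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
  p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
  p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
  (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
    (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
    (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
    (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
}

#' Detect branch and cross points on a skeleton
#'
#' Under the default `"crossing"` rule a skeleton pixel is a junction
#' when its Rutovitz crossing number (0-to-1 transitions around the
#' circular 8-neighbour sequence) is at least 3 -- i.e. at least three
#' distinct branches leave the pixel. This is immune to the staircase
#' corners thinning leaves on oblique lines, where a pixel can have
#' three foreground neighbours that belong to only two branches. The
#' plain neighbour-count rule (>= 3 foreground 8-neighbours) is
#' available as `rule = "neighbors"`.
#'
#' Because thinning can emit small clusters of adjacent junction pixels
#' at one anatomical junction, 8-connected junction pixels are merged
#' into a single candidate at their rounded centroid.
#'
#' @param skel Logical skeleton matrix.
#' @param rule Junction criterion, `"crossing"` (default) or
#'   `"neighbors"`.
#' @return A candidate set: data frame with columns `x`, `y` (0-based
#'   pixel coordinates), `status` (all `"active"`) and `reason` (`NA`).
#' @export
find_branch_points <- function(skel, rule = c("crossing", "neighbors")) {
  rule <- match.arg(rule)
  skel <- skel & TRUE
  junction <- if (rule == "crossing") {
    skel & crossing_number(skel) >= 3L
  } else {
    skel & neighbor_count(skel) >= 3L
  }
  if (!any(junction)) {
    return(data.frame(x = integer(0), y = integer(0),
                      status = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  labs <- label_components(junction, connectivity = 8)
  ids <- sort(unique(labs[labs > 0L]))
  xs <- ys <- integer(length(ids))
  for (i in seq_along(ids)) {
    idx <- which(labs == ids[i], arr.ind = TRUE)
    xs[i] <- as.integer(round(mean(idx[, 2]))) - 1L
    ys[i] <- as.integer(round(mean(idx[, 1]))) - 1L
  }
  ord <- order(ys, xs)
  data.frame(x = xs[ord], y = ys[ord],
             status = "active", reason = NA_character_,
             stringsAsFactors = FALSE)
}
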