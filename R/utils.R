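# Internal helpers shared across modules.
#
# Coordinate convention (everywhere in the package): x = column, y = row,
# origin at the top-left pixel, 0-based, y increases downward. R matrices
# are 1-based [row, col], so x = col - 1 and y = row - 1 at the boundary
# between public data frames and internal matrix code.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
xy_to_rowcol <- function(x, y) cbind(row = y + 1L, col = x + 1L)

#' @noRd
clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# Shift a matrix by (dr, dc): result[i, j] = m[i + dr, j + dc], zero fill.
#' @noRd
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) && length(cs)) out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# 3x3 convolution with replicated (clamped) borders; kernel indexed
# [row, col] with the centre at [2, 2].
#' @noRd
conv3x3_replicate <- function(m, kernel) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    kv <- kernel[dr + 2L, dc + 2L]
    if (kv == 0) next
    rs <- clamp(seq_len(h) + dr, 1L, h)
    cs <- clamp(seq_len(w) + dc, 1L, w)
    out <- out + kv * m[rs, cs, drop = FALSE]
  }
  out
}

# BT.601 luminance of an H x W x 3 array in [0, 1].
#' @noRd
to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Label connected components of a logical matrix (4- or 8-connectivity).
# Vectorised frontier BFS; returns an integer matrix, 0 = background.
#' @noRd
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (!any(mask)) return(labels)
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  todo <- which(mask)
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      cc <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(r, nrow(offs)) + rep(offs[, "dr"], each = length(r))
      nc <- rep(cc, nrow(offs)) + rep(offs[, "dc"], each = length(r))
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      idx <- unique((nc[ok] - 1L) * h + nr[ok])
      idx <- idx[mask[idx] & labels[idx] == 0L]
      labels[idx] <- lab
      frontier <- idx
    }
  }
  labels
}

#' @noRd
stop_if_empty <- function(x, what) {
  if (is.null(x) || NROW(x) == 0) stop(what, call. = FALSE)
  invisible(x)
}
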