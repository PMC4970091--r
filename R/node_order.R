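# Node order estimation: affinity propagation on detection y-coordinates
# (capture time removed), order assignment by decreasing cluster mean y,
# then per-order linear regression of y on capture time ("node lines").

#' Affinity propagation clustering
#'
#' Standard responsibility / availability message passing (Frey & Dueck)
#' with damping, on a user-supplied similarity matrix. The number of
#' clusters is determined by the algorithm. Deterministic for a fixed
#' input (a tiny index-ordered perturbation breaks exact ties, as is
#' conventional, but is not random).
#'
#' @param S Numeric similarity matrix `n x n`; the diagonal holds the
#'   preferences.
#' @param damping Damping factor in \[0.5, 1) (default 0.5).
#' @param max_iter Maximum iterations (default 1000).
#' @param conv_window Stop after this many iterations without a change in
#'   the exemplar set (default 100).
#' @return List with `exemplars` (indices), `assignment` (cluster id per
#'   point, 1..n_clusters), `n_clusters`, `converged`, `iterations`.
#' @export
affinity_propagation <- function(S, damping = 0.5, max_iter = 1000,
                                 conv_window = 100) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S),
            damping >= 0.5, damping < 1)
  n <- nrow(S)
  if (n == 1L) {
    return(list(exemplars = 1L, assignment = 1L, n_clusters = 1L,
                converged = TRUE, iterations = 0L))
  }
  # break exact similarity ties deterministically (scaled to the data)
  sc <- max(abs(S[is.finite(S)]), 1)
  S <- S + matrix(seq_len(n * n), n, n) * 1e-12 * sc / (n * n)
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- integer(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    mx1 <- apply(AS, 1, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), w1)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Rmax <- matrix(mx1, n, n)
    Rmax[cbind(seq_len(n), w1)] <- mx2
    R <- damping * R + (1 - damping) * (S - Rmax)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, prev_ex) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= conv_window) break
    } else {
      stable <- 0L
      prev_ex <- ex
    }
  }
  converged <- stable >= conv_window
  if (!converged) {
    warning("affinity propagation did not converge; using final messages")
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) {
    ex <- which.max(diag(A) + diag(R))
  }
  assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  cluster <- match(assign_to, ex)
  list(exemplars = ex, assignment = cluster, n_clusters = length(ex),
       converged = converged, iterations = it)
}

#' Cluster node detections by their y coordinate
#'
#' Similarity between detections is the negative squared difference of
#' their y values; the shared preference (self-similarity) defaults to
#' the median of the off-diagonal similarities, so the cluster count is
#' chosen by the algorithm, not supplied.
#'
#' @param nodes Data frame of detections with columns `y` and (optional
#'   downstream) `t`, or a numeric vector of y values.
#' @param damping Damping factor (default 0.5).
#' @param preference Optional numeric preference; default median of
#'   off-diagonal similarities.
#' @param max_iter,conv_window Iteration controls, see
#'   [affinity_propagation()].
#' @return Object of class `"node_clustering"`: list with `n`,
#'   `assignment` (cluster id per detection), `exemplars`, `mean_y`
#'   (per cluster).
#' @export
cluster_by_y <- function(nodes, damping = 0.5, preference = NULL,
                         max_iter = 1000, conv_window = 100) {
  y <- if (is.data.frame(nodes)) nodes$y else as.numeric(nodes)
  stop_if_empty(y, "no detections to cluster")
  n <- length(y)
  S <- -outer(y, y, function(a, b) (a - b)^2)
  if (is.null(preference)) {
    off <- S[row(S) != col(S)]
    preference <- if (length(off)) stats::median(off) else 0
  }
  diag(S) <- preference
  # Oscillation guard: message passing at low damping can cycle on
  # inputs with many duplicate y values (tight node tracks produce
  # them routinely). If the run does not converge, retry with stronger
  # damping -- a deterministic fallback that leaves the fixed points of
  # the update unchanged.
  for (d in unique(pmax(c(damping, 0.7, 0.9), damping))) {
    ap <- suppressWarnings(
      affinity_propagation(S, damping = d, max_iter = max_iter,
                           conv_window = conv_window))
    if (ap$converged) break
  }
  if (!ap$converged) {
    warning("affinity propagation did not converge at any damping; ",
            "using final assignment")
  }
  mean_y <- as.numeric(tapply(y, ap$assignment, mean))
  structure(list(n = ap$n_clusters, assignment = ap$assignment,
                 exemplars = ap$exemplars, mean_y = mean_y,
                 converged = ap$converged),
            class = "node_clustering")
}

#' Assign node orders to clusters
#'
#' Order 1 is the cluster with the largest mean y (lowest on the plant
#' in image coordinates); orders increase as mean y decreases. Exact
#' ties in mean y are broken by the smaller minimum timestamp (the older
#' cluster gets the lower order).
#'
#' @param clustering A `"node_clustering"`.
#' @param t Optional numeric vector of detection timestamps (UNIX
#'   seconds), parallel to the clustered detections; used only for tie
#'   breaking.
#' @return Integer vector: `order[k]` is the node order of cluster `k`.
#' @export
assign_orders <- function(clustering, t = NULL) {
  stopifnot(inherits(clustering, "node_clustering"))
  my <- clustering$mean_y
  tmin <- if (is.null(t)) rep(0, clustering$n) else {
    as.numeric(tapply(t, clustering$assignment, min))
  }
  rnk <- order(-my, tmin)
  ord <- integer(clustering$n)
  ord[rnk] <- seq_len(clustering$n)
  ord
}

#' Fit per-order node lines
#'
#' Per cluster, ordinary least squares of y (pixels) on capture time
#' (UNIX seconds). A singleton cluster gets slope 0 and its own y as
#' intercept. The appearance time of a node is the minimum timestamp
#' among its detections.
#'
#' @param nodes Data frame with columns `t` (UNIX seconds) and `y`
#'   (pixels).
#' @param clustering A `"node_clustering"` over the same rows.
#' @return Data frame of class `"node_lines"`: one row per node order,
#'   columns `order`, `slope` (px/s), `intercept` (px),
#'   `appearance_time`, `n_members`.
#' @export
fit_node_lines <- function(nodes, clustering) {
  stopifnot(inherits(clustering, "node_clustering"),
            nrow(nodes) == length(clustering$assignment))
  ord <- assign_orders(clustering, nodes$t)
  res <- lapply(seq_len(clustering$n), function(k) {
    sel <- clustering$assignment == k
    tt <- nodes$t[sel]; yy <- nodes$y[sel]
    if (sum(sel) == 1L || length(unique(tt)) == 1L) {
      slope <- 0; intercept <- mean(yy)
    } else {
      fit <- stats::lm.fit(cbind(1, tt), yy)
      intercept <- unname(fit$coefficients[1])
      slope <- unname(fit$coefficients[2])
    }
    data.frame(order = ord[k], slope = slope, intercept = intercept,
               appearance_time = min(tt), n_members = sum(sel))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$order), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("node_lines", "data.frame")
  out
}

#' Evaluate a node line at given times
#'
#' `y(t) = intercept + slope * t`; extrapolation is permitted (this is
#' how missed detections are interpolated).
#'
#' @param lines A `"node_lines"` data frame.
#' @param order Node order to evaluate.
#' @param t Numeric vector of times (UNIX seconds).
#' @return Numeric vector of y positions (pixels).
#' @export
node_y_at <- function(lines, order, t) {
  row <- lines[lines$order == order, , drop = FALSE]
  if (nrow(row) != 1L) stop("no node line with order ", order, call. = FALSE)
  row$intercept + row$slope * t
}
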