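# Shared fixtures, built once per test run and cached. All synthetic,
# generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small rendered sequence: 320 x 480, 4 nodes, 4 nights (20 frames).
small_sequence <- function() {
  fixture("small_sequence", function() {
    render_sequence(seedling_spec(width = 320, height = 480, n_nodes = 4,
                                  nights = 4, base_x = 150, seed = 7))
  })
}

# A reduced pipeline configuration that keeps unit tests fast.
small_config <- function() {
  pipeline_config(pixel_counts = c(stem = 4000, leaf = 2000,
                                   background = 4000),
                  n_node_patches = 60, n_non_node_patches = 80,
                  n_trees = 100)
}

# Models trained on the small sequence.
small_models <- function() {
  fixture("small_models", function() {
    train_pipeline(small_sequence(), small_config())
  })
}

# Detections of the small sequence under its own models.
small_detection <- function() {
  fixture("small_detection", function() {
    run_detection(small_models(), small_sequence(), small_config())
  })
}

# Brute-force junction scan: double loop over pixels, counting
# foreground 8-neighbours or 0->1 transitions, depending on the rule.
brute_force_junctions <- function(skel, rule = c("crossing", "neighbors")) {
  rule <- match.arg(rule)
  h <- nrow(skel); w <- ncol(skel)
  hits <- matrix(FALSE, h, w)
  at <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && skel[r, c]
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!skel[r, c]) next
    # circular neighbour sequence: N, NE, E, SE, S, SW, W, NW
    seq8 <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
              at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
    if (rule == "neighbors") {
      hits[r, c] <- sum(seq8) >= 3
    } else {
      trans <- sum(!seq8 & c(seq8[-1], seq8[1]))
      hits[r, c] <- trans >= 3
    }
  }
  hits
}

# Raw junction-pixel mask of the implementation (before centroid
# merging), for pixel-level oracle comparison.
impl_junction_mask <- function(skel, rule = "crossing") {
  if (rule == "crossing") {
    skel & phenonode:::crossing_number(skel) >= 3L
  } else {
    skel & phenonode:::neighbor_count(skel) >= 3L
  }
}

# Closed-form simple linear regression (normal equations).
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Exhaustive exemplar-subset search maximising net similarity (sum of
# point-to-exemplar similarities plus exemplar preferences). Feasible
# for n <= 12.
exhaustive_exemplars <- function(S) {
  n <- nrow(S)
  stopifnot(n <= 12)
  best <- NULL; bestv <- -Inf
  for (m in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    rest <- setdiff(seq_len(n), ex)
    v <- sum(diag(S)[ex])
    if (length(rest)) {
      sub <- S[rest, ex, drop = FALSE]
      v <- v + sum(apply(sub, 1, max))
    }
    if (v > bestv) { bestv <- v; best <- ex }
  }
  assign <- integer(n)
  for (i in seq_len(n)) {
    assign[i] <- if (i %in% best) match(i, best) else
      which.max(S[i, best])
  }
  list(exemplars = best, assignment = assign, value = bestv)
}

# Partition equality up to cluster relabelling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
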