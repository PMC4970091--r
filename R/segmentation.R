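#' @importFrom stats predict
NULL

CLASS_LEVELS <- c("background", "stem", "leaf")

#' Train the decision-tree segmentation model (DTSM)
#'
#' Fits a CART classification tree (Gini impurity) on 15-dimensional
#' colour feature vectors labelled stem / leaf / background. The tree is
#' grown with a depth cap and a minimum leaf size rather than
#' cost-complexity pruning.
#'
#' @param features Numeric matrix `n x 15` of colour features
#'   (see [color_features()]).
#' @param labels Character or factor vector of length `n` with values in
#'   `c("background", "stem", "leaf")`.
#' @param max_depth Maximum tree depth (default 10).
#' @param min_leaf Minimum number of samples per leaf (default 5).
#' @param seed Integer seed fixing any tie-breaking.
#' @return An object of class `"dtsm"`.
#' @export
train_dtsm <- function(features, labels, max_depth = 10, min_leaf = 5,
                       seed = 1L) {
  stop_if_empty(features, "empty training set")
  features <- as.matrix(features)
  stopifnot(ncol(features) == 15, nrow(features) == length(labels))
  labels <- as.character(labels)
  stopifnot(all(labels %in% CLASS_LEVELS))
  classes <- unique(labels)
  if (length(classes) == 1L) {
    warning("single-class training set; returning a degenerate one-leaf tree")
    fit <- NULL
  } else {
    df <- as.data.frame(features)
    colnames(df) <- color_feature_names()
    df$class <- factor(labels, levels = CLASS_LEVELS)
    set.seed(seed)
    fit <- rpart::rpart(
      class ~ ., data = df, method = "class",
      parms = list(split = "gini"),
      control = rpart::rpart.control(maxdepth = max_depth,
                                     minbucket = min_leaf,
                                     minsplit = 2 * min_leaf,
                                     cp = 0, xval = 0))
  }
  structure(list(fit = fit, constant = if (is.null(fit)) classes else NULL,
                 levels = CLASS_LEVELS),
            class = "dtsm")
}

#' Predict pixel classes from colour features
#'
#' @param object A `"dtsm"` model.
#' @param features Numeric matrix `n x 15`.
#' @param ... Unused.
#' @return Character vector of class labels.
#' @export
predict.dtsm <- function(object, features, ...) {
  features <- as.matrix(features)
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(features)))
  }
  df <- as.data.frame(features)
  colnames(df) <- color_feature_names()
  as.character(predict(object$fit, newdata = df, type = "class"))
}

#' Segment an image into stem / leaf / background
#'
#' Applies the segmentation tree to every pixel's colour feature vector.
#'
#' @param model A `"dtsm"` model from [train_dtsm()].
#' @param img Numeric array `H x W x 3` with values in \[0,1\].
#' @return A class map: integer matrix `H x W` with values 1..3 and a
#'   `"levels"` attribute `c("background", "stem", "leaf")`.
#' @export
segment_image <- function(model, img) {
  stopifnot(inherits(model, "dtsm"))
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[1] == 0 || d[2] == 0) {
    stop("empty image")
  }
  feats <- image_color_features(img)
  pred <- predict(model, feats)
  cm <- matrix(match(pred, CLASS_LEVELS), d[1], d[2])
  attr(cm, "levels") <- CLASS_LEVELS
  cm
}

#' Binary stem mask from a class map
#'
#' @param class_map Integer matrix as returned by [segment_image()], or a
#'   character matrix of class labels.
#' @return Logical matrix, `TRUE` where the pixel is classified as stem.
#' @export
stem_mask <- function(class_map) {
  if (is.character(class_map)) {
    m <- class_map == "stem"
  } else {
    m <- class_map == match("stem", CLASS_LEVELS)
  }
  dim(m) <- dim(class_map)
  m
}
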