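# Classifier primitives: the RBF-SVM decision function evaluated exactly as
# deployed on-device, small threshold rules and decision trees, and JSON
# model files.
#
# The decision function is
#   f(x) = sign( sum_i alpha_i y_i exp(-||x_i - x||^2 / (2 sigma^2)) + b )
# with sign(0) := -1 (an exact tie flags no symptom, conservative toward the
# actuation system). Features are z-scored with training-set statistics
# stored inside the model artifact before the kernel is evaluated; RBF
# kernels on raw mixed-unit features would be degenerate.

MODEL_FORMAT_VERSION <- 1L

#' Construct an RBF-SVM model object
#'
#' @param support_vectors l x d numeric matrix (standardised feature space).
#' @param alpha l non-negative kernel weights.
#' @param y l support-vector labels in -1/+1.
#' @param sigma kernel width, > 0.
#' @param b bias term.
#' @param feature_names d unique feature names.
#' @param scaler list with `mean` and `sd` (length d) used to standardise
#'   inputs before kernel evaluation.
#' @return an `svm_model`.
#' @export
svm_model <- function(support_vectors, alpha, y, sigma, b, feature_names,
                      scaler) {
  support_vectors <- as.matrix(support_vectors)
  l <- nrow(support_vectors); d <- ncol(support_vectors)
  stopifnot(length(alpha) == l, length(y) == l, all(y %in% c(-1, 1)),
            length(feature_names) == d, !anyDuplicated(feature_names),
            length(scaler$mean) == d, length(scaler$sd) == d,
            length(sigma) == 1L, length(b) == 1L)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(support_vectors = unname(support_vectors),
                 alpha = as.numeric(alpha), y = as.numeric(y),
                 sigma = as.numeric(sigma), b = as.numeric(b),
                 feature_names = as.character(feature_names),
                 scaler = list(mean = as.numeric(scaler$mean),
                               sd = as.numeric(scaler$sd)),
                 version = MODEL_FORMAT_VERSION),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d support vectors, %d features, sigma = %.4g, b = %.4g\n",
              nrow(x$support_vectors), length(x$feature_names), x$sigma, x$b))
  cat(sprintf("  single-precision storage footprint: %d bytes\n",
              model_memory_bytes(x)))
  invisible(x)
}

#' Single-precision storage footprint of a model
#'
#' `l * d * 4` bytes: support vectors stored as 4-byte floats, the quantity
#' that feeds the flash-memory budget arithmetic.
#'
#' @param model an [svm_model()].
#' @return integer byte count.
#' @export
model_memory_bytes <- function(model) {
  nrow(model$support_vectors) * length(model$feature_names) * 4L
}

standardise_input <- function(model, x) {
  miss <- setdiff(model$feature_names, names(x))
  if (length(miss) > 0L) {
    stop("feature vector is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  (as.numeric(x[model$feature_names]) - model$scaler$mean) / model$scaler$sd
}

#' Evaluate the RBF-SVM decision function
#'
#' @param model an [svm_model()].
#' @param x named feature vector covering `model$feature_names`.
#' @return list with `label` (-1 or +1; sign(0) := -1) and `margin`.
#' @export
svm_decision <- function(model, x) {
  z <- standardise_input(model, x)
  d2 <- colSums((t(model$support_vectors) - z)^2)
  margin <- sum(model$alpha * model$y * exp(-d2 / (2 * model$sigma^2))) +
    model$b
  list(label = if (margin > 0) 1 else -1, margin = margin)
}

#' Evaluate the decision function on many feature vectors
#'
#' @param model an [svm_model()].
#' @param X matrix or data.frame with feature-named columns.
#' @return data.frame with `margin` and `label` per row.
#' @export
svm_decision_many <- function(model, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X[, model$feature_names, drop = FALSE], 2,
                   model$scaler$mean), 2, model$scaler$sd, "/")
  SV <- model$support_vectors
  d2 <- outer(rowSums(Z^2), rep(1, nrow(SV))) +
    outer(rep(1, nrow(Z)), rowSums(SV^2)) - 2 * Z %*% t(SV)
  d2[d2 < 0] <- 0  # clamp tiny negative rounding residue
  margin <- as.numeric(exp(-d2 / (2 * model$sigma^2)) %*%
                         (model$alpha * model$y)) + model$b
  data.frame(margin = margin, label = ifelse(margin > 0, 1, -1))
}

#' Train an RBF-SVM and extract it into the deployable form
#'
#' Wraps libsvm C-classification (via e1071) on z-scored features, then
#' extracts support vectors, weights and bias into an [svm_model()] whose
#' [svm_decision()] margins reproduce the trainer's own decision values. The
#' positive class is `TRUE` / `+1` / the first factor level.
#'
#' @param features matrix or data.frame with named feature columns.
#' @param labels logical, -1/+1 numeric, or 2-level factor.
#' @param C soft-margin cost.
#' @param sigma kernel width; default `sqrt(d / 2)` (the libsvm
#'   `gamma = 1/d` heuristic expressed as a width).
#' @param seed RNG seed (training is deterministic; the seed also pins the
#'   trainer's internals).
#' @return an [svm_model()].
#' @export
fit_svm <- function(features, labels, C = 1, sigma = NULL, seed = 1L) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("features must have column names", call. = FALSE)
  pos <- if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels > 0
  else labels == levels(as.factor(labels))[1]
  if (length(unique(pos)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1  # constant feature: leave centred, unscaled
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (is.null(sigma)) sigma <- sqrt(ncol(X) / 2)
  yf <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
  fit <- with_seed(seed, e1071::svm(Z, yf, kernel = "radial",
                                    gamma = 1 / (2 * sigma^2), cost = C,
                                    scale = FALSE))
  model <- svm_model(support_vectors = fit$SV,
                     alpha = abs(as.numeric(fit$coefs)),
                     y = sign(as.numeric(fit$coefs)),
                     sigma = sigma, b = -fit$rho,
                     feature_names = colnames(X),
                     scaler = list(mean = mu, sd = sdv))
  # libsvm orients its decision values toward whichever class appears first
  # in the training data; align our margins so positive means the positive
  # class, using the trainer's own predictions as the reference
  pr <- predict(fit, Z)
  ours <- svm_decision_many(model, X)$margin
  if (mean((ours > 0) == (pr == "pos")) < 0.5) {
    model$y <- -model$y
    model$b <- -model$b
  }
  model
}

#' Write / read a model as a versioned JSON file
#'
#' @param model an [svm_model()].
#' @param path JSON file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != MODEL_FORMAT_VERSION) {
    stop("unsupported model file version", call. = FALSE)
  }
  need <- c("support_vectors", "alpha", "y", "sigma", "b", "feature_names",
            "scaler")
  if (!all(need %in% names(obj))) {
    stop("model file is missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  }
  sv <- obj$support_vectors
  if (is.null(dim(sv))) sv <- matrix(sv, nrow = length(obj$alpha))
  svm_model(sv, obj$alpha, obj$y, obj$sigma, obj$b, obj$feature_names,
            obj$scaler)
}

#' Single-feature threshold rule
#'
#' @param feature feature name the rule reads.
#' @param threshold decision threshold.
#' @param direction `"above"` fires when the feature exceeds the threshold,
#'   `"below"` when it falls under it; equality never fires.
#' @return a `threshold_rule`.
#' @export
threshold_rule <- function(feature, threshold,
                           direction = c("above", "below")) {
  direction <- match.arg(direction)
  structure(list(feature = feature, threshold = threshold,
                 direction = direction), class = "threshold_rule")
}

#' Evaluate a threshold rule on a feature vector
#'
#' @param rule a [threshold_rule()].
#' @param x named feature vector.
#' @return logical flag.
#' @export
rule_eval <- function(rule, x) {
  if (!rule$feature %in% names(x)) {
    stop("feature '", rule$feature, "' not present", call. = FALSE)
  }
  v <- as.numeric(x[rule$feature])
  if (rule$direction == "above") v > rule$threshold else v < rule$threshold
}

#' Decision-tree nodes and leaves
#'
#' `tree_leaf(label)` terminates a branch; `tree_node(feature, threshold,
#' left, right)` routes `x[feature] <= threshold` to `left` (ties go left).
#'
#' @param label leaf label (any scalar).
#' @return a `tree_leaf` / `tree_node`.
#' @export
tree_leaf <- function(label) structure(list(label = label), class = "tree_leaf")

#' @rdname tree_leaf
#' @param feature feature name tested at the node.
#' @param threshold split threshold.
#' @param left,right subtrees (`tree_node` or `tree_leaf`).
#' @export
tree_node <- function(feature, threshold, left, right) {
  stopifnot(inherits(left, c("tree_node", "tree_leaf")),
            inherits(right, c("tree_node", "tree_leaf")))
  structure(list(feature = feature, threshold = threshold, left = left,
                 right = right), class = "tree_node")
}

#' Evaluate a decision tree
#'
#' Deterministic root-to-leaf traversal; a value exactly at a node threshold
#' takes the left (<=) branch.
#'
#' @param tree a [tree_node()] or [tree_leaf()].
#' @param x named feature vector covering the referenced features.
#' @return the reached leaf's label.
#' @export
tree_eval <- function(tree, x) {
  while (inherits(tree, "tree_node")) {
    if (!tree$feature %in% names(x)) {
      stop("feature '", tree$feature, "' not present", call. = FALSE)
    }
    tree <- if (as.numeric(x[tree$feature]) <= tree$threshold) tree$left
    else tree$right
  }
  tree$label
}
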