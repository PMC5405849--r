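# Probabilistic classification of regions from sparse annotations. The
# default classifier is an extremely randomized forest (ERF): robust across
# descriptor types with no parameter tuning. All classifiers run
# single-threaded with a fixed seed so that repeated runs are identical.

inv_freq_weights <- function(y) {
  tab <- table(y)
  w <- sum(tab) / (length(tab) * tab)
  as.numeric(w) # ordered by factor levels
}

#' Train a region classifier
#'
#' Fits a probabilistic classifier on the annotated rows of a descriptor
#' matrix. Classes are weighted by inverse frequency, since annotation
#' strokes typically cover the classes very unevenly.
#'
#' Available classifiers: `"erf"` (extremely randomized forest, the
#' default; ranger with random split points), `"rf"` (random forest),
#' `"gbm"` (gradient boosting, xgboost), `"svm"` (RBF support vector
#' machine with probability calibration; slower), `"linear"`
#' (multinomial logistic regression, glmnet).
#'
#' @param desc descriptor matrix, one row per region.
#' @param ann integer vector of length `nrow(desc)`: label id per region,
#'   `-1` or `NA` = unannotated. At least two distinct labels required.
#' @param classifier one of `"erf"`, `"rf"`, `"gbm"`, `"svm"`, `"linear"`.
#' @param hyperparams named list overriding defaults (`num_trees`, `mtry`
#'   for forests; `nrounds`, `max_depth`, `eta` for gbm; `cost`, `gamma`
#'   for svm; `lambda` for linear).
#' @param seed RNG seed; fixed seed implies an identical model.
#' @return An object of class `surseg_model`.
#' @export
train_model <- function(desc, ann, classifier = c("erf", "rf", "gbm", "svm", "linear"),
                        hyperparams = list(), seed = 1L) {
  if (is.character(classifier) && length(classifier) == 1L &&
      !classifier %in% c("erf", "rf", "gbm", "svm", "linear"))
    stop("unknown classifier kind: ", classifier)
  classifier <- match.arg(classifier)
  desc <- as.matrix(desc)
  ann <- as.integer(ann)
  if (length(ann) != nrow(desc))
    stop("`ann` must have one entry per descriptor row")
  idx <- which(!is.na(ann) & ann >= 0L)
  if (!length(idx)) stop("empty annotations")
  label_ids <- sort(unique(ann[idx]))
  if (length(label_ids) < 2L)
    stop("at least two distinct labels are required for training")
  X <- desc[idx, , drop = FALSE]
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(ann[idx], levels = label_ids)
  w <- inv_freq_weights(y)
  hp <- function(name, default) hyperparams[[name]] %||% default

  fit <- switch(classifier,
    erf = ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = hp("num_trees", 100L),
      mtry = hp("mtry", max(1L, floor(sqrt(ncol(X))))),
      splitrule = "extratrees", num.random.splits = 1L,
      class.weights = w, seed = seed, num.threads = 1L),
    rf = ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = hp("num_trees", 100L),
      mtry = hp("mtry", max(1L, floor(sqrt(ncol(X))))),
      class.weights = w, seed = seed, num.threads = 1L),
    gbm = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("classifier \"gbm\" requires the xgboost package")
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                     weight = w[as.integer(y)])
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(label_ids),
                      max_depth = hp("max_depth", 4L),
                      eta = hp("eta", 0.3), nthread = 1L),
        data = dtrain, nrounds = hp("nrounds", 50L), verbose = 0))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("classifier \"svm\" requires the e1071 package")
      cw <- w; names(cw) <- levels(y)
      with_seed(seed, e1071::svm(
        x = X, y = y, probability = TRUE, kernel = "radial",
        cost = hp("cost", 1), gamma = hp("gamma", 1 / ncol(X)),
        class.weights = cw))
    },
    linear = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop("classifier \"linear\" requires the glmnet package")
      with_seed(seed, glmnet::glmnet(
        X, y, family = "multinomial", lambda = hp("lambda", 1e-2)))
    })

  structure(list(fit = fit, kind = classifier, label_ids = label_ids,
                 feature_dim = ncol(desc), seed = seed),
            class = "surseg_model")
}

#' @export
print.surseg_model <- function(x, ...) {
  cat(sprintf("<surseg_model> %s, %d labels (%s), %d features\n",
              x$kind, length(x$label_ids),
              paste(x$label_ids, collapse = ","), x$feature_dim))
  invisible(x)
}

#' Predict label probabilities for all regions
#'
#' Returns a probability field: one row per region (annotated rows
#' included), one column per label, rows summing to 1. The argmax of each
#' row is the raw (pre-refinement) labelling.
#'
#' @param model a [train_model()] result.
#' @param desc descriptor matrix with the training width.
#' @return A `probability_field`: numeric matrix with attribute
#'   `label_ids` (column order).
#' @export
predict_probs <- function(model, desc) {
  desc <- as.matrix(desc)
  if (ncol(desc) != model$feature_dim)
    stop("descriptor width (", ncol(desc), ") does not match training width (",
         model$feature_dim, ")")
  colnames(desc) <- paste0("f", seq_len(ncol(desc)))
  L <- length(model$label_ids)
  probs <- switch(model$kind,
    erf = ,
    rf = predict(model$fit, data = desc, num.threads = 1L, seed = model$seed)$predictions,
    gbm = {
      p <- predict(model$fit, newdata = xgboost::xgb.DMatrix(desc))
      if (is.matrix(p)) p else matrix(p, ncol = L, byrow = TRUE)
    },
    svm = {
      pr <- predict(model$fit, newdata = desc, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, match(as.character(model$label_ids), colnames(p)), drop = FALSE]
    },
    linear = predict(model$fit, newx = desc, type = "response")[, , 1])
  probs <- as.matrix(probs)
  colnames(probs) <- as.character(model$label_ids)
  probs <- probs / rowSums(probs)
  structure(probs, label_ids = model$label_ids, class = "probability_field")
}

pf_matrix <- function(pf) {
  m <- unclass(pf)
  attr(m, "label_ids") <- NULL
  m
}

pf_label_ids <- function(pf) {
  ids <- attr(pf, "label_ids")
  if (is.null(ids)) ids <- seq_len(ncol(pf)) - 1L
  as.integer(ids)
}

#' Per-voxel confidence map
#'
#' Broadcasts each region's maximum class probability to its voxels.
#' Values lie in `[1/L, 1]`; low-confidence areas are the most useful
#' targets for further annotation.
#'
#' @param pf a `probability_field` (rows = regions).
#' @param p a `supervoxel_partition` or 0-based label grid mapping voxels
#'   to probability rows.
#' @return 3D numeric array of maximum class probabilities.
#' @export
confidence_map <- function(pf, p) {
  labs <- partition_labels(p)
  m <- pf_matrix(pf)
  if (nrow(m) != max(labs) + 1L)
    stop("probability rows must match region count")
  conf <- m[cbind(seq_len(nrow(m)), rowmax_idx(m))]
  array(conf[as.vector(labs) + 1L], dim = dim(labs))
}

#' Accept confident predictions as annotations
#'
#' Regions whose maximum class probability reaches `threshold` and that are
#' not yet annotated receive the argmax label; existing annotations are
#' never overwritten. Lowering the threshold accepts a superset. This is
#' the programmatic form of confidence-based acceptance in the iterative
#' annotate-train-accept workflow, which only ever grows the annotation
#' set.
#'
#' @param pf a `probability_field`.
#' @param threshold acceptance threshold in `(1/L, 1]`.
#' @param ann region-level annotation vector (-1 = unlabelled).
#' @return Updated annotation vector; attribute `accepted` holds the
#'   0-based ids of newly annotated regions.
#' @export
accept_by_confidence <- function(pf, threshold, ann) {
  m <- pf_matrix(pf)
  L <- ncol(m)
  if (threshold <= 1 / L || threshold > 1)
    stop("threshold must lie in (1/L, 1]")
  ann <- as.integer(ann)
  if (length(ann) != nrow(m)) stop("`ann` must have one entry per region")
  ids <- pf_label_ids(pf)
  best <- rowmax_idx(m)
  conf <- m[cbind(seq_len(nrow(m)), best)]
  take <- which(conf >= threshold & (is.na(ann) | ann < 0L))
  ann[take] <- ids[best[take]]
  attr(ann, "accepted") <- take - 1L
  ann
}
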