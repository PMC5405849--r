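# Classifier training, prediction, confidence and acceptance.

sep_toy <- function(n = 60, seed = 40) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, -4, 0.3), n / 2, 2),
             matrix(rnorm(n, 4, 0.3), n / 2, 2))
  ann <- rep(c(0L, 1L), each = n / 2)
  list(X = X, ann = ann)
}

test_that("separable classes are learned perfectly by every classifier kind", {
  toy <- sep_toy()
  for (kind in c("erf", "rf", "gbm", "svm", "linear")) {
    model <- train_model(toy$X, toy$ann, classifier = kind, seed = 1)
    pf <- predict_probs(model, toy$X)
    expect_equal(rowSums(pf), rep(1, nrow(toy$X)), ignore_attr = TRUE,
                 tolerance = 1e-6)
    pred <- attr(pf, "label_ids")[max.col(pf)]
    expect_equal(pred, toy$ann, ignore_attr = TRUE)
  }
})

test_that("training validates annotations and classifier kind", {
  toy <- sep_toy()
  expect_error(train_model(toy$X, rep(0L, nrow(toy$X))), "two distinct labels")
  expect_error(train_model(toy$X, rep(-1L, nrow(toy$X))), "empty annotations")
  expect_error(train_model(toy$X, toy$ann, classifier = "megaboost"),
               "unknown classifier")
  expect_error(predict_probs(train_model(toy$X, toy$ann, seed = 1),
                             toy$X[, 1, drop = FALSE]), "width")
})

test_that("conflicting duplicate annotations yield near-uniform probabilities", {
  # two identical points with opposite labels: symmetry forces ~0.5
  X <- matrix(c(0, 0, 0, 0, 5, 5, -5, -5), 4, 2, byrow = TRUE)
  ann <- c(0L, 1L, 0L, 1L)
  model <- train_model(X, ann, classifier = "erf", seed = 2)
  pf <- predict_probs(model, X)
  expect_lt(abs(pf[1, 1] - 0.5), 0.2)
  expect_lt(abs(pf[2, 1] - 0.5), 0.2)
})

test_that("prediction is row-equivariant and seed-deterministic", {
  toy <- sep_toy()
  model <- train_model(toy$X, toy$ann, seed = 5)
  pf <- predict_probs(model, toy$X)
  perm <- sample(nrow(toy$X))
  pf_perm <- predict_probs(model, toy$X[perm, ])
  expect_equal(unclass(pf_perm), unclass(pf)[perm, ], ignore_attr = TRUE)
  model2 <- train_model(toy$X, toy$ann, seed = 5)
  expect_equal(unclass(predict_probs(model2, toy$X)), unclass(pf),
               ignore_attr = TRUE)
})

test_that("confidence maps broadcast the per-region maximum probability", {
  labs <- array(c(0L, 0L, 1L, 1L), c(4, 1, 1))
  pf <- structure(matrix(c(1, 0.3, 0, 0.7), 2, 2),
                  label_ids = c(0L, 1L), class = "probability_field")
  cm <- confidence_map(pf, labs)
  expect_equal(as.vector(cm), c(1, 1, 0.7, 0.7))
  # all certain -> map of ones; uniform -> 1/L
  pf1 <- structure(matrix(c(1, 1, 0, 0), 2, 2), label_ids = 0:1,
                   class = "probability_field")
  expect_true(all(confidence_map(pf1, labs) == 1))
  pfu <- structure(matrix(0.5, 2, 2), label_ids = 0:1,
                   class = "probability_field")
  expect_true(all(confidence_map(pfu, labs) == 0.5))
})

test_that("confidence acceptance is monotone and never overwrites", {
  set.seed(41)
  n <- 50
  probs <- matrix(runif(n * 3), n, 3)
  probs <- probs / rowSums(probs)
  pf <- structure(probs, label_ids = c(2L, 4L, 6L), class = "probability_field")
  ann <- rep(-1L, n)
  ann[1:5] <- 99L
  out9 <- accept_by_confidence(pf, 0.9, ann)
  expect_equal(out9[1:5], rep(99L, 5)) # annotated rows untouched
  # threshold 1.0 on strictly-sub-1 rows: no change
  expect_equal(as.integer(accept_by_confidence(pf, 1.0, ann)), ann)
  # slightly above 1/L: all unannotated rows accepted
  all_in <- accept_by_confidence(pf, 1 / 3 + 1e-9, ann)
  expect_true(all(all_in >= 0))
  # monotone: lower threshold accepts a superset
  for (th in c(0.8, 0.6, 0.45)) {
    hi <- accept_by_confidence(pf, th + 0.1, ann)
    lo <- accept_by_confidence(pf, th, ann)
    expect_true(all(which(hi >= 0) %in% which(lo >= 0)))
    # agreement where both accepted
    both <- hi >= 0 & lo >= 0
    expect_equal(hi[both], lo[both])
  }
  expect_error(accept_by_confidence(pf, 0.2, ann), "threshold")
})

test_that("iterated train-predict-accept only grows the annotation set", {
  toy <- sep_toy(n = 40)
  ann <- rep(-1L, 40)
  ann[c(1, 2, 21, 22)] <- toy$ann[c(1, 2, 21, 22)]
  for (it in 1:3) {
    n_before <- sum(ann >= 0)
    model <- train_model(toy$X, ann, seed = it)
    pf <- predict_probs(model, toy$X)
    ann_new <- accept_by_confidence(pf, 0.9, ann)
    expect_true(all(which(ann >= 0) %in% which(ann_new >= 0)))
    expect_equal(ann_new[ann >= 0], ann[ann >= 0])
    expect_gte(sum(ann_new >= 0), n_before)
    ann <- as.integer(ann_new)
  }
})
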