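test_that("stratified splits hit exact quotas, deterministically", {
  ft <- tibble::tibble(x = rnorm(200),
                       label = rep(c("a", "b", "c", "d"), each = 50))
  sp <- split_dataset(ft, seed = 3)
  tab <- table(ft$label, sp$.split)
  expect_true(all(tab[, "train"] == 30))
  expect_true(all(tab[, "validation"] == 10))
  expect_true(all(tab[, "test"] == 10))
  expect_false(any(is.na(sp$.split)))

  sp2 <- split_dataset(ft, seed = 3)
  expect_identical(sp$.split, sp2$.split)
  sp3 <- split_dataset(ft, seed = 4)
  expect_false(identical(sp$.split, sp3$.split))

  expect_error(split_dataset(ft, fractions = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(split_dataset(ft[1, ], seed = 1), "too small")
  expect_error(split_dataset(dplyr::select(ft, -label)), "label")
})

test_that("backprop gradients match finite differences", {
  withr::local_seed(12)
  X <- matrix(rnorm(5 * 4), 5)
  Y <- diag(3)[sample(1:3, 5, TRUE), ]
  params <- pfec:::mlp_init(4, c(6, 5), 3)
  grads <- pfec:::mlp_grad(params, X, Y)
  eps <- 1e-6
  for (l in seq_along(params)) {
    for (idx in sample(length(params[[l]]$W), 5)) {
      p_hi <- params; p_hi[[l]]$W[idx] <- p_hi[[l]]$W[idx] + eps
      p_lo <- params; p_lo[[l]]$W[idx] <- p_lo[[l]]$W[idx] - eps
      fd <- (pfec:::mlp_loss(p_hi, X, Y) - pfec:::mlp_loss(p_lo, X, Y)) /
        (2 * eps)
      expect_equal(grads[[l]]$W[idx], fd, tolerance = 1e-5)
    }
    p_hi <- params; p_hi[[l]]$b[1] <- p_hi[[l]]$b[1] + eps
    p_lo <- params; p_lo[[l]]$b[1] <- p_lo[[l]]$b[1] - eps
    fd <- (pfec:::mlp_loss(p_hi, X, Y) - pfec:::mlp_loss(p_lo, X, Y)) /
      (2 * eps)
    expect_equal(grads[[l]]$b[1], fd, tolerance = 1e-5)
  }
})

test_that("well-separated classes are learned almost perfectly", {
  traces <- labeled_traces(separable_panel(), n_per_class = 200, seed = 31)
  ft <- split_dataset(pac_features(traces), seed = 5)
  model <- train_classifier(ft, small_mlp())
  test <- ft[ft$.split == "test", ]
  cm <- evaluate(test$label, predict(model, test), classes = model$classes)
  expect_gte(cm$accuracy, 0.95)
})

test_that("permuted labels collapse accuracy to chance level", {
  traces <- labeled_traces(separable_panel(), n_per_class = 150, seed = 41)
  ft <- pac_features(traces)
  withr::with_seed(6, ft$label <- sample(ft$label))
  sp <- split_dataset(ft, seed = 6)
  model <- train_classifier(sp, small_mlp(epochs = 40))
  test <- sp[sp$.split == "test", ]
  acc <- evaluate(test$label, predict(model, test))$accuracy
  n <- nrow(test)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
})

test_that("training is reproducible under identical seeds", {
  traces <- labeled_traces(separable_panel(), n_per_class = 60, seed = 51)
  sp <- split_dataset(pac_features(traces), seed = 7)
  m1 <- train_classifier(sp, small_mlp(epochs = 20))
  m2 <- train_classifier(sp, small_mlp(epochs = 20))
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, sp), predict(m2, sp))
})

test_that("training rejects degenerate inputs", {
  ft <- tibble::tibble(x = rnorm(30), label = "only",
                       .split = factor(rep(c("train", "validation", "test"),
                                           10)))
  expect_error(train_classifier(ft, small_mlp()), "2 classes")
  ft2 <- tibble::tibble(x = c(NA, rnorm(29)), label = rep(c("a", "b"), 15),
                        .split = factor(rep("train", 30),
                                        levels = c("train", "validation",
                                                   "test")))
  expect_error(train_classifier(ft2, small_mlp()), "non-finite")
})

test_that("confusion matrices reproduce hand-built counts and accuracy", {
  # binary case: TP 9, FN 1, FP 2, TN 8 -> accuracy 0.85
  lb <- labels_from_counts(rbind(c(9, 1), c(2, 8)), c("pos", "neg"))
  cm <- evaluate(lb$y_true, lb$y_pred, classes = c("pos", "neg"))
  expect_equal(cm$accuracy, 0.85)
  expect_equal(unname(unlist(cm$by_class[1, c("TP", "FN", "FP", "TN")])),
               c(9, 1, 2, 8))

  counts3 <- rbind(c(8, 1, 1), c(2, 7, 1), c(0, 0, 10))
  lb3 <- labels_from_counts(counts3, c("x", "y", "z"))
  cm3 <- evaluate(lb3$y_true, lb3$y_pred)
  expect_equal(cm3$accuracy, 25 / 30)
  expect_equal(unname(cm3$counts), counts3)

  perfect <- evaluate(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))

  expect_error(evaluate(character(0), character(0)), "empty")
  expect_error(evaluate(c("a", "b"), "a"), "mismatch")
  expect_error(evaluate("a", "b", classes = "a"), "outside")
})

test_that("confusion accuracy equals the elementwise agreement rate", {
  withr::local_seed(14)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    y <- sample(letters[1:k], 60, TRUE)
    p <- sample(letters[1:k], 60, TRUE)
    expect_identical(evaluate(y, p, classes = letters[1:k])$accuracy,
                     mean(y == p))
  }
})

test_that("pulse-average features suffice when only mean q differs", {
  traces <- labeled_traces(separable_panel(), n_per_class = 150, seed = 61)
  cmp <- compare_pac_pfec(traces, small_mlp(epochs = 50), seed = 8)
  expect_gte(cmp$pac$accuracy, 0.9)
  expect_lt(abs(cmp$delta), 0.08)
})

test_that("tidy and glance summarise models and confusions", {
  traces <- labeled_traces(separable_panel(), n_per_class = 40, seed = 71)
  sp <- split_dataset(pac_features(traces), seed = 9)
  m <- train_classifier(sp, small_mlp(epochs = 10))
  td <- tidy(m)
  expect_equal(nrow(td), 3)    # two hidden + output
  expect_equal(glance(m)$n_classes, 2)
  test <- sp[sp$.split == "test", ]
  cm <- evaluate(test$label, predict(m, test))
  expect_equal(sum(tidy(cm)$n), cm$n)
  expect_equal(glance(cm)$accuracy, cm$accuracy)
})
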