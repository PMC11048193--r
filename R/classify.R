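# Classifier workflow: stratified splitting, network training, confusion
# matrix evaluation, and the pulse-feature vs pulse-average comparison.

#' Classifier configuration
#'
#' Defaults mirror the reference architecture: five hidden layers of
#' 64, 128, 256, 128 and 64 rectified-linear neurons, softmax
#' cross-entropy loss, Adam updates, early stopping on validation loss.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param learn_rate Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(hidden = c(64, 128, 256, 128, 64),
                       learn_rate = 1e-3, epochs = 300, batch_size = 64,
                       patience = 20, seed = 1) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1),
            learn_rate > 0, epochs >= 1, batch_size >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), learn_rate = learn_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = seed),
            class = "mlp_config")
}

#' Stratified train / validation / test split
#'
#' Partitions a labeled feature table into disjoint, exhaustive subsets,
#' stratified by label, with exact per-class quotas (largest-remainder
#' rounding) and seed-deterministic assignment.
#'
#' @param features Data frame with a label column.
#' @param fractions Named or positional numeric vector
#'   `(train, validation, test)` summing to 1 (default 0.6 / 0.2 / 0.2).
#' @param label_col Name of the label column.
#' @param seed Optional integer seed.
#' @return The input tibble with an added `.split` factor column with
#'   levels `train`, `validation`, `test`.
#' @export
split_dataset <- function(features, fractions = c(0.6, 0.2, 0.2),
                          label_col = "label", seed = NULL) {
  if (!label_col %in% names(features))
    abort(paste0("no `", label_col, "` column to stratify on."))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    abort("`fractions` must be three nonnegative numbers summing to 1.")
  lab <- as.character(features[[label_col]])
  parts <- factor(rep(NA_character_, nrow(features)),
                  levels = c("train", "validation", "test"))
  with_seed_or_local(seed, {
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      n <- length(idx)
      quota <- floor(fractions * n)
      rem <- n - sum(quota)
      if (rem > 0) {
        extra <- order(fractions * n - quota, decreasing = TRUE)[seq_len(rem)]
        quota[extra] <- quota[extra] + 1L
      }
      if (any(quota == 0 & fractions > 0))
        abort(paste0("class `", cl, "` too small to stratify."))
      perm <- sample(idx)
      parts[perm] <- rep(c("train", "validation", "test"), times = quota)
    }
  })
  out <- as_tibble(features)
  out$.split <- parts
  out
}

#' Train the backpropagation network on a labeled feature table
#'
#' Features are z-scored with statistics of the training split only; the
#' model with the best validation loss is kept (early stopping). Training
#' is deterministic given identical data and configuration.
#'
#' @param features Tibble with feature columns, a label column and a
#'   `.split` column from [split_dataset()].
#' @param config An [mlp_config()].
#' @param label_col,split_col Column names.
#' @param feature_cols Character vector of feature columns; default: all
#'   numeric columns except labels, split and bookkeeping columns.
#' @return A `pfec_mlp` model object.
#' @export
train_classifier <- function(features, config = mlp_config(),
                             label_col = "label", split_col = ".split",
                             feature_cols = NULL) {
  stopifnot(inherits(config, "mlp_config"))
  if (!split_col %in% names(features))
    abort("no split column; run split_dataset() first.")
  meta <- c(label_col, split_col, "qc_imputed", "pulse_id", "start", "end",
            "n_samples", "n_below_floor", "sample_id")
  feature_cols <- feature_cols %||%
    names(features)[vapply(features, is.numeric, TRUE) &
                      !names(features) %in% meta]
  if (length(feature_cols) == 0) abort("no feature columns found.")
  X <- as.matrix(features[feature_cols])
  if (!all(is.finite(X))) abort("non-finite feature values.")
  lab <- as.character(features[[label_col]])
  classes <- sort(unique(lab))
  if (length(classes) < 2) abort("need at least 2 classes to train.")
  split <- features[[split_col]]

  itr <- which(split == "train")
  iva <- which(split == "validation")
  if (length(itr) == 0) abort("empty training split.")
  center <- colMeans(X[itr, , drop = FALSE])
  scale <- apply(X[itr, , drop = FALSE], 2, sd)
  scale[scale < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  Y <- outer(lab, classes, "==") * 1

  Ztr <- Z[itr, , drop = FALSE]; Ytr <- Y[itr, , drop = FALSE]
  Zva <- Z[iva, , drop = FALSE]; Yva <- Y[iva, , drop = FALSE]
  monitor_val <- length(iva) > 0

  with_seed_or_local(config$seed, {
    params <- mlp_init(ncol(Z), config$hidden, length(classes))
    state <- adam_state(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- vector("list", config$epochs)
    t_step <- 0L
    stale <- 0L
    n_tr <- nrow(Ztr)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1L, n_tr)]
        grads <- mlp_grad(params, Ztr[bi, , drop = FALSE],
                          Ytr[bi, , drop = FALSE])
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, t_step, config$learn_rate)
        params <- upd$params
        state <- upd$state
      }
      tr_loss <- mlp_loss(params, Ztr, Ytr)
      va_loss <- if (monitor_val) mlp_loss(params, Zva, Yva) else tr_loss
      history[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss,
                                 val_loss = va_loss)
      if (va_loss < best$loss - 1e-9) {
        best <- list(loss = va_loss, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    structure(
      list(params = best$params, classes = classes,
           feature_cols = feature_cols, center = center, scale = scale,
           config = config, best_epoch = best$epoch,
           val_loss = best$loss,
           history = dplyr::bind_rows(history)),
      class = "pfec_mlp")
  })
}

#' @export
print.pfec_mlp <- function(x, ...) {
  cat("<pfec_mlp> ", length(x$feature_cols), " features -> [",
      paste(x$config$hidden, collapse = ", "), "] -> ",
      length(x$classes), " classes\n", sep = "")
  cat("  best epoch ", x$best_epoch, " (validation loss ",
      signif(x$val_loss, 4), ")\n", sep = "")
  invisible(x)
}

#' Predict classes or class probabilities
#'
#' @param object A `pfec_mlp`.
#' @param newdata Data frame containing the model's feature columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of classes, or a tibble of class
#'   probabilities. Argmax ties break to the lowest class index.
#' @export
predict.pfec_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$feature_cols, names(newdata))
  if (length(miss))
    abort(paste0("newdata lacks feature columns: ",
                 paste(miss, collapse = ", ")))
  X <- as.matrix(newdata[object$feature_cols])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  P <- mlp_probs(object$params, Z)
  colnames(P) <- object$classes
  if (type == "prob") return(as_tibble(P))
  object$classes[max.col(P, ties.method = "first")]
}

#' @method tidy pfec_mlp
#' @export
tidy.pfec_mlp <- function(x, ...) {
  tibble(layer = seq_along(x$params),
         n_in = vapply(x$params, function(p) nrow(p$W), 0L),
         n_out = vapply(x$params, function(p) ncol(p$W), 0L),
         n_weights = vapply(x$params, function(p) length(p$W) + length(p$b), 0L))
}

#' @method glance pfec_mlp
#' @export
glance.pfec_mlp <- function(x, ...) {
  tibble(n_features = length(x$feature_cols),
         n_classes = length(x$classes),
         n_parameters = sum(vapply(x$params,
                                   function(p) length(p$W) + length(p$b), 0L)),
         best_epoch = x$best_epoch, val_loss = x$val_loss)
}

#' Confusion matrix and accuracy
#'
#' Rows are actual categories, columns predicted categories. Overall
#' accuracy is the trace over the total; per-class one-vs-rest TP / FN /
#' FP / TN counts are exposed in the `by_class` table, each class's
#' one-vs-rest accuracy being `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Ordered class labels; default the sorted union.
#' @return A `pfec_confusion` object.
#' @export
evaluate <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0) abort("empty input.")
  if (length(y_true) != length(y_pred)) abort("length mismatch.")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% classes))
    abort("labels outside `classes`.")
  counts <- table(factor(y_true, classes), factor(y_pred, classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  total <- sum(counts)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- total - tp - fn - fp
  structure(
    list(classes = classes, counts = counts,
         accuracy = sum(tp) / total, n = total,
         by_class = tibble(class = classes, TP = tp, FN = fn, FP = fp,
                           TN = tn,
                           accuracy = (tp + tn) / total,
                           recall = ifelse(tp + fn > 0, tp / (tp + fn), NA))),
    class = "pfec_confusion")
}

#' @export
print.pfec_confusion <- function(x, ...) {
  cat("<pfec_confusion>  overall accuracy ",
      sprintf("%.2f%%", 100 * x$accuracy), " on ", x$n, " particles\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' @method tidy pfec_confusion
#' @export
tidy.pfec_confusion <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "n",
                                stringsAsFactors = FALSE))
}

#' @method glance pfec_confusion
#' @export
glance.pfec_confusion <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n, n_classes = length(x$classes))
}

#' Write a confusion matrix as CSV
#' @param cm A `pfec_confusion`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  df <- as.data.frame(cm$counts)
  readr::write_csv(tidy(cm), path)
  invisible(path)
}

#' Compare pulse-feature and pulse-average classification
#'
#' Featurizes the same labeled traces both ways (38-feature and 6-feature
#' vectors), trains two networks on identical stratified partitions, and
#' reports both confusion matrices with per-class and overall accuracy
#' deltas.
#'
#' @param traces Labeled [stokes_traces()] table.
#' @param config An [mlp_config()].
#' @param fractions Split fractions, as in [split_dataset()].
#' @param seed Split seed (shared by both arms).
#' @return A `pfec_comparison` list with elements `pac`, `pfec`
#'   (`pfec_confusion` objects) and `delta` (accuracy-point gain of the
#'   pulse-feature method).
#' @export
compare_pac_pfec <- function(traces, config = mlp_config(),
                             fractions = c(0.6, 0.2, 0.2), seed = 1) {
  if (!"label" %in% names(traces)) abort("`traces` must carry labels.")
  key <- split_dataset(tibble(label = traces$label), fractions,
                       seed = seed)$.split
  arms <- list(pac = pac_features(traces), pfec = pfec_features(traces))
  out <- purrr::map(arms, function(ft) {
    ft$.split <- key
    model <- train_classifier(ft, config)
    test <- ft[ft$.split == "test", ]
    evaluate(test$label, predict(model, test), classes = model$classes)
  })
  structure(list(pac = out$pac, pfec = out$pfec,
                 delta = out$pfec$accuracy - out$pac$accuracy),
            class = "pfec_comparison")
}

#' @export
print.pfec_comparison <- function(x, ...) {
  cat("<pfec_comparison>\n")
  cat(sprintf("  pulse-average  accuracy: %.2f%%\n", 100 * x$pac$accuracy))
  cat(sprintf("  pulse-feature  accuracy: %.2f%%\n", 100 * x$pfec$accuracy))
  cat(sprintf("  gain: %+.2f accuracy points\n", 100 * x$delta))
  invisible(x)
}

#' @method glance pfec_comparison
#' @export
glance.pfec_comparison <- function(x, ...) {
  tibble(pac_accuracy = x$pac$accuracy, pfec_accuracy = x$pfec$accuracy,
         delta = x$delta, n_test = x$pac$n)
}
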