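#' Stratified 70:15:15 split of a labelled pixel table
#'
#' Randomly partitions the rows into training, testing and validation sets,
#' stratified by class so each split keeps the global spike:non-spike ratio
#' (to within one row). Deterministic given `seed`.
#'
#' @param table Labelled pixel table (must contain a `label` column).
#' @param fractions Numeric triple summing to 1.
#' @param seed Integer seed.
#' @return Named list of tibbles `training`, `testing`, `validation`:
#'   disjoint, with union equal to the input.
#' @export
split_pixels <- function(table, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  if (length(fractions) != 3) abort("need exactly three fractions")
  counts <- table(table$label)
  if (any(counts < 3))
    abort(sprintf("every class needs at least 3 rows (got %s)",
                  paste(sprintf("%s=%d", names(counts), counts),
                        collapse = ", ")))
  with_seed(seed, {
    assign_split <- function(n) {
      n1 <- round(n * fractions[1]); n2 <- round(n * fractions[2])
      n3 <- n - n1 - n2
      sample(rep(c("training", "testing", "validation"), c(n1, n2, n3)))
    }
    table$.split <- NA_character_
    for (cls in names(counts)) {
      i <- which(table$label == cls)
      table$.split[i] <- assign_split(length(i))
    }
    out <- lapply(c(training = "training", testing = "testing",
                    validation = "validation"),
                  function(s) {
                    t <- table[table$.split == s, , drop = FALSE]
                    t$.split <- NULL
                    t
                  })
    out
  })
}

feature_cols <- function(table) {
  cols <- grep("^f[0-9]+$", names(table), value = TRUE)
  if (length(cols) == 0) abort("no feature columns f1..fk found")
  as.matrix(table[, cols, drop = FALSE])
}

# Forward pass of the stored 8-10-2 network: z-scale, logistic hidden layer,
# softmax output. Returns the spike-class probability.
forward_prob <- function(model, x) {
  if (ncol(x) != model$n_in)
    abort(sprintf("model expects %d features, got %d", model$n_in, ncol(x)))
  if (any(!is.finite(x))) abort("non-finite feature values")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  z <- 1 / (1 + exp(-(xs %*% t(model$w1) +
                        matrix(model$b1, nrow(xs), length(model$b1),
                               byrow = TRUE))))
  o <- z %*% t(model$w2) +
    matrix(model$b2, nrow(z), length(model$b2), byrow = TRUE)
  e <- exp(o - apply(o, 1, max))
  (e / rowSums(e))[, 1]            # column 1 = spike
}

# Mean cross-entropy of spike probabilities against labels.
xent <- function(p_spike, labels) {
  p <- ifelse(labels == "spike", p_spike, 1 - p_spike)
  -mean(log(pmax(p, 1e-12)))
}

# Unpack an nnet weight vector for architecture n_in -> hidden -> 2 into
# explicit matrices (nnet orders weights unit by unit, bias first).
unpack_nnet_wts <- function(wts, n_in, hidden) {
  n1 <- (n_in + 1) * hidden
  m1 <- matrix(wts[seq_len(n1)], nrow = n_in + 1)        # col j = hidden j
  m2 <- matrix(wts[n1 + seq_len((hidden + 1) * 2)], nrow = hidden + 1)
  list(b1 = m1[1, ], w1 = t(m1[-1, , drop = FALSE]),
       b2 = m2[1, ], w2 = t(m2[-1, , drop = FALSE]))
}

#' Train the 8-10-2 spike pixel classifier
#'
#' Fits a feed-forward network with eight inputs (the Laws features), one
#' hidden layer of ten logistic units and two softmax outputs, by quasi-Newton
#' optimisation of the cross-entropy (via \pkg{nnet}), in warm-restarted
#' segments with early stopping on the validation cross-entropy. Features
#' are z-scaled with statistics learned on the training rows only. Training
#' is reproducible: the same data and seed give identical weights.
#'
#' @param train,val Labelled pixel tables with columns `f1` ... `f8` and
#'   `label`.
#' @param seed Integer seed for the weight initialisation.
#' @param max_epochs Optimisation iteration budget.
#' @param patience Early stopping: stop after this many epochs without
#'   validation improvement.
#' @param hidden Hidden layer width.
#' @return Object of class `spike_classifier` holding the weights, the
#'   feature scaler and training metadata.
#' @export
train_classifier <- function(train, val, seed = 1L, max_epochs = 500L,
                             patience = 10L, hidden = 10L) {
  xt <- feature_cols(train); xv <- feature_cols(val)
  if (any(!is.finite(xt)))
    abort(sprintf("non-finite features in training rows: %s",
                  paste(head(which(rowSums(!is.finite(xt)) > 0), 5),
                        collapse = ", ")))
  if (length(unique(train$label)) < 2)
    abort("training table must contain both classes")
  center <- colMeans(xt)
  scale <- pmax(apply(xt, 2, sd), 1e-8)
  zt <- sweep(sweep(xt, 2, center), 2, scale, "/")
  y <- cbind(spike = as.numeric(train$label == "spike"),
             nonspike = as.numeric(train$label != "spike"))

  model <- list(n_in = ncol(xt), hidden = as.integer(hidden),
                center = center, scale = scale, train_seed = as.integer(seed),
                levels = c("spike", "nonspike"))
  chunk <- 10L
  best <- list(loss = Inf, wts = NULL, epoch = 0L)
  wts <- NULL
  epochs <- 0L
  with_seed(seed, {
    while (epochs < max_epochs) {
      it <- min(chunk, max_epochs - epochs)
      fit <- if (is.null(wts))
        nnet::nnet(zt, y, size = hidden, softmax = TRUE, maxit = it,
                   trace = FALSE, MaxNWts = 5000)
      else
        nnet::nnet(zt, y, size = hidden, softmax = TRUE, maxit = it,
                   Wts = wts, trace = FALSE, MaxNWts = 5000)
      converged <- !is.null(wts) && isTRUE(all.equal(wts, fit$wts))
      wts <- fit$wts
      epochs <- epochs + it
      u <- unpack_nnet_wts(wts, ncol(xt), hidden)
      probe <- model; probe[names(u)] <- u
      loss <- xent(forward_prob(probe, xv), val$label)
      if (loss < best$loss - 1e-9)
        best <- list(loss = loss, wts = wts, epoch = epochs)
      if (converged || epochs - best$epoch >= patience) break
    }
  })
  u <- unpack_nnet_wts(best$wts, ncol(xt), hidden)
  model[names(u)] <- u
  model$epochs <- best$epoch
  model$val_loss <- best$loss
  structure(model, class = "spike_classifier")
}

#' @export
print.spike_classifier <- function(x, ...) {
  cat(sprintf("<spike_classifier %d-%d-2, %d weights, val loss %.4f at epoch %d>\n",
              x$n_in, x$hidden,
              length(x$b1) + length(x$w1) + length(x$b2) + length(x$w2),
              x$val_loss, x$epochs))
  invisible(x)
}

#' Predict spike probabilities or classes
#'
#' @param object A `spike_classifier`.
#' @param newdata Matrix of features or a table with `f1` ... `f8` columns.
#' @param type `"prob"` for spike probabilities, `"class"` for labels at the
#'   0.5 threshold.
#' @param ... Unused.
#' @return Numeric vector of spike probabilities, or character labels.
#' @export
predict.spike_classifier <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else feature_cols(newdata)
  p <- forward_prob(object, x)
  if (type == "prob") p else ifelse(p > 0.5, "spike", "nonspike")
}

#' Confusion-matrix metrics for a labelled table
#'
#' Evaluates the classifier with spike as the positive class:
#' TP rate = TP/(TP+FN), TN rate = TN/(TN+FP), and overall
#' accuracy = (TP+TN)/(TP+FP+FN+TN).
#'
#' @param model A `spike_classifier`.
#' @param table Labelled pixel table.
#' @return One-row tibble with counts, the confusion matrix cells and the
#'   three rates.
#' @export
evaluate_classifier <- function(model, table) {
  if (nrow(table) == 0) abort("cannot evaluate on an empty table")
  pred <- predict(model, table, type = "class")
  confusion_metrics(table$label, pred, n_total = nrow(table))
}

confusion_metrics <- function(truth, pred, n_total = length(truth)) {
  tp <- sum(truth == "spike" & pred == "spike")
  fn <- sum(truth == "spike" & pred == "nonspike")
  tn <- sum(truth == "nonspike" & pred == "nonspike")
  fp <- sum(truth == "nonspike" & pred == "spike")
  tibble(n = n_total, n_spike = tp + fn, n_nonspike = tn + fp,
         tp = tp, fp = fp, fn = fn, tn = tn,
         tp_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         tn_rate = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         accuracy = (tp + tn) / (tp + fp + fn + tn))
}

#' Classify the plant pixels of a feature stack
#'
#' Applies the classifier at every `TRUE` pixel of the half-scale plant mask
#' and thresholds the spike probability at 0.5 (strictly greater). Pixels
#' outside the plant mask are always non-spike, so the result is contained
#' in the plant mask.
#'
#' @param model A `spike_classifier`.
#' @param stack A `feature_stack` from [laws_features()].
#' @param plant_mask_half Half-scale [binary_mask] matching the stack.
#' @return Half-scale [binary_mask] of candidate spike pixels.
#' @export
classify_image <- function(model, stack, plant_mask_half) {
  px <- extract_pixel_features(stack, plant_mask_half)
  out <- matrix(FALSE, dim(stack)[1], dim(stack)[2])
  if (nrow(px) > 0) {
    p <- predict(model, px, type = "prob")
    out[cbind(px$row, px$col)] <- p > 0.5
  }
  binary_mask(out, "half")
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Save / load a trained classifier
#'
#' The model file is JSON: architecture, training metadata, and all weights
#' and scaler statistics serialised as 17-significant-digit decimal strings,
#' which round-trip IEEE doubles exactly -- saved and reloaded models give
#' bit-identical predictions.
#'
#' @param model A `spike_classifier`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   classifier.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "spike_classifier")) abort("expected a spike_classifier")
  obj <- list(
    format = "wheatspike-classifier", version = 1L,
    architecture = c(model$n_in, model$hidden, 2L),
    train_seed = model$train_seed, epochs = model$epochs,
    val_loss = fmt17(model$val_loss),
    center = fmt17(model$center), scale = fmt17(model$scale),
    b1 = fmt17(model$b1), w1 = fmt17(as.vector(model$w1)),
    b2 = fmt17(model$b2), w2 = fmt17(as.vector(model$w2)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    abort(sprintf("corrupt or unreadable model file %s: %s",
                                  path, conditionMessage(e))))
  need <- c("format", "architecture", "center", "scale", "b1", "w1", "b2", "w2")
  if (!all(need %in% names(obj)) ||
      !identical(obj$format, "wheatspike-classifier"))
    abort(sprintf("not a wheatspike classifier file: %s", path))
  arch <- as.integer(obj$architecture)
  num <- function(s) as.numeric(s)
  model <- list(
    n_in = arch[1], hidden = arch[2],
    center = num(obj$center), scale = num(obj$scale),
    b1 = num(obj$b1), w1 = matrix(num(obj$w1), arch[2], arch[1]),
    b2 = num(obj$b2), w2 = matrix(num(obj$w2), 2, arch[2]),
    train_seed = as.integer(obj$train_seed),
    epochs = as.integer(obj$epochs), val_loss = as.numeric(obj$val_loss),
    levels = c("spike", "nonspike"))
  if (length(model$center) != arch[1] || length(model$b1) != arch[2])
    abort(sprintf("model file %s is inconsistent with its declared architecture",
                  path))
  structure(model, class = "spike_classifier")
}

#' @export
tidy.spike_classifier <- function(x, ...) {
  h <- dplyr::bind_rows(
    tibble(layer = "hidden", unit = seq_len(x$hidden), input = "bias",
           weight = x$b1),
    purrr::map_dfr(seq_len(x$n_in), function(i)
      tibble(layer = "hidden", unit = seq_len(x$hidden),
             input = paste0("f", i), weight = x$w1[, i])))
  o <- dplyr::bind_rows(
    tibble(layer = "output", unit = 1:2, input = "bias", weight = x$b2),
    purrr::map_dfr(seq_len(x$hidden), function(j)
      tibble(layer = "output", unit = 1:2, input = paste0("h", j),
             weight = x$w2[, j])))
  dplyr::bind_rows(h, o)
}

#' @export
glance.spike_classifier <- function(x, ...) {
  tibble(n_inputs = x$n_in, hidden_units = x$hidden, n_outputs = 2L,
         n_parameters = length(x$b1) + length(x$w1) + length(x$b2) +
           length(x$w2),
         epochs = x$epochs, val_loss = x$val_loss, train_seed = x$train_seed)
}

#' Train a classifier on freshly simulated scenes
#'
#' Convenience wrapper for the standard training recipe: generate `n_scenes`
#' default scenes with derived seeds, sample labelled pixels at roughly the
#' 1:3.35 spike:non-spike ratio, split 70:15:15 stratified by class, and fit
#' the 8-10-2 network with early stopping on the validation split.
#'
#' @param n_scenes Number of training scenes.
#' @param seed Master seed (scene generation, sampling, split and weight
#'   initialisation all derive from it).
#' @param n_spike,n_nonspike Pixels sampled per class per scene.
#' @param scene Template [scene_spec()].
#' @return A `spike_classifier` with the testing-split metrics attached as
#'   attribute `test_metrics`.
#' @export
train_synthetic_classifier <- function(n_scenes = 20L, seed = 1L,
                                       n_spike = 150L, n_nonspike = 500L,
                                       scene = scene_spec()) {
  scenes <- lapply(seq_len(n_scenes), function(i) {
    sc <- scene
    sc$rng_seed <- derive_seed(seed, 100L, i)
    generate_scene(sc)
  })
  tab <- make_training_table(scenes, n_spike = n_spike,
                             n_nonspike = n_nonspike,
                             seed = derive_seed(seed, 200L))
  parts <- split_pixels(tab, seed = derive_seed(seed, 300L))
  model <- train_classifier(parts$training, parts$validation,
                            seed = derive_seed(seed, 400L))
  attr(model, "test_metrics") <- evaluate_classifier(model, parts$testing)
  model
}
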