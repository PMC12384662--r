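# Training (Adam on the batch-mean margin loss) and the evaluation protocol:
# 7:3 split, three-fold cross-validation over the training portion, one
# model per fold, each fold-model evaluated on the shared held-out test set,
# metrics reported as mean +/- sd across folds.

#' Training configuration
#'
#' Defaults follow the canonical protocol: Adam with learning rate 5e-4,
#' batch size 32, training budget of 400 epochs (hard cap 1000) at which
#' the loss curve has typically plateaued. Reduce `epochs` for smoke runs.
#'
#' @param learning_rate Adam step size (default 0.0005).
#' @param batch_size minibatch size (default 32).
#' @param epochs epochs to run (default 400).
#' @param max_epochs hard cap (default 1000); `epochs` may not exceed it.
#' @param seed master seed for init and batch order.
#' @param class_weights optional per-class loss multipliers (length K).
#' @param loss_threshold optional early stop: training stops once the epoch
#'   training loss falls below this value (disabled when `NULL`).
#' @param patience optional early stop on validation-loss plateau (epochs
#'   without improvement); disabled when `NULL`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 32L,
                         epochs = 400L, max_epochs = 1000L, seed = 1L,
                         class_weights = NULL, loss_threshold = NULL,
                         patience = NULL) {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (epochs > max_epochs)
    stopf("epochs (%d) exceeds max_epochs (%d)", epochs, max_epochs)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), class_weights = class_weights,
                 loss_threshold = loss_threshold, patience = patience),
            class = "train_config")
}

adam_init <- function(model) {
  st <- list(t = 0L)
  for (nm in param_names) {
    st[[paste0("m_", nm)]] <- model[[nm]] * 0
    st[[paste0("v_", nm)]] <- model[[nm]] * 0
  }
  st
}

adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in param_names) {
    g <- grads[[nm]]
    st[[paste0("m_", nm)]] <- beta1 * st[[paste0("m_", nm)]] + (1 - beta1) * g
    st[[paste0("v_", nm)]] <- beta2 * st[[paste0("v_", nm)]] + (1 - beta2) * g^2
    model[[nm]] <- model[[nm]] -
      lr * (st[[paste0("m_", nm)]] / bc1) /
        (sqrt(st[[paste0("v_", nm)]] / bc2) + eps)
  }
  list(model = model, state = st)
}

# Forward in chunks to bound memory on large evaluation sets.
predict_in_chunks <- function(model, X, labels = NULL, chunk = 128L,
                              class_weights = NULL) {
  n <- dim(X)[1L]
  probs <- matrix(0, n, model$cfg$n_classes)
  loss_sum <- 0
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    fw <- capsnet_forward(model,
                          array(X[idx, , , drop = FALSE],
                                c(length(idx), dim(X)[2:3])),
                          labels = labels[idx], class_weights = class_weights)
    probs[idx, ] <- fw$probs
    if (!is.null(labels)) loss_sum <- loss_sum + fw$loss * length(idx)
  }
  list(probs = probs, pred = predict_classes(probs),
       loss = if (is.null(labels)) NA_real_ else loss_sum / n)
}

#' Train a micro-capsule network
#'
#' Minimises the batch-mean margin loss with Adam. Batch order is reshuffled
#' every epoch from the configured seed, so a run is fully reproducible.
#' History records train/validation loss and accuracy each epoch.
#'
#' @param model an initialised `capsnet_model`.
#' @param X_train (n, h, w) array of expanded segment matrices.
#' @param y_train 0-based class labels.
#' @param X_val,y_val optional validation set, evaluated each epoch.
#' @param cfg a [train_config].
#' @return `list(model, history)` with `history` a data.frame of
#'   epoch, train_loss, train_acc, val_loss, val_acc.
#' @export
train_capsnet <- function(model, X_train, y_train, X_val = NULL, y_val = NULL,
                          cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  n <- dim(X_train)[1L]
  if (n == 0L) stopf("empty training set")
  K <- model$cfg$n_classes
  present <- sort(unique(as.integer(y_train)))
  if (!identical(present, 0:(K - 1L)))
    stopf("training data covers classes {%s} but the model has %d classes",
          paste(present, collapse = ","), K)
  st <- adam_init(model)
  hist <- vector("list", cfg$epochs)
  best_val <- Inf; stale <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, sprintf("batch%d", epoch)))
    ord <- sample.int(n)
    loss_acc <- 0; correct <- 0L
    for (s in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- array(X_train[idx, , , drop = FALSE], c(length(idx), dim(X_train)[2:3]))
      fw <- capsnet_forward(model, xb, labels = y_train[idx],
                            class_weights = cfg$class_weights,
                            keep_cache = TRUE)
      grads <- capsnet_backward(model, fw)
      upd <- adam_step(model, grads, st, cfg$learning_rate)
      model <- upd$model; st <- upd$state
      loss_acc <- loss_acc + fw$loss * length(idx)
      correct <- correct + sum(fw$pred == y_train[idx])
    }
    row <- data.frame(epoch = epoch, train_loss = loss_acc / n,
                      train_acc = correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(X_val)) {
      ev <- predict_in_chunks(model, X_val, y_val)
      row$val_loss <- ev$loss
      row$val_acc <- mean(ev$pred == y_val)
    }
    hist[[epoch]] <- row
    stop_now <- FALSE
    if (!is.null(cfg$loss_threshold) && row$train_loss < cfg$loss_threshold) {
      log_msg("train", "epoch %d: loss %.4f below threshold %.4f, stopping",
              epoch, row$train_loss, cfg$loss_threshold)
      stop_now <- TRUE
    }
    if (!is.null(cfg$patience) && !is.null(X_val)) {
      if (row$val_loss < best_val - 1e-9) { best_val <- row$val_loss; stale <- 0L }
      else stale <- stale + 1L
      if (stale >= cfg$patience) {
        log_msg("train", "epoch %d: validation plateau (%d epochs), stopping",
                epoch, stale)
        stop_now <- TRUE
      }
    }
    if (stop_now) { hist <- hist[seq_len(epoch)]; break }
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Confusion matrix from actual and predicted labels
#' @param actual,predicted 0-based integer class labels.
#' @param K number of classes.
#' @return K x K integer matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, K) {
  cm <- matrix(0L, K, K,
               dimnames = list(actual = 0:(K - 1L), predicted = 0:(K - 1L)))
  for (k in seq_along(actual))
    cm[actual[k] + 1L, predicted[k] + 1L] <- cm[actual[k] + 1L, predicted[k] + 1L] + 1L
  cm
}

#' Accuracy, sensitivity, and specificity from a confusion matrix
#'
#' Accuracy is the correctly classified share of all samples. For binary
#' cases the highest class index (the ictal class in the canonical cases)
#' is the positive class: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). For K > 2 both are macro-averages of the per-class
#' one-vs-rest values; a class with no actual samples is excluded from the
#' macro-average with a warning. All values are percentages.
#'
#' @param cm K x K confusion matrix, rows = actual, columns = predicted.
#' @return `list(accuracy, sensitivity, specificity)` in percent.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) stopf("need a square nonnegative matrix")
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  K <- nrow(cm)
  if (K == 2L) {
    pos <- 2L  # class index 1 (ictal) is positive
    sens <- cm[pos, pos] / sum(cm[pos, ])
    spec <- cm[1L, 1L] / sum(cm[1L, ])
  } else {
    sens_k <- spec_k <- rep(NA_real_, K)
    for (k in seq_len(K)) {
      actual_k <- sum(cm[k, ])
      if (actual_k == 0) {
        warnf("class %d has no actual samples; excluded from macro-average", k - 1L)
        next
      }
      sens_k[k] <- cm[k, k] / actual_k
      tn <- total - actual_k - sum(cm[, k]) + cm[k, k]
      spec_k[k] <- tn / (total - actual_k)
    }
    sens <- mean(sens_k, na.rm = TRUE)
    spec <- mean(spec_k, na.rm = TRUE)
  }
  list(accuracy = 100 * acc, sensitivity = 100 * sens, specificity = 100 * spec)
}

#' Run the full evaluation protocol for one dataset case
#'
#' Segments the case's recordings, standardizes with training statistics,
#' expands each segment into its 2-D matrix, shuffles and splits 7:3,
#' plans three validation folds over the training portion, trains one model
#' per fold, evaluates each fold-model on the shared held-out test set, and
#' reports accuracy/sensitivity/specificity as mean +/- sd across the three
#' folds.
#'
#' @param recordings_by_set named list: set label -> list of recordings.
#' @param case a [dataset_case].
#' @param seg_cfg a [segmentation_config].
#' @param train_cfg a [train_config].
#' @param routing_iters,model_args routing iterations and further overrides
#'   passed to [capsnet_config()].
#' @return an object of class `metrics_report`.
#' @export
run_case <- function(recordings_by_set, case, seg_cfg = segmentation_config(),
                     train_cfg = train_config(), routing_iters = 3L,
                     model_args = list()) {
  labelled <- build_case(recordings_by_set, case)
  segset <- segment_case(labelled, seg_cfg)
  K <- case$n_classes
  plan <- make_splits(segset$class_idx, seed = train_cfg$seed)
  std <- standardize(segset$values, plan$train_idx)
  X <- expand_segment_set(std$values, seg_cfg$h, seg_cfg$w)
  y <- segset$class_idx
  log_msg("run_case", "%s: %d segments (%d train / %d test), input %dx%d",
          case$name, length(y), length(plan$train_idx), length(plan$test_idx),
          seg_cfg$h, seg_cfg$w)

  mcfg <- do.call(capsnet_config,
                  c(list(input_hw = c(seg_cfg$h, seg_cfg$w), n_classes = K,
                         routing_iters = routing_iters,
                         loss_threshold = train_cfg$loss_threshold),
                    model_args))
  take <- function(idx) array(X[idx, , , drop = FALSE], c(length(idx), dim(X)[2:3]))

  folds <- vector("list", length(plan$folds))
  for (f in seq_along(plan$folds)) {
    fl <- plan$folds[[f]]
    fcfg <- train_cfg
    fcfg$seed <- derive_seed(train_cfg$seed, sprintf("fold%d", f))
    model <- init_capsnet(mcfg, seed = fcfg$seed)
    fit <- train_capsnet(model, take(fl$train), y[fl$train],
                         take(fl$val), y[fl$val], fcfg)
    ev <- predict_in_chunks(fit$model, take(plan$test_idx), y[plan$test_idx])
    cm <- confusion_matrix(y[plan$test_idx], ev$pred, K)
    folds[[f]] <- list(model = fit$model, history = fit$history,
                       confusion = cm, metrics = confusion_metrics(cm))
    log_msg("run_case", "%s fold %d: test acc %.2f%%", case$name, f,
            folds[[f]]$metrics$accuracy)
  }
  agg <- function(field) {
    v <- vapply(folds, function(fd) fd$metrics[[field]], numeric(1))
    c(mean = mean(v), sd = stats::sd(v))
  }
  structure(list(
    case = case$name, n_classes = K,
    accuracy = agg("accuracy"), sensitivity = agg("sensitivity"),
    specificity = agg("specificity"),
    confusions = lapply(folds, `[[`, "confusion"),
    histories = lapply(folds, `[[`, "history"),
    models = lapply(folds, `[[`, "model"),
    split = plan, standardize = std[c("mean", "sd")],
    seg_cfg = seg_cfg, train_cfg = unclass(train_cfg),
    model_cfg = unclass(mcfg)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> case %s (%d classes, %d folds)\n",
              x$case, x$n_classes, length(x$confusions)))
  for (f in c("accuracy", "sensitivity", "specificity"))
    cat(sprintf("  %-12s %6.2f +/- %5.2f %%\n", f, x[[f]]["mean"], x[[f]]["sd"]))
  invisible(x)
}

#' Serialise a metrics report to JSON (machine) and CSV (human)
#'
#' Writes `<stem>.json` with the full report (minus model weights),
#' `<stem>.csv` with the metric summary, and one history CSV per fold.
#'
#' @param report a `metrics_report`.
#' @param stem output path stem (no extension).
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, stem) {
  js <- report[c("case", "n_classes", "accuracy", "sensitivity",
                 "specificity", "confusions", "standardize", "train_cfg",
                 "model_cfg")]
  for (f in c("accuracy", "sensitivity", "specificity"))
    js[[f]] <- as.list(js[[f]])
  jsonlite::write_json(js, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  summ <- data.frame(metric = c("accuracy", "sensitivity", "specificity"))
  summ$mean <- vapply(summ$metric, function(f) report[[f]]["mean"], numeric(1))
  summ$sd <- vapply(summ$metric, function(f) report[[f]]["sd"], numeric(1))
  utils::write.csv(summ, paste0(stem, ".csv"), row.names = FALSE)
  for (f in seq_along(report$histories))
    utils::write.csv(report$histories[[f]],
                     sprintf("%s_history_fold%d.csv", stem, f),
                     row.names = FALSE)
  invisible(paste0(stem, ".json"))
}

#' Accuracy as a function of the segmentation time interval
#'
#' Re-runs the full protocol for each window duration (defaults: 0.6, 0.8,
#' 1.0, 1.2, 1.4 s), recomputing segment length and 2-D expansion each
#' time. The 1.0 s row is flagged as the selected operating point: beyond
#' it accuracy gains are marginal while detection latency grows.
#'
#' @param recordings_by_set named list: set label -> recordings.
#' @param case a [dataset_case].
#' @param intervals window durations in seconds.
#' @param train_cfg a [train_config].
#' @param fs sampling rate in Hz.
#' @param ... further arguments passed to [run_case()].
#' @return data.frame with one row per interval: window points, grid,
#'   mean/sd accuracy, and the operating-point flag.
#' @export
time_interval_sweep <- function(recordings_by_set, case,
                                intervals = c(0.6, 0.8, 1.0, 1.2, 1.4),
                                train_cfg = train_config(), fs = BONN_FS, ...) {
  rows <- lapply(intervals, function(iv) {
    scfg <- segmentation_config(window_s = iv, fs = fs)
    min_len <- min(vapply(unlist(recordings_by_set, recursive = FALSE),
                          function(r) length(r$samples), numeric(1)))
    if (scfg$window_pts > min_len)
      stopf("interval %.2f s (%d points) exceeds the shortest recording (%d points)",
            iv, scfg$window_pts, min_len)
    rep_ <- run_case(recordings_by_set, case, scfg, train_cfg, ...)
    data.frame(interval_s = iv, window_pts = scfg$window_pts,
               h = scfg$h, w = scfg$w,
               mean_accuracy = unname(rep_$accuracy["mean"]),
               sd_accuracy = unname(rep_$accuracy["sd"]),
               operating_point = abs(iv - 1.0) < 1e-9)
  })
  do.call(rbind, rows)
}
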