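# Training and evaluation pipeline.
#
# Protocol defaults follow the reference training settings: learning rate
# 1e-5, batch size 16, 100 epochs, AdamW with cross-entropy loss, inputs
# scaled to [0, 1] (no further standardization by default, no augmentation),
# bilinear resize to 224 x 224, per-epoch validation and best-validation
# checkpointing, and one seed controlling initialization, shuffling and any
# stochastic layers.

#' Construct a training configuration
#'
#' @param learningRate optimizer step size (default 1e-5).
#' @param batchSize minibatch size (default 16).
#' @param epochs training epochs (default 100).
#' @param optimizer `"adamw"` (default) or `"adam"`.
#' @param weightDecay decoupled weight decay for adamw (ignored by adam).
#' @param lrSchedule `"constant"` (default) or `"cosine"` half-period decay
#'   of the learning rate over the epochs.
#' @param augment `"none"` (default, the reference protocol) or `"flip"`:
#'   each training image is randomly flipped along either spatial axis, a
#'   label-preserving augmentation for lesion geometry.
#' @param emaDecay when positive, keep an exponential moving average of all
#'   weights during optimization and adopt it as the final model (with
#'   BatchNorm statistics re-estimated for the averaged weights); stabilizes
#'   short schedules.
#' @param resize target (H, W); images are bilinearly resized.
#' @param standardize channel standardization after `[0,1]` scaling
#'   (off by default).
#' @param seed master seed.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-5, batchSize = 16L, epochs = 100L,
                        optimizer = "adamw", weightDecay = 0.01,
                        lrSchedule = "constant", augment = "none",
                        emaDecay = 0, resize = c(224L, 224L),
                        standardize = FALSE, seed = 1L) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      optimizer = as.character(optimizer), weightDecay = as.numeric(weightDecay),
      lrSchedule = as.character(lrSchedule), augment = as.character(augment),
      emaDecay = as.numeric(emaDecay), resize = as.integer(resize),
      standardize = standardize, seed = as.integer(seed))
}

# (n, H, W) grayscale stack -> (n, 3, H, W) batch tensor in [0, 1] with
# optional resize and channel standardization
prepare_batch <- function(images, idx, resize = NULL, standardize = FALSE) {
  n <- length(idx)
  H <- dim(images)[2]; W <- dim(images)[3]
  if (!is.null(resize) && (resize[1] != H || resize[2] != W)) {
    out <- array(0, c(n, 3, resize[1], resize[2]))
    for (i in seq_len(n)) {
      im <- bilinear_resize(images[idx[i], , ], resize[1], resize[2])
      out[i, 1, , ] <- im; out[i, 2, , ] <- im; out[i, 3, , ] <- im
    }
  } else {
    out <- array(0, c(n, 3, H, W))
    im <- images[idx, , , drop = FALSE]
    out[, 1, , ] <- im; out[, 2, , ] <- im; out[, 3, , ] <- im
  }
  if (standardize) {
    mu <- mean(out); s <- sd(out)
    if (s > 0) out <- (out - mu) / s
  }
  out
}

# random horizontal/vertical flips of a (B, 3, H, W) training batch
augment_flip <- function(x) {
  d <- dim(x)
  fh <- runif(d[1]) < 0.5
  fw <- runif(d[1]) < 0.5
  for (i in seq_len(d[1])) {
    if (fh[i]) x[i, , , ] <- x[i, , d[3]:1, , drop = FALSE]
    if (fw[i]) x[i, , , ] <- x[i, , , d[4]:1, drop = FALSE]
  }
  x
}

# softmax cross-entropy loss and logit gradient, averaged over the batch
ce_loss <- function(logits, labels01) {
  B <- nrow(logits)
  p <- row_softmax(logits)
  eps <- 1e-12
  idx <- cbind(seq_len(B), labels01 + 1L)
  loss <- -mean(log(p[idx] + eps))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / B)
}

# Re-estimate BatchNorm running statistics with frozen weights ("precise
# BN"): one pass over the training split accumulating the exact mean of
# per-batch statistics.  Momentum-based running averages lag the weights
# whenever the schedule is short or the learning rate large; recalibrating
# after training makes evaluation-mode forward passes consistent with the
# final weights.
recalibrate_bn <- function(model, images, idx, batchSize, resize = NULL,
                           standardize = FALSE) {
  bns <- Filter(function(L) L$kind == "bn", net_layers(model))
  if (length(bns) == 0 || length(idx) == 0) return(invisible(NULL))
  for (L in bns) {
    L$buffers$running_mean[] <- 0
    L$buffers$running_var[] <- 0
  }
  starts <- seq(1, length(idx), by = batchSize)
  for (bi in seq_along(starts)) {
    for (L in bns) L$meta$momentum <- 1 / bi     # cumulative mean of batches
    take <- idx[starts[bi]:min(starts[bi] + batchSize - 1, length(idx))]
    xb <- prepare_batch(images, take, resize, standardize)
    invisible(net_forward(model, xb, training = TRUE))
  }
  for (L in net_layers(model)) {
    L$cache <- NULL
    if (L$kind == "bn") L$meta$momentum <- 0.1
  }
  invisible(NULL)
}

snapshot_params <- function(net) {
  lapply(net_layers(net), function(L)
    list(par = L$par, buffers = if (!is.null(L$buffers)) L$buffers else NULL))
}

restore_params <- function(net, snap) {
  ly <- net_layers(net)
  for (i in seq_along(ly)) {
    ly[[i]]$par <- snap[[i]]$par
    if (!is.null(snap[[i]]$buffers)) ly[[i]]$buffers <- snap[[i]]$buffers
  }
  invisible(NULL)
}

#' Train a StarMA Net classifier
#'
#' Epoch loop with cross-entropy loss: per-epoch mean training loss and
#' validation accuracy are logged (console and, when `outDir` is given,
#' JSON-lines), and the weights with the highest validation accuracy are
#' retained (falling back to the final epoch when the dataset has no
#' validation split).  Everything stochastic is pinned by
#' `trainCfg@seed`.
#'
#' @param dataset a [LabeledImageSet-class] with split assignments, or a
#'   directory path in class-per-folder layout.
#' @param config a [BackboneConfig-class]; its `numClasses` must match the
#'   data.
#' @param trainCfg a [TrainConfig-class].
#' @param outDir optional directory for the checkpoint (`checkpoint.rds`)
#'   and training log (`train_log.jsonl`).
#' @param verbose print per-epoch progress.
#' @return list with `model` (best weights restored), `history` data.frame,
#'   `bestEpoch`, `bestValAccuracy`, `configHash`.
#' @export
trainNetwork <- function(dataset, config, trainCfg = trainConfig(),
                         outDir = NULL, verbose = TRUE) {
  if (is.character(dataset))
    dataset <- importImageFolder(dataset, resize = trainCfg@resize)
  K <- length(dataset@classNames)
  if (K != config@numClasses)
    stop("config declares ", config@numClasses, " classes but the data has ", K)
  tr <- which(dataset@split == "train")
  va <- which(dataset@split == "val")
  if (length(tr) == 0) stop("training split is empty")
  resize <- if (all(dim(dataset@images)[2:3] == trainCfg@resize)) NULL
            else trainCfg@resize
  model <- buildStarMANet(config, seed = trainCfg@seed)
  layers <- net_layers(model)
  wd <- if (trainCfg@optimizer == "adamw") trainCfg@weightDecay else 0
  hist <- list()
  best_acc <- -Inf; best_epoch <- 0L; best_snap <- NULL
  step <- 0L
  log_con <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file.path(outDir, "train_log.jsonl")
    if (file.exists(log_con)) unlink(log_con)
  }
  chash <- config_hash(list(config = config, train = trainCfg))
  ema <- NULL
  if (trainCfg@emaDecay > 0)
    ema <- lapply(layers, function(L) L$par)
  with_seed(trainCfg@seed, {
    for (epoch in seq_len(trainCfg@epochs)) {
      lr_epoch <- if (trainCfg@lrSchedule == "cosine")
        trainCfg@learningRate * 0.5 *
          (1 + cos(pi * (epoch - 1) / trainCfg@epochs))
      else trainCfg@learningRate
      ord <- sample(tr)
      losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = trainCfg@batchSize)) {
        idx <- ord[b0:min(b0 + trainCfg@batchSize - 1, length(ord))]
        x <- prepare_batch(dataset@images, idx, resize, trainCfg@standardize)
        if (trainCfg@augment == "flip") x <- augment_flip(x)
        logits <- net_forward(model, x, training = TRUE)
        l <- ce_loss(logits, dataset@labels[idx])
        zero_grads(layers)
        net_backward(model, l$grad)
        step <- step + 1L
        adamw_step(layers, lr_epoch, weight_decay = wd,
                   t = step, decoupled = trainCfg@optimizer == "adamw")
        if (!is.null(ema)) {
          d <- trainCfg@emaDecay
          for (li in seq_along(layers))
            for (nm in names(ema[[li]]))
              ema[[li]][[nm]] <- d * ema[[li]][[nm]] +
                (1 - d) * layers[[li]]$par[[nm]]
        }
        losses <- c(losses, l$loss)
      }
      val_acc <- NA_real_
      if (length(va) > 0) {
        pred <- predictClasses(model, dataset@images[va, , , drop = FALSE],
                               resize, trainCfg@standardize,
                               batchSize = trainCfg@batchSize)
        val_acc <- mean(pred == dataset@labels[va])
        if (val_acc > best_acc) {
          best_acc <- val_acc; best_epoch <- epoch
          best_snap <- snapshot_params(model)
        }
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_accuracy = val_acc)
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f  val acc %s", epoch,
                        mean(losses),
                        ifelse(is.na(val_acc), "-", sprintf("%.4f", val_acc))))
      if (!is.null(log_con))
        cat(jsonlite::toJSON(hist[[epoch]][1, ], auto_unbox = TRUE,
                             dataframe = "rows"),
            "\n", sep = "", file = log_con, append = TRUE)
    }
  })
  if (!is.null(best_snap)) restore_params(model, best_snap)
  else best_epoch <- trainCfg@epochs
  if (!is.null(ema) && is.null(best_snap))
    for (li in seq_along(layers)) layers[[li]]$par <- ema[[li]]
  recalibrate_bn(model, dataset@images, tr, trainCfg@batchSize, resize,
                 trainCfg@standardize)
  out <- list(model = model, history = do.call(rbind, hist),
              bestEpoch = best_epoch,
              bestValAccuracy = if (is.finite(best_acc)) best_acc else NA_real_,
              configHash = chash)
  if (!is.null(outDir))
    saveCheckpoint(model, file.path(outDir, "checkpoint.rds"),
                   extra = list(bestEpoch = best_epoch, trainCfg = trainCfg,
                                configHash = chash))
  out
}

#' Predict class probabilities / labels
#'
#' Deterministic evaluation-mode forward passes in minibatches.
#'
#' @param model a [StarMANet-class].
#' @param images (n, H, W) grayscale stack in `[0, 1]`.
#' @param resize optional (H, W) bilinear resize.
#' @param standardize channel standardization flag (match training).
#' @param batchSize minibatch size.
#' @return `predictProba`: (n, K) softmax matrix; `predictClasses`: integer
#'   labels in `[0, K)`.
#' @export
predictProba <- function(model, images, resize = NULL, standardize = FALSE,
                         batchSize = 16L) {
  n <- dim(images)[1]
  out <- NULL
  for (b0 in seq(1, n, by = batchSize)) {
    idx <- b0:min(b0 + batchSize - 1, n)
    x <- prepare_batch(images, idx, resize, standardize)
    logits <- net_forward(model, x, training = FALSE)
    out <- rbind(out, row_softmax(logits))
  }
  out
}

#' @rdname predictProba
#' @export
predictClasses <- function(model, images, resize = NULL, standardize = FALSE,
                           batchSize = 16L) {
  p <- predictProba(model, images, resize, standardize, batchSize)
  max.col(p, ties.method = "first") - 1L
}

#' Evaluate a model on a dataset split
#'
#' Runs deterministic forward passes and assembles the full evaluation
#' report: multiclass (or binary) metric report with macro one-vs-rest AUC,
#' the confusion matrix, per-class ROC curves, and run metadata.
#'
#' @param model a [StarMANet-class].
#' @param dataset a [LabeledImageSet-class] or image-folder path.
#' @param split which split to score.
#' @param trainCfg the [TrainConfig-class] used in training (for resize /
#'   standardization); defaults to no resize.
#' @param outDir optional directory: writes `metrics_<split>.json`,
#'   `confusion_<split>.csv`, `roc_<split>_class<k>.csv` and plot PNGs.
#' @return list with `report` ([MetricReport-class]), `confusion`
#'   ([ConfusionMatrix-class]), `roc` (list of [ROCCurve-class]),
#'   `probabilities`, `labels`, `configHash`.
#' @export
evaluateNetwork <- function(model, dataset, split = "test",
                            trainCfg = NULL, outDir = NULL) {
  if (is.character(dataset)) dataset <- importImageFolder(dataset)
  idx <- which(dataset@split == split)
  if (length(idx) == 0) stop("split '", split, "' is empty")
  resize <- NULL; standardize <- FALSE
  if (!is.null(trainCfg)) {
    if (!all(dim(dataset@images)[2:3] == trainCfg@resize))
      resize <- trainCfg@resize
    standardize <- trainCfg@standardize
  }
  K <- length(dataset@classNames)
  if (K != model@config@numClasses)
    stop("model head has ", model@config@numClasses,
         " classes but the data has ", K)
  prob <- predictProba(model, dataset@images[idx, , , drop = FALSE],
                       resize, standardize)
  pred <- max.col(prob, ties.method = "first") - 1L
  truth <- dataset@labels[idx]
  cm <- confusionMatrix(truth, pred, nClasses = K,
                        classLabels = dataset@classNames)
  roc <- lapply(seq_len(K) - 1L, function(k)
    tryCatch(rocCurve(as.integer(truth == k), prob[, k + 1L]),
             error = function(e) NULL))
  auc <- mean(vapply(roc, function(r) if (is.null(r)) NA_real_ else r@auc,
                     0), na.rm = TRUE)
  report <- if (K == 2) binaryMetrics(cm, auc = auc)
            else multiclassMetrics(cm, auc = auc)
  chash <- config_hash(model@config)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMetricReport(report, file.path(outDir, sprintf("metrics_%s.json", split)))
    utils::write.csv(cm@counts, file.path(outDir, sprintf("confusion_%s.csv", split)))
    plotConfusionMatrix(cm, file.path(outDir, sprintf("confusion_%s.png", split)))
    for (k in seq_len(K))
      if (!is.null(roc[[k]])) {
        writeRocPoints(roc[[k]], file.path(outDir,
                       sprintf("roc_%s_class%d.csv", split, k - 1L)))
        plotRocCurve(roc[[k]], file.path(outDir,
                     sprintf("roc_%s_class%d.png", split, k - 1L)))
      }
  }
  list(report = report, confusion = cm, roc = roc, probabilities = prob,
       labels = truth, configHash = chash)
}

#' Save / load model checkpoints
#'
#' Checkpoints are RDS files holding every parameter array, normalization
#' buffer, the full backbone configuration and a hash of the configuration
#' that produced them.
#'
#' @param model a [StarMANet-class].
#' @param path checkpoint file path.
#' @param extra optional named list stored alongside.
#' @return `saveCheckpoint`: the path, invisibly; `loadCheckpoint`: the
#'   rebuilt [StarMANet-class] (attribute `"meta"` carries the extras).
#' @export
saveCheckpoint <- function(model, path, extra = list()) {
  obj <- list(config = model@config, params = snapshot_params(model),
              configHash = config_hash(model@config), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  model <- buildStarMANet(obj$config)
  restore_params(model, obj$params)
  attr(model, "meta") <- obj$extra
  model
}
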