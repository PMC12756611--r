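# S4 classes for the configuration objects, result containers and models.

#' StarMA attention configuration
#'
#' Hyperparameters of the star-shaped multi-scale attention block: the number
#' of channel groups processed in parallel, the kernel schedule of the stacked
#' convolution branch, how the downsampled star-gate strip is restored to full
#' length, and the seed controlling weight initialization.
#'
#' @slot groups integer, number of channel groups G (channels must divide by G).
#' @slot scbKernels integer vector, kernel sizes of the stacked convolution
#'   branch in application order (default 1, 5, 7).
#' @slot starUpsample `"nearest"` or `"linear"`; interpolation used to restore
#'   the stride-2-downsampled gate strip to length H+W.
#' @slot seed integer seed for weight initialization.
#' @exportClass StarMAConfig
setClass("StarMAConfig",
  representation(groups = "integer", scbKernels = "integer",
                 starUpsample = "character", seed = "integer"),
  prototype(groups = 8L, scbKernels = c(1L, 5L, 7L),
            starUpsample = "nearest", seed = 1L))

setValidity("StarMAConfig", function(object) {
  if (length(object@groups) != 1 || object@groups < 1)
    return("groups must be a single integer >= 1")
  if (!object@starUpsample %in% c("nearest", "linear"))
    return("starUpsample must be 'nearest' or 'linear'")
  if (length(object@scbKernels) != 3)
    return("scbKernels must list three kernel sizes")
  TRUE
})

#' StarMA Net backbone configuration
#'
#' All architecture hyperparameters of the classifier: channel widths of the
#' input stream (two stem convolutions and three downsampling Base Blocks),
#' the constant trunk width of the four StarMA Blocks, the MLP expansion
#' ratio, the output-stream widths, the class count, the stochastic-depth
#' rate, a global width multiplier (0.5 reproduces the channel-halved
#' variant), and the four ablation switches that rewire the attention block.
#'
#' @slot stemWidths two integers, output channels of the stem convolutions.
#' @slot stageWidths three integers, output channels of the Base Blocks.
#' @slot trunkWidth integer, channel width of the StarMA Blocks.
#' @slot mlpRatio numeric, expansion ratio of the block MLP.
#' @slot outWidths two integers, channels of the output-stream stride-2 3x3
#'   and 1x1 convolutions.
#' @slot numClasses integer number of classes (>= 2).
#' @slot dropPath numeric stochastic-depth rate in `[0, 1)`.
#' @slot widthMultiplier numeric, scales every width (rounded to a multiple of
#'   the attention group count).
#' @slot useCcib,useSss,useScb,useCsfa logical ablation flags.
#' @slot starma a [StarMAConfig-class].
#' @exportClass BackboneConfig
setClass("BackboneConfig",
  representation(stemWidths = "integer", stageWidths = "integer",
                 trunkWidth = "integer", mlpRatio = "numeric",
                 outWidths = "integer", numClasses = "integer",
                 dropPath = "numeric", widthMultiplier = "numeric",
                 useCcib = "logical", useSss = "logical",
                 useScb = "logical", useCsfa = "logical",
                 starma = "StarMAConfig"))

setValidity("BackboneConfig", function(object) {
  if (length(object@stemWidths) != 2) return("stemWidths must have length 2")
  if (length(object@stageWidths) != 3) return("stageWidths must have length 3")
  if (length(object@outWidths) != 2) return("outWidths must have length 2")
  if (object@numClasses < 2) return("numClasses must be >= 2")
  if (object@dropPath < 0 || object@dropPath >= 1)
    return("dropPath must lie in [0, 1)")
  if (object@widthMultiplier <= 0) return("widthMultiplier must be positive")
  if (!object@useCcib && !object@useScb)
    return("at least one attention branch (CCIB or SCB) must be enabled")
  TRUE
})

#' Training configuration
#'
#' @slot learningRate numeric (default 1e-5).
#' @slot batchSize integer (default 16).
#' @slot epochs integer (default 100).
#' @slot optimizer `"adamw"` (default) or `"adam"`.
#' @slot weightDecay numeric, decoupled weight decay for adamw.
#' @slot lrSchedule `"constant"` (default) or `"cosine"` per-epoch decay.
#' @slot augment `"none"` (default) or `"flip"`: random horizontal/vertical
#'   flips of training batches.
#' @slot emaDecay numeric in `[0, 1)`; when positive, an exponential moving
#'   average of the weights is maintained during training and used as the
#'   final model (0 disables).
#' @slot resize two integers, target image size (default 224 x 224, bilinear).
#' @slot standardize logical; channel mean/sd standardization after the
#'   default divide-to-`[0,1]` scaling (off by default).
#' @slot seed integer controlling initialization, shuffling and any
#'   stochastic layers.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", optimizer = "character",
                 weightDecay = "numeric", lrSchedule = "character",
                 augment = "character", emaDecay = "numeric",
                 resize = "integer", standardize = "logical",
                 seed = "integer"),
  prototype(learningRate = 1e-5, batchSize = 16L, epochs = 100L,
            optimizer = "adamw", weightDecay = 0.01, lrSchedule = "constant",
            augment = "none", emaDecay = 0, resize = c(224L, 224L),
            standardize = FALSE, seed = 1L))

setValidity("TrainConfig", function(object) {
  if (!object@optimizer %in% c("adamw", "adam"))
    return("optimizer must be 'adamw' or 'adam'")
  if (!object@lrSchedule %in% c("constant", "cosine"))
    return("lrSchedule must be 'constant' or 'cosine'")
  if (!object@augment %in% c("none", "flip"))
    return("augment must be 'none' or 'flip'")
  if (object@emaDecay < 0 || object@emaDecay >= 1)
    return("emaDecay must lie in [0, 1)")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1 || object@epochs < 1)
    return("batchSize and epochs must be >= 1")
  TRUE
})

#' Confusion matrix
#'
#' K x K contingency table of true class (rows) against predicted class
#' (columns), the substrate from which all scalar classification metrics are
#' derived.  For K = 2 the second class (label 1) is the positive class.
#'
#' @slot counts K x K numeric matrix of non-negative counts.
#' @slot classLabels character vector of class names.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", classLabels = "character"))

setValidity("ConfusionMatrix", function(object) {
  if (nrow(object@counts) != ncol(object@counts))
    return("counts must be square")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@classLabels) != nrow(object@counts))
    return("classLabels length must match matrix order")
  TRUE
})

#' Classification metric report
#'
#' Scalar metrics derived from a confusion matrix (and, for AUC, from scores):
#' accuracy, precision, sensitivity (recall), specificity, F1, Matthews
#' correlation coefficient, Cohen's kappa and AUC, with either binary or
#' macro (one-vs-rest) averaging.
#'
#' @exportClass MetricReport
setClass("MetricReport",
  representation(accuracy = "numeric", precision = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 f1 = "numeric", mcc = "numeric", kappa = "numeric",
                 auc = "numeric", averaging = "character"))

#' ROC curve
#'
#' Threshold sweep of a binary scorer: aligned vectors of thresholds, false
#' positive rate and true positive rate, with the trapezoidal area under the
#' curve.
#'
#' @exportClass ROCCurve
setClass("ROCCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric", positiveClass = "character"))

setValidity("ROCCurve", function(object) {
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    return("fpr and tpr must be non-decreasing")
  TRUE
})

#' Model complexity report
#'
#' Layer-by-layer trainable parameter and multiply-accumulate counts with
#' totals.  One fused multiply-add counts as one MAC; only convolution and
#' fully-connected layers contribute (normalization, activations, pooling and
#' softmax are excluded), the convention under which the standard VGG19 and
#' ResNet34 budgets are reproduced.
#'
#' @exportClass ComplexityReport
setClass("ComplexityReport",
  representation(perLayer = "data.frame", totalParams = "numeric",
                 totalMacs = "numeric", inputSize = "integer"))

setValidity("ComplexityReport", function(object) {
  if (abs(sum(object@perLayer$params) - object@totalParams) > 0.5)
    return("totalParams must equal the per-layer sum")
  if (abs(sum(object@perLayer$macs) - object@totalMacs) > 0.5)
    return("totalMacs must equal the per-layer sum")
  TRUE
})

#' Synthetic lesion dataset specification
#'
#' Parametric description of a deterministic synthetic dataset: grayscale
#' images with one elliptical lesion each, drawn on a textured background
#' with multiplicative speckle (ultrasound-like) and additive Gaussian noise.
#' Classes differ by lesion size/eccentricity/texture, so they are separable
#' by construction, and every image records its lesion mask.
#'
#' @slot nClasses integer >= 2.
#' @slot counts per-class sample counts (supports class imbalance).
#' @slot imageSize two integers (H, W).
#' @slot classParams list, one list per class with elements `radiusRange`
#'   (px), `eccRange`, `contrast`, `textureFreq`, `textureAmp`.
#' @slot speckleVar variance of the multiplicative speckle field.
#' @slot gaussianSd sd of the additive Gaussian noise.
#' @slot seed integer; identical spec + seed gives bit-identical pixels.
#' @exportClass SyntheticImageSpec
setClass("SyntheticImageSpec",
  representation(nClasses = "integer", counts = "integer",
                 imageSize = "integer", classParams = "list",
                 speckleVar = "numeric", gaussianSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticImageSpec", function(object) {
  if (object@nClasses < 2) return("nClasses must be >= 2")
  if (length(object@counts) != object@nClasses)
    return("counts must have one entry per class")
  if (any(object@counts < 1)) return("every class needs at least one sample")
  if (length(object@classParams) != object@nClasses)
    return("classParams must have one entry per class")
  half <- min(object@imageSize) / 2
  for (p in object@classParams) {
    axis_max <- max(p$radiusRange) / sqrt(min(p$eccRange))
    if (axis_max >= half)
      return(sprintf("lesion axis %.1f does not fit an image of size %dx%d",
                     axis_max, object@imageSize[1], object@imageSize[2]))
  }
  TRUE
})

#' Labeled synthetic image set
#'
#' Materialized output of a [SyntheticImageSpec-class]: an (N, H, W) image
#' array in `[0, 1]`, integer labels in `[0, K)`, per-image logical lesion
#' masks and stratified train/val/test split assignments.
#'
#' @exportClass LabeledImageSet
setClass("LabeledImageSet",
  representation(images = "array", labels = "integer", masks = "array",
                 classNames = "character", split = "character",
                 spec = "ANY"))

setValidity("LabeledImageSet", function(object) {
  n <- dim(object@images)[1]
  if (length(object@labels) != n) return("one label per image required")
  if (length(object@split) != n && length(object@split) != 0)
    return("split must assign every image (or be empty)")
  if (any(object@labels < 0) ||
      any(object@labels >= length(object@classNames)))
    return("labels must lie in [0, K)")
  TRUE
})

#' StarMA attention module
#'
#' A trainable star-shaped multi-scale attention block for a fixed channel
#' count.  Wraps the mutable parameter store; apply it with [forwardPass()].
#'
#' @slot channels integer, input channel count C.
#' @slot config the [StarMAConfig-class] used to build it.
#' @slot state environment holding layers and caches.
#' @exportClass StarMAAttention
setClass("StarMAAttention",
  representation(channels = "integer", config = "StarMAConfig",
                 state = "environment"))

#' StarMA Net model
#'
#' A built classifier: input stream (stem and three Base Blocks), four StarMA
#' Blocks, output stream, with all weights and normalization buffers.
#'
#' @slot config the [BackboneConfig-class] used to build it.
#' @slot state environment holding the stage list and parameters.
#' @exportClass StarMANet
setClass("StarMANet",
  representation(config = "BackboneConfig", state = "environment"))
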