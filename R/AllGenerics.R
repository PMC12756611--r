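#' Apply a module to a feature map or image batch
#'
#' Runs the forward pass of a [StarMAAttention-class] module (input: a
#' (B, C, H, W) feature map, output: a re-weighted map of the same shape) or a
#' [StarMANet-class] model (input: a (B, 3, H, W) image batch, output: a
#' (B, K) logit matrix).
#'
#' @param object the module or model.
#' @param x numeric array, see above.
#' @param training logical; training mode enables batch statistics, caches
#'   and stochastic depth. Evaluation mode (default) is deterministic.
#' @return the transformed array.
#' @export
setGeneric("forwardPass", function(object, x, training = FALSE)
  standardGeneric("forwardPass"))

#' Count trainable parameters
#'
#' Sums the element counts of every trainable weight, bias and normalization
#' affine parameter.
#'
#' @param object a [StarMANet-class] model or an architecture descriptor list.
#' @param ... unused.
#' @return total parameter count (numeric, exact integer value).
#' @export
setGeneric("countParams", function(object, ...) standardGeneric("countParams"))

#' Count multiply-accumulate operations
#'
#' Counts MACs for one forward pass at the given input size, under the
#' convention that one fused multiply-add is one unit, convolutions cost
#' `out_ch * in_ch * kh * kw * H_out * W_out` (divided by the group count for
#' grouped convolutions), linear layers cost `in * out`, and normalization,
#' activations, pooling and softmax are free.
#'
#' @param object a [StarMANet-class] model or an architecture descriptor list.
#' @param inputSize integer `(H, W)` spatial input size (default 224 x 224).
#' @param ... unused.
#' @return total MAC count (numeric).
#' @export
setGeneric("countMacs", function(object, inputSize = c(224L, 224L), ...)
  standardGeneric("countMacs"))

#' Per-layer complexity report
#'
#' @param object a [StarMANet-class] model or an architecture descriptor list.
#' @param inputSize integer `(H, W)` spatial input size.
#' @param ... unused.
#' @return a [ComplexityReport-class].
#' @export
setGeneric("complexityReport", function(object, inputSize = c(224L, 224L), ...)
  standardGeneric("complexityReport"))
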