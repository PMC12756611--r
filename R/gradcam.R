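# Gradient-weighted class activation mapping.
#
# The class score's gradient at a chosen trunk stage is global-average-pooled
# per channel; those pooled gradients weight the stage's activation channels,
# the weighted sum is rectified, normalized to [0, 1] and bilinearly
# upsampled to the input size.  The default target is the output of the last
# StarMA Block, the deepest attention-bearing representation.

#' Grad-CAM heat map for one image
#'
#' @param model a [StarMANet-class].
#' @param image (H, W) grayscale matrix in `[0, 1]`, or a (1, 3, H, W) batch.
#' @param targetClass class index in `[0, K)` to explain; default is the
#'   predicted class.
#' @param targetStage index into the model's stage list; default is the last
#'   StarMA Block.  Out-of-range values raise a configuration error.
#' @param overlayPath optional PNG path: writes the heat map blended over
#'   the input image.
#' @return list with `heatmap` ((H, W) matrix in `[0, 1]` at input
#'   resolution), `targetClass`, `classScore`, `configHash`.
#' @export
gradCam <- function(model, image, targetClass = NULL, targetStage = NULL,
                    overlayPath = NULL) {
  st <- model@state
  n_stages <- length(st$stages)
  stage <- targetStage %||% st$trunk_stage
  if (stage < 1 || stage > n_stages)
    stop("targetStage must name an existing stage in 1..", n_stages)
  if (is.matrix(image)) {
    H <- nrow(image); W <- ncol(image)
    x <- array(0, c(1, 3, H, W))
    x[1, 1, , ] <- image; x[1, 2, , ] <- image; x[1, 3, , ] <- image
  } else {
    x <- image
    H <- dim(x)[3]; W <- dim(x)[4]
  }
  logits <- net_forward(model, x, training = "grad", record_stage = stage)
  act <- st$recorded
  st$recorded <- NULL
  k <- targetClass %||% (which.max(logits[1, ]) - 1L)
  dlogits <- matrix(0, 1, ncol(logits))
  dlogits[1, k + 1L] <- 1
  grad <- net_backward(model, dlogits, stop_after = stage)
  # channel weights: global-average-pooled gradients
  d <- dim(act)
  w <- rowMeans(matrix(grad, d[2], d[3] * d[4]))
  cam <- matrix(0, d[3], d[4])
  for (c in seq_len(d[2])) cam <- cam + w[c] * act[1, c, , ]
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  heat <- bilinear_resize(cam, H, W)
  heat <- pmin(pmax(heat, 0), 1)
  if (!is.null(overlayPath)) {
    gray <- x[1, 1, , ]
    rgb <- array(0, c(H, W, 3))
    rgb[, , 1] <- pmin(1, 0.6 * gray + 0.7 * heat)
    rgb[, , 2] <- 0.6 * gray
    rgb[, , 3] <- pmin(1, 0.6 * gray + 0.7 * (1 - heat) * 0.3)
    png::writePNG(rgb, overlayPath)
  }
  list(heatmap = heat, targetClass = as.integer(k),
       classScore = logits[1, k + 1L],
       configHash = config_hash(model@config))
}

#' Lesion-localization score of Grad-CAM maps
#'
#' For each test image, checks whether the mean heat inside the stored
#' lesion mask exceeds the mean outside -- the localization property a
#' lesion-focused classifier should satisfy.
#'
#' @param model a trained [StarMANet-class].
#' @param dataset a [LabeledImageSet-class] with masks.
#' @param split which split to score (default `"test"`).
#' @param maxImages optional cap on the number of images scored.
#' @return list with `fractionLocalized` (share of images where inside mean
#'   > outside mean) and `perImage` logical vector.
#' @export
gradCamLocalization <- function(model, dataset, split = "test",
                                maxImages = NULL) {
  idx <- which(dataset@split == split)
  if (!is.null(maxImages)) idx <- head(idx, maxImages)
  ok <- logical(length(idx))
  for (i in seq_along(idx)) {
    g <- gradCam(model, dataset@images[idx[i], , ],
                 targetClass = dataset@labels[idx[i]])
    m <- dataset@masks[idx[i], , ]
    if (!any(m) || all(m)) { ok[i] <- NA; next }
    ok[i] <- mean(g$heatmap[m]) > mean(g$heatmap[!m])
  }
  list(fractionLocalized = mean(ok, na.rm = TRUE), perImage = ok)
}
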