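# StarMA Net backbone.
#
# Input stream: two 3x3 stem convolutions (the first carries stride 2) and
# three Base Blocks (3x3 conv -> BatchNorm -> GELU -> 2x2 max pool ->
# DropPath), together performing four stages of spatial reduction
# (224 -> 112 -> 56 -> 28 -> 14).  Trunk: four StarMA Blocks at constant
# width and resolution.  Output stream: a Normal Block (Base Block without
# pooling), a stride-2 3x3 convolution (14 -> 7), a 1x1 convolution,
# BatchNorm, GELU, global average pooling and the classifier head.

#' Construct a StarMA Net backbone configuration
#'
#' The default widths are the package's frozen reference configuration,
#' calibrated once against the published parameter/MAC budget of the
#' architecture (about 47.5M parameters and 18.11G MACs at 224 x 224 with a
#' binary head); see [countParams()] and the methods vignette.
#'
#' @param stemWidths output channels of the two stem convolutions.
#' @param stageWidths output channels of the three Base Blocks.
#' @param trunkWidth channel width of the four StarMA Blocks.
#' @param mlpRatio expansion ratio of the block MLP.
#' @param outWidths channels of the output-stream stride-2 3x3 and 1x1
#'   convolutions.
#' @param numClasses number of target classes.
#' @param dropPath stochastic-depth rate (0 disables it; forward passes are
#'   then deterministic).
#' @param widthMultiplier global width scale; every width is multiplied and
#'   rounded to the nearest multiple of the attention group count
#'   (0.5 gives the channel-halved variant).
#' @param useCcib,useSss,useScb,useCsfa ablation switches for the attention
#'   block's sub-modules.
#' @param starma a [StarMAConfig-class].
#' @return a [BackboneConfig-class].
#' @export
backboneConfig <- function(stemWidths = c(64L, 128L),
                           stageWidths = c(264L, 320L, 512L),
                           trunkWidth = 512L,
                           mlpRatio = 4,
                           outWidths = c(800L, 1024L),
                           numClasses = 2L,
                           dropPath = 0,
                           widthMultiplier = 1,
                           useCcib = TRUE, useSss = TRUE,
                           useScb = TRUE, useCsfa = TRUE,
                           starma = starMAConfig()) {
  new("BackboneConfig",
      stemWidths = as.integer(stemWidths),
      stageWidths = as.integer(stageWidths),
      trunkWidth = as.integer(trunkWidth),
      mlpRatio = as.numeric(mlpRatio),
      outWidths = as.integer(outWidths),
      numClasses = as.integer(numClasses),
      dropPath = as.numeric(dropPath),
      widthMultiplier = as.numeric(widthMultiplier),
      useCcib = useCcib, useSss = useSss, useScb = useScb, useCsfa = useCsfa,
      starma = starma)
}

# Resolve the effective channel widths after the global width multiplier,
# rounding to the nearest positive multiple of the attention group count.
effective_widths <- function(cfg) {
  g <- cfg@starma@groups
  scale <- function(w) pmax(g, as.integer(round(w * cfg@widthMultiplier / g) * g))
  list(stem = scale(cfg@stemWidths), stages = scale(cfg@stageWidths),
       trunk = scale(cfg@trunkWidth), out = scale(cfg@outWidths),
       mlp_hidden = scale(round(cfg@trunkWidth * cfg@mlpRatio)))
}

## ---- StarMA Block ----------------------------------------------------------

smblock_new <- function(width, mlp_hidden, cfg) {
  st <- new.env(parent = emptyenv())
  st$conv1 <- conv_new(width, width, 3)
  st$conv2 <- conv_new(width, width, 3)
  st$bn <- bn_new(width)
  st$att <- attention_state_new(width, cfg@starma)
  st$att$flags <- list(ccib = cfg@useCcib, sss = cfg@useSss,
                       scb = cfg@useScb, csfa = cfg@useCsfa)
  st$conv3 <- conv_new(width, width, 3)
  st$dp_attn <- droppath_new(cfg@dropPath)
  st$mlp1 <- conv_new(width, mlp_hidden, 1)
  st$mlp2 <- conv_new(mlp_hidden, width, 1)
  st$dp_mlp <- droppath_new(cfg@dropPath)
  st$width <- width
  st
}

smblock_layers <- function(st) {
  c(list(st$conv1, st$conv2, st$bn, st$conv3, st$mlp1, st$mlp2),
    attention_layers(st$att))
}

# x_a = Conv3x3(GELU(StarMA(BN(Conv3x3(Conv3x3(x)))))); x_attn = DropPath(x_a) + x;
# M = MLP(x_attn); output = GELU(DropPath(M) + x_attn)
smblock_fwd <- function(st, x, training = FALSE) {
  if (dim(x)[2] != st$width)
    stop("StarMA Block expects ", st$width, " channels, got ", dim(x)[2])
  a1 <- conv_fwd(st$conv1, x, training)
  a2 <- conv_fwd(st$conv2, a1, training)
  bnx <- bn_fwd(st$bn, a2, training)
  at <- att_forward(st$att, bnx, training)
  Fa <- pnorm(at)
  xa <- conv_fwd(st$conv3, at * Fa, training)
  da <- droppath_fwd(st$dp_attn, xa, training)
  xattn <- da + x
  m1 <- conv_fwd(st$mlp1, xattn, training)
  Fm <- pnorm(m1)
  m2 <- conv_fwd(st$mlp2, m1 * Fm, training)
  dm <- droppath_fwd(st$dp_mlp, m2, training)
  pre <- dm + xattn
  Fp <- pnorm(pre)
  if (!isFALSE(training))
    st$cache <- list(g_at = Fa + at * dnorm(at), g_m1 = Fm + m1 * dnorm(m1),
                     g_pre = Fp + pre * dnorm(pre))
  pre * Fp
}

smblock_bwd <- function(st, dout) {
  ca <- st$cache
  dpre <- dout * ca$g_pre
  dxattn <- dpre
  dm2 <- droppath_bwd(st$dp_mlp, dpre)
  dgm <- conv_bwd(st$mlp2, dm2)
  dm1 <- dgm * ca$g_m1
  dxattn <- dxattn + conv_bwd(st$mlp1, dm1)
  dxa <- droppath_bwd(st$dp_attn, dxattn)
  dga <- conv_bwd(st$conv3, dxa)
  dat <- dga * ca$g_at
  dbn <- att_backward(st$att, dat)
  da2 <- bn_bwd(st$bn, dbn)
  da1 <- conv_bwd(st$conv2, da2)
  dx <- dxattn + conv_bwd(st$conv1, da1)
  st$cache <- NULL
  dx
}

## ---- network assembly ------------------------------------------------------

stage_new <- function(kind, layer) {
  s <- new.env(parent = emptyenv())
  s$kind <- kind
  s$layer <- layer
  s
}

build_stages <- function(cfg) {
  w <- effective_widths(cfg)
  stages <- list()
  add <- function(kind, layer = NULL) stages[[length(stages) + 1]] <<- stage_new(kind, layer)
  # stem: first convolution carries the stride-2 reduction
  add("conv", conv_new(3L, w$stem[1], 3, sh = 2))
  add("bn", bn_new(w$stem[1])); add("gelu", gelu_stage_new())
  add("conv", conv_new(w$stem[1], w$stem[2], 3))
  add("bn", bn_new(w$stem[2])); add("gelu", gelu_stage_new())
  # three Base Blocks
  cin <- w$stem[2]
  for (wi in w$stages) {
    add("conv", conv_new(cin, wi, 3))
    add("bn", bn_new(wi)); add("gelu", gelu_stage_new())
    add("maxpool", maxpool_new())
    add("droppath", droppath_new(cfg@dropPath))
    cin <- wi
  }
  if (cin != w$trunk)
    stop("third stage width must equal trunkWidth (got ", cin, " vs ", w$trunk, ")")
  # four StarMA Blocks
  for (i in 1:4) add("smblock", smblock_new(w$trunk, w$mlp_hidden, cfg))
  # output stream: Normal Block (Base Block without pooling), stride-2 3x3,
  # 1x1, BN, GELU, GAP, classifier
  add("conv", conv_new(w$trunk, w$trunk, 3))
  add("bn", bn_new(w$trunk)); add("gelu", gelu_stage_new())
  add("conv", conv_new(w$trunk, w$out[1], 3, sh = 2))
  add("conv", conv_new(w$out[1], w$out[2], 1))
  add("bn", bn_new(w$out[2])); add("gelu", gelu_stage_new())
  add("gap", gap_new())
  add("fc", lin_new(w$out[2], cfg@numClasses))
  stages
}

#' Build a StarMA Net classifier
#'
#' Assembles the full backbone under the configuration's seed: weights are
#' truncated-normal (sd 0.02), biases zero, BatchNorm affines at identity.
#' The trunk is fully convolutional, so any input size whose spatial
#' dimensions survive the five stride-2 reductions (e.g. multiples of 32)
#' produces valid logits.
#'
#' @param config a [BackboneConfig-class].
#' @param seed optional integer overriding `config@starma@seed` for weight
#'   initialization.
#' @return a [StarMANet-class].
#' @export
buildStarMANet <- function(config = backboneConfig(), seed = NULL) {
  validObject(config)
  w <- effective_widths(config)
  g <- config@starma@groups
  widths <- c(w$stem, w$stages, w$trunk, w$out)
  if (any(widths %% g != 0))
    stop("all widths must be divisible by the attention group count ", g)
  st <- with_seed(seed %||% config@starma@seed, {
    e <- new.env(parent = emptyenv())
    e$stages <- build_stages(config)
    e
  })
  st$trunk_stage <- max(which(vapply(st$stages, function(s) s$kind, "") == "smblock"))
  new("StarMANet", config = config, state = st)
}

net_layers <- function(net) {
  out <- list()
  for (s in net@state$stages) {
    if (s$kind == "smblock") out <- c(out, smblock_layers(s$layer))
    else if (!is.null(s$layer) && length(s$layer$par) > 0) out <- c(out, list(s$layer))
  }
  out
}

stage_fwd <- function(s, x, training) {
  switch(s$kind,
         conv = conv_fwd(s$layer, x, training),
         bn = bn_fwd(s$layer, x, training),
         gelu = gelu_stage_fwd(s$layer, x, training),
         maxpool = maxpool_fwd(s$layer, x, training),
         droppath = droppath_fwd(s$layer, x, training),
         smblock = smblock_fwd(s$layer, x, training),
         gap = gap_fwd(s$layer, x, training),
         fc = lin_fwd(s$layer, x, training),
         stop("unknown stage kind ", s$kind))
}

stage_bwd <- function(s, dy) {
  switch(s$kind,
         conv = conv_bwd(s$layer, dy),
         bn = bn_bwd(s$layer, dy),
         gelu = gelu_stage_bwd(s$layer, dy),
         maxpool = maxpool_bwd(s$layer, dy),
         droppath = droppath_bwd(s$layer, dy),
         smblock = smblock_bwd(s$layer, dy),
         gap = gap_bwd(s$layer, dy),
         fc = lin_bwd(s$layer, dy),
         stop("unknown stage kind ", s$kind))
}

# Forward through all stages.  `record_stage` stores that stage's output
# activation in net$state$recorded (used by Grad-CAM).
net_forward <- function(net, x, training = FALSE, record_stage = NULL) {
  st <- net@state
  for (i in seq_along(st$stages)) {
    x <- stage_fwd(st$stages[[i]], x, training)
    if (!is.null(record_stage) && i == record_stage) st$recorded <- x
  }
  x
}

# Backward from logit gradients.  Stops early (returning the gradient flowing
# INTO stage `stop_after`'s output) when requested.
net_backward <- function(net, dlogits, stop_after = NULL) {
  st <- net@state
  dy <- dlogits
  for (i in rev(seq_along(st$stages))) {
    if (!is.null(stop_after) && i == stop_after) return(dy)
    dy <- stage_bwd(st$stages[[i]], dy)
  }
  dy
}

#' @describeIn forwardPass run the classifier on a (B, 3, H, W) image batch;
#'   returns a (B, numClasses) logit matrix.
#' @export
setMethod("forwardPass", "StarMANet", function(object, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[2] != 3)
    stop("expected a (B, 3, H, W) image batch, got dims (",
         paste(d, collapse = ", "), ")")
  net_forward(object, x, training)
})

setMethod("show", "StarMANet", function(object) {
  w <- effective_widths(object@config)
  cat("StarMA Net classifier\n")
  cat("  stem:", paste(w$stem, collapse = " -> "),
      " stages:", paste(w$stages, collapse = " -> "),
      " trunk:", w$trunk, "x4 blocks\n")
  cat("  output stream:", paste(w$out, collapse = " -> "),
      " classes:", object@config@numClasses, "\n")
  cat("  widthMultiplier:", object@config@widthMultiplier,
      " dropPath:", object@config@dropPath, "\n")
  fl <- c(CCIB = object@config@useCcib, SSS = object@config@useSss,
          SCB = object@config@useScb, CSFA = object@config@useCsfa)
  cat("  attention flags:", paste(names(fl)[fl], collapse = " + "), "\n")
  cat("  parameters:", format(countParams(object), big.mark = ","), "\n")
})

#' Build an ablated model variant
#'
#' Rewires the attention blocks according to the four sub-module switches
#' while keeping everything else (and the weight-init seed) identical: with
#' the star-shape structure off, the star-gate factors are dropped from the
#' CCIB product; with CSFA off, the two branches fuse as
#' `sigmoid(x1 + x2) * x_group`; with a single branch, its own channel-pooled
#' softmax-weighted map forms the gate.  All switches on reproduces the full
#' model bit-exactly.
#'
#' @param config a [BackboneConfig-class].
#' @param useCcib,useSss,useScb,useCsfa the switches to apply.
#' @return a [StarMANet-class].
#' @export
applyAblation <- function(config, useCcib = config@useCcib,
                          useSss = config@useSss, useScb = config@useScb,
                          useCsfa = config@useCsfa) {
  config@useCcib <- useCcib
  config@useSss <- useSss
  config@useScb <- useScb
  config@useCsfa <- useCsfa
  validObject(config)
  buildStarMANet(config)
}

## ---- configuration serialization -------------------------------------------

#' Write / read a backbone configuration as YAML
#'
#' Every field is explicit, so configurations round-trip losslessly.
#'
#' @param config a [BackboneConfig-class].
#' @param path file path.
#' @return `writeBackboneConfig` returns `path` invisibly;
#'   `readBackboneConfig` returns the [BackboneConfig-class].
#' @export
writeBackboneConfig <- function(config, path) {
  sm <- config@starma
  obj <- list(
    stemWidths = config@stemWidths, stageWidths = config@stageWidths,
    trunkWidth = config@trunkWidth, mlpRatio = config@mlpRatio,
    outWidths = config@outWidths, numClasses = config@numClasses,
    dropPath = config@dropPath, widthMultiplier = config@widthMultiplier,
    useCcib = config@useCcib, useSss = config@useSss,
    useScb = config@useScb, useCsfa = config@useCsfa,
    starma = list(groups = sm@groups, scbKernels = sm@scbKernels,
                  starUpsample = sm@starUpsample, seed = sm@seed))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeBackboneConfig
#' @export
readBackboneConfig <- function(path) {
  o <- yaml::read_yaml(path)
  backboneConfig(
    stemWidths = o$stemWidths, stageWidths = o$stageWidths,
    trunkWidth = o$trunkWidth, mlpRatio = o$mlpRatio,
    outWidths = o$outWidths, numClasses = o$numClasses,
    dropPath = o$dropPath, widthMultiplier = o$widthMultiplier,
    useCcib = o$useCcib, useSss = o$useSss,
    useScb = o$useScb, useCsfa = o$useCsfa,
    starma = starMAConfig(groups = o$starma$groups,
                          scbKernels = o$starma$scbKernels,
                          starUpsample = o$starma$starUpsample,
                          seed = o$starma$seed))
}
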