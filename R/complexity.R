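# Parameter and multiply-accumulate accounting.
#
# Architectures are walked as descriptor lists; one fused multiply-add is one
# MAC, convolutions cost out_ch*in_ch*kh*kw*Hout*Wout (times the group count
# for the attention convolutions, which run once per channel group with
# shared weights), linear layers cost in*out, and normalization, activations,
# pooling, softmax and the data-data matrix products of the fusion stage are
# free.  This is the convention under which the standard VGG19 (143.67M
# params, 19.63G MACs) and ResNet34 (21.8M, 3.66G) budgets at 224 x 224 are
# reproduced, and the reference StarMA Net configuration is calibrated to its
# published budget under the same convention.

conv_desc <- function(name, cin, cout, k, stride = 1, pad = (k - 1) %/% 2,
                      bias = TRUE, mult = 1, track = TRUE, len = NULL) {
  list(name = name, kind = "conv", cin = cin, cout = cout, kh = k, kw = k,
       sh = stride, sw = stride, ph = pad, pw = pad, bias = bias,
       mult = mult, track = track, len = len)
}
norm_desc <- function(name, C) list(name = name, kind = "norm", C = C)
pool_desc <- function(name, k = 2, stride = k)
  list(name = name, kind = "pool", k = k, stride = stride)
gap_desc <- function(name = "gap") list(name = name, kind = "gap")
fc_desc <- function(name, cin, cout)
  list(name = name, kind = "fc", cin = cin, cout = cout)
att_desc <- function(name, K, G, kernels = c(1L, 5L, 7L))
  list(name = name, kind = "att", K = K, G = G, kernels = kernels)

# Walk a descriptor list at a given input size, returning per-layer rows.
count_arch <- function(arch, inputSize = c(224L, 224L), in_channels = 3L) {
  H <- inputSize[1]; W <- inputSize[2]; C <- in_channels
  rows <- list()
  add <- function(name, kind, params, macs)
    rows[[length(rows) + 1]] <<- data.frame(name = name, kind = kind,
                                            params = params, macs = macs)
  for (d in arch) {
    if (d$kind == "conv") {
      if (is.null(d$len)) {
        Ho <- (H + 2 * d$ph - d$kh) %/% d$sh + 1
        Wo <- (W + 2 * d$pw - d$kw) %/% d$sw + 1
      } else {                         # 1-D strip convolution (star gates)
        Ho <- d$len; Wo <- 1
      }
      params <- d$cout * d$cin * d$kh * d$kw + if (isTRUE(d$bias)) d$cout else 0
      macs <- as.numeric(d$cout) * d$cin * d$kh * d$kw * Ho * Wo * d$mult
      add(d$name, "conv", params, macs)
      if (isTRUE(d$track)) { H <- Ho; W <- Wo; C <- d$cout }
    } else if (d$kind == "norm") {
      add(d$name, "norm", 2 * d$C, 0)
    } else if (d$kind == "pool") {
      H <- H %/% d$stride; W <- W %/% d$stride
    } else if (d$kind == "gap") {
      H <- 1; W <- 1
    } else if (d$kind == "fc") {
      cin <- if (identical(d$cin, "flatten")) C * H * W else d$cin
      add(d$name, "fc", cin * d$cout + d$cout, as.numeric(cin) * d$cout)
    } else if (d$kind == "att") {
      K <- d$K; G <- d$G; Ld <- ceiling((H + W) / 2)
      for (k in d$kernels)
        add(paste0(d$name, ".scb", k, "x", k), "conv",
            K * K * k * k + K, as.numeric(K) * K * k * k * H * W * G)
      add(paste0(d$name, ".star_down"), "conv", K * K + K,
          as.numeric(K) * K * Ld * G)
      add(paste0(d$name, ".star_f"), "conv", K * K + K,
          as.numeric(K) * K * Ld * G)
      add(paste0(d$name, ".star_g"), "conv", K * K + K,
          as.numeric(K) * K * Ld * G)
      add(paste0(d$name, ".gn"), "norm", 2 * K, 0)
    } else stop("unknown descriptor kind ", d$kind)
  }
  do.call(rbind, rows)
}

#' Architecture descriptors for complexity accounting
#'
#' `starmaNetArch` expands a [BackboneConfig-class] into the descriptor list
#' the accountant walks; `vgg19Arch` and `resnet34Arch` build the two
#' standard reference classifiers (1000-class heads) used to calibrate the
#' counting convention.
#'
#' @param config a [BackboneConfig-class].
#' @return a descriptor list consumable by [countParams()], [countMacs()]
#'   and [complexityReport()].
#' @export
starmaNetArch <- function(config = backboneConfig()) {
  w <- effective_widths(config)
  g <- config@starma@groups
  K <- w$trunk %/% g
  a <- list()
  p <- function(d) a[[length(a) + 1]] <<- d
  p(conv_desc("stem.conv1", 3, w$stem[1], 3, stride = 2))
  p(norm_desc("stem.bn1", w$stem[1]))
  p(conv_desc("stem.conv2", w$stem[1], w$stem[2], 3))
  p(norm_desc("stem.bn2", w$stem[2]))
  cin <- w$stem[2]
  for (i in 1:3) {
    p(conv_desc(sprintf("base%d.conv", i), cin, w$stages[i], 3))
    p(norm_desc(sprintf("base%d.bn", i), w$stages[i]))
    p(pool_desc(sprintf("base%d.pool", i)))
    cin <- w$stages[i]
  }
  for (i in 1:4) {
    nm <- sprintf("block%d", i)
    p(conv_desc(paste0(nm, ".conv1"), w$trunk, w$trunk, 3))
    p(conv_desc(paste0(nm, ".conv2"), w$trunk, w$trunk, 3))
    p(norm_desc(paste0(nm, ".bn"), w$trunk))
    p(att_desc(paste0(nm, ".att"), K, g, config@starma@scbKernels))
    p(conv_desc(paste0(nm, ".conv3"), w$trunk, w$trunk, 3))
    p(conv_desc(paste0(nm, ".mlp1"), w$trunk, w$mlp_hidden, 1))
    p(conv_desc(paste0(nm, ".mlp2"), w$mlp_hidden, w$trunk, 1))
  }
  p(conv_desc("out.normal", w$trunk, w$trunk, 3))
  p(norm_desc("out.normal_bn", w$trunk))
  p(conv_desc("out.conv3x3s2", w$trunk, w$out[1], 3, stride = 2))
  p(conv_desc("out.conv1x1", w$out[1], w$out[2], 1))
  p(norm_desc("out.bn", w$out[2]))
  p(gap_desc())
  p(fc_desc("head", w$out[2], config@numClasses))
  a
}

#' @rdname starmaNetArch
#' @param numClasses classifier head size of the reference model.
#' @export
vgg19Arch <- function(numClasses = 1000L) {
  plan <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
               c(512, 512, 512, 512), c(512, 512, 512, 512))
  a <- list(); cin <- 3; li <- 0
  for (bi in seq_along(plan)) {
    for (w in plan[[bi]]) {
      li <- li + 1
      a[[length(a) + 1]] <- conv_desc(sprintf("conv%d", li), cin, w, 3)
      cin <- w
    }
    a[[length(a) + 1]] <- pool_desc(sprintf("pool%d", bi))
  }
  a[[length(a) + 1]] <- fc_desc("fc6", "flatten", 4096)
  a[[length(a) + 1]] <- fc_desc("fc7", 4096, 4096)
  a[[length(a) + 1]] <- fc_desc("fc8", 4096, numClasses)
  a
}

#' @rdname starmaNetArch
#' @export
resnet34Arch <- function(numClasses = 1000L) {
  a <- list()
  p <- function(d) a[[length(a) + 1]] <<- d
  p(conv_desc("conv1", 3, 64, 7, stride = 2, pad = 3, bias = FALSE))
  p(norm_desc("bn1", 64))
  p(pool_desc("maxpool", k = 2, stride = 2))   # 3x3/2 pool: same 56x56 output
  blocks <- list(c(64, 3), c(128, 4), c(256, 6), c(512, 3))
  cin <- 64
  for (bi in seq_along(blocks)) {
    w <- blocks[[bi]][1]; n <- blocks[[bi]][2]
    for (j in seq_len(n)) {
      s <- if (bi > 1 && j == 1) 2 else 1
      nm <- sprintf("layer%d.%d", bi, j)
      p(conv_desc(paste0(nm, ".conv1"), cin, w, 3, stride = s, bias = FALSE))
      p(norm_desc(paste0(nm, ".bn1"), w))
      p(conv_desc(paste0(nm, ".conv2"), w, w, 3, bias = FALSE))
      p(norm_desc(paste0(nm, ".bn2"), w))
      if (s == 2 || cin != w) {
        # projection shortcut, emitted after the strided 3x3 so the tracker
        # already sits at the block's output resolution; stride 1 here
        # because its output size is what the MAC count needs
        p(conv_desc(paste0(nm, ".downsample"), cin, w, 1, stride = 1,
                    pad = 0, bias = FALSE, track = FALSE))
        p(norm_desc(paste0(nm, ".downsample_bn"), w))
      }
      cin <- w
    }
  }
  p(gap_desc())
  p(fc_desc("fc", 512, numClasses))
  a
}

## ---- generics over descriptor lists and models ------------------------------

#' @describeIn countParams analytic count over an architecture descriptor list.
#' @export
setMethod("countParams", "list", function(object, ...) {
  sum(count_arch(object)$params)
})

#' @describeIn countParams exact count over a built model's parameter arrays.
#' @export
setMethod("countParams", "StarMANet", function(object, ...) {
  sum(vapply(net_layers(object),
             function(L) sum(vapply(L$par, length, 0)), 0))
})

#' @describeIn countMacs count over an architecture descriptor list.
#' @export
setMethod("countMacs", "list", function(object, inputSize = c(224L, 224L), ...) {
  sum(count_arch(object, as.integer(inputSize))$macs)
})

#' @describeIn countMacs count for a built model (derived from its
#'   configuration; batch-size independent).
#' @export
setMethod("countMacs", "StarMANet", function(object, inputSize = c(224L, 224L), ...) {
  sum(count_arch(starmaNetArch(object@config), as.integer(inputSize))$macs)
})

.make_report <- function(arch, inputSize) {
  tab <- count_arch(arch, as.integer(inputSize))
  new("ComplexityReport", perLayer = tab,
      totalParams = sum(tab$params), totalMacs = sum(tab$macs),
      inputSize = as.integer(inputSize))
}

#' @describeIn complexityReport report over an architecture descriptor list.
#' @export
setMethod("complexityReport", "list", function(object, inputSize = c(224L, 224L), ...) {
  .make_report(object, inputSize)
})

#' @describeIn complexityReport report for a built model.
#' @export
setMethod("complexityReport", "StarMANet", function(object, inputSize = c(224L, 224L), ...) {
  .make_report(starmaNetArch(object@config), inputSize)
})

setMethod("show", "ComplexityReport", function(object) {
  cat(sprintf("ComplexityReport at %dx%d input\n",
              object@inputSize[1], object@inputSize[2]))
  cat(sprintf("  layers: %d   params: %.2fM   MACs: %.2fG\n",
              nrow(object@perLayer), object@totalParams / 1e6,
              object@totalMacs / 1e9))
  top <- head(object@perLayer[order(-object@perLayer$macs), ], 5)
  cat("  heaviest layers (MACs):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-22s %12s params %14s MACs\n", top$name[i],
                format(top$params[i], big.mark = ","),
                format(top$macs[i], big.mark = ",")))
})

#' Channel-coupling proxy statistics
#'
#' Quantifies inter-channel interaction from a batch of per-channel attention
#' weight vectors: `cci` is the mean absolute off-diagonal Pearson
#' correlation between channels' weights across samples (a documented proxy
#' for a channel-coupling index; identical channels give 1, independent
#' channels approach 0), and `weightVariance` is the mean per-sample variance
#' of the channel weights (zero when each sample's weights are constant
#' across channels).
#'
#' @param weights numeric (nSamples, nChannels) matrix of attention weights.
#' @return list with `cci` and `weightVariance`.
#' @export
channelCouplingProxy <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 2)
    stop("need at least 2 samples to estimate channel coupling")
  cm <- suppressWarnings(cor(weights))
  cm[is.na(cm)] <- 1                 # constant channels: perfectly coupled
  off <- abs(cm[upper.tri(cm) | lower.tri(cm)])
  list(cci = mean(off),
       weightVariance = mean(apply(weights, 1, var)))
}

#' Per-channel attention weights of a StarMA block
#'
#' Collects, for each input sample, the spatial mean of the CCIB gate product
#' for every channel -- the per-channel re-weighting profile the coupling
#' proxy consumes.
#'
#' @param module a [StarMAAttention-class].
#' @param x a (B, C, H, W) feature-map batch.
#' @return numeric (B, C) matrix.
#' @export
attentionChannelWeights <- function(module, x) {
  st <- module@state
  d <- dim(x); B <- d[1]; C <- d[2]
  xg <- groupFeatures(x, st$G)
  invisible(ccib_fwd(st, xg, training = TRUE))
  P <- st$ccib_cache$P
  st$ccib_cache <- NULL
  st$star_cache <- NULL
  dg <- dim(xg)
  pm <- matrix(rowMeans(matrix(P, dg[1] * dg[2], dg[3] * dg[4])), dg[1], dg[2])
  out <- matrix(0, B, C)
  K <- st$K
  for (g in seq_len(st$G))
    out[, ((g - 1) * K + 1):(g * K)] <- pm[((g - 1) * B + 1):(g * B), ]
  out
}
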