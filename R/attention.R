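# Star-shaped multi-scale attention (StarMA).
#
# The block splits channels into G groups folded into the batch axis, runs two
# parallel branches on each group -- a cross-channel information interaction
# branch (CCIB: axial average pooling, sigmoid gates and a star-shape gate
# strip) and a stacked convolution branch (SCB: 1x1 -> 5x5 -> 7x7 -> GELU) --
# fuses them by cross-spatial feature aggregation (CSFA: mutual
# channel-softmax x spatial-map products), gates the grouped input with the
# sigmoid of the fused map, and regroups.  Output shape always equals input
# shape and |output| <= |input| elementwise because every fused factor is a
# sigmoid output.

#' Construct a StarMA configuration
#'
#' @param groups number of channel groups G processed in parallel (default 8).
#' @param scbKernels kernel sizes of the stacked convolution branch, in
#'   application order.
#' @param starUpsample `"nearest"` or `"linear"` restoration of the
#'   downsampled star-gate strip.
#' @param seed integer seed for weight initialization.
#' @return a [StarMAConfig-class].
#' @export
starMAConfig <- function(groups = 8L, scbKernels = c(1L, 5L, 7L),
                         starUpsample = "nearest", seed = 1L) {
  new("StarMAConfig", groups = as.integer(groups),
      scbKernels = as.integer(scbKernels),
      starUpsample = as.character(starUpsample), seed = as.integer(seed))
}

#' Split a feature map into channel groups
#'
#' Divides the C channels of a (B, C, H, W) feature map into G contiguous
#' groups and folds the group index into the batch axis, giving a
#' (B*G, C/G, H, W) array.  Channel k of group g maps to source channel
#' `g*(C/G) + k` (0-based).  [ungroupFeatures()] is its exact inverse.
#'
#' @param x numeric (B, C, H, W) array.
#' @param groups integer G; C must be divisible by G.
#' @return numeric (B*G, C/G, H, W) array.
#' @export
groupFeatures <- function(x, groups) {
  d <- dim(x)
  if (length(d) != 4) stop("x must be a (B, C, H, W) array")
  if (d[2] %% groups != 0)
    stop("channel count C = ", d[2], " is not divisible by groups G = ", groups)
  K <- d[2] %/% groups
  dim(x) <- c(d[1], K, groups, d[3], d[4])
  x <- aperm(x, c(1, 3, 2, 4, 5))
  dim(x) <- c(d[1] * groups, K, d[3], d[4])
  x
}

#' Undo [groupFeatures()]
#'
#' @param xg numeric (B*G, C/G, H, W) array produced by [groupFeatures()].
#' @param groups the G used to group.
#' @return the original (B, C, H, W) array, bit-exactly.
#' @export
ungroupFeatures <- function(xg, groups) {
  d <- dim(xg)
  B <- d[1] %/% groups
  dim(xg) <- c(B, groups, d[2], d[3], d[4])
  xg <- aperm(xg, c(1, 3, 2, 4, 5))
  dim(xg) <- c(B, d[2] * groups, d[3], d[4])
  xg
}

#' Axial average pooling
#'
#' Collapses each spatial axis of a grouped feature map into a directional
#' descriptor: `xH[b, c, h, 1]` is the mean over the width axis of row h and
#' `xW[b, c, 1, w]` the mean over the height axis of column w, so the pair
#' retains per-height and per-width spatial structure at 1-D cost.
#'
#' @param xg numeric (M, K, H, W) array (grouped feature map).
#' @return list with `xH` (M, K, H, 1) and `xW` (M, K, 1, W).
#' @export
axialPool <- function(xg) {
  d <- dim(xg); M <- d[1]; K <- d[2]; H <- d[3]; W <- d[4]
  xH <- rowMeans(matrix(xg, M * K * H, W))
  dim(xH) <- c(M, K, H, 1)
  xW <- colSums(aperm(array(xg, c(M * K, H, W)), c(2, 1, 3))) / H
  dim(xW) <- c(M, K, 1, W)
  list(xH = xH, xW = xW)
}

## ---- internal module construction -----------------------------------------

# Build the trainable state for one attention block acting on K = C/G channels
# per group.  Layers are shared across groups (groups ride the batch axis).
attention_state_new <- function(channels, cfg) {
  G <- cfg@groups
  if (channels %% G != 0)
    stop("channel count C = ", channels, " is not divisible by groups G = ", G)
  K <- channels %/% G
  ks <- cfg@scbKernels
  st <- new.env(parent = emptyenv())
  st$G <- G; st$K <- K; st$channels <- channels
  st$upsample <- cfg@starUpsample
  # star-shape structure: stride-2 1x1 downsampling along the H+W strip, then
  # two parallel width-preserving 1x1 maps whose product forms the star
  st$star_down <- conv_new(K, K, 1, 1, sh = 2, sw = 1, ph = 0, pw = 0)
  st$star_f <- conv_new(K, K, 1, 1, ph = 0, pw = 0)
  st$star_g <- conv_new(K, K, 1, 1, ph = 0, pw = 0)
  # stacked convolution branch, same padding, constant width
  st$scb1 <- conv_new(K, K, ks[1], ks[1])
  st$scb2 <- conv_new(K, K, ks[2], ks[2])
  st$scb3 <- conv_new(K, K, ks[3], ks[3])
  # per-channel group normalization feeding the CSFA channel descriptor
  st$gn <- gn_new(K)
  st$flags <- list(ccib = TRUE, sss = TRUE, scb = TRUE, csfa = TRUE)
  st
}

attention_layers <- function(st) {
  ly <- list(st$scb1, st$scb2, st$scb3, st$gn)
  c(ly, list(st$star_down, st$star_f, st$star_g))
}

#' Construct a StarMA attention module
#'
#' Builds a trainable attention block for feature maps with `channels`
#' channels.  Weights are truncated-normal (sd 0.02) initialized under
#' `config@seed`; biases start at zero.  Apply with [forwardPass()] or the
#' branch-level operations [ccib()], [scb()], [csfa()].
#'
#' @param channels input channel count C; must be divisible by
#'   `config@groups`.
#' @param config a [StarMAConfig-class].
#' @return a [StarMAAttention-class].
#' @export
starmaAttention <- function(channels, config = starMAConfig()) {
  st <- with_seed(config@seed, attention_state_new(as.integer(channels), config))
  new("StarMAAttention", channels = as.integer(channels), config = config,
      state = st)
}

# nearest / linear 1-D upsampling of a gate strip (M, K, Ld, 1) -> length L.
# Returns the upsampled strip plus the weights needed for the adjoint.
strip_upsample <- function(p, L, mode) {
  Ld <- dim(p)[3]
  if (mode == "nearest") {
    idx <- floor((seq_len(L) - 1) * Ld / L) + 1
    list(up = p[, , idx, , drop = FALSE], idx = idx)
  } else {
    pos <- (seq_len(L) - 0.5) * Ld / L - 0.5
    i0 <- pmin(pmax(floor(pos), 0), Ld - 1)
    i1 <- pmin(i0 + 1, Ld - 1)
    w1 <- pmin(pmax(pos - i0, 0), 1)
    up <- p[, , i0 + 1, , drop = FALSE] * rep(1 - w1, each = dim(p)[1] * dim(p)[2])
    up <- up + p[, , i1 + 1, , drop = FALSE] * rep(w1, each = dim(p)[1] * dim(p)[2])
    list(up = up, i0 = i0 + 1, i1 = i1 + 1, w1 = w1)
  }
}

strip_upsample_bwd <- function(dup, us, Ld, mode) {
  d <- dim(dup); M <- d[1]; K <- d[2]; L <- d[3]
  dp <- array(0, c(M, K, Ld, 1))
  if (mode == "nearest") {
    for (i in seq_len(L))
      dp[, , us$idx[i], 1] <- dp[, , us$idx[i], 1] + dup[, , i, 1]
  } else {
    for (i in seq_len(L)) {
      dp[, , us$i0[i], 1] <- dp[, , us$i0[i], 1] + (1 - us$w1[i]) * dup[, , i, 1]
      dp[, , us$i1[i], 1] <- dp[, , us$i1[i], 1] + us$w1[i] * dup[, , i, 1]
    }
  }
  dp
}

## star-shape structure -------------------------------------------------------

star_fwd <- function(st, xH, xW, training = FALSE) {
  dH <- dim(xH); M <- dH[1]; K <- dH[2]; H <- dH[3]
  W <- dim(xW)[4]
  L <- H + W
  if (L < 2) stop("degenerate input: H + W must be at least 2")
  u <- array(0, c(M, K, L, 1))
  u[, , 1:H, 1] <- xH
  u[, , (H + 1):L, 1] <- array(xW, c(M, K, W))
  dn <- conv_fwd(st$star_down, u, training)         # (M, K, ceil(L/2), 1)
  f <- conv_fwd(st$star_f, dn, training)
  g <- conv_fwd(st$star_g, dn, training)
  gg <- gelu(g)
  s <- f * gg                                       # the star product
  p <- sigmoid(s)
  us <- strip_upsample(p, L, st$upsample)
  gateH <- us$up[, , 1:H, , drop = FALSE]
  gateW <- array(us$up[, , (H + 1):L, 1], c(M, K, 1, W))
  if (!isFALSE(training))
    st$star_cache <- list(f = f, g = g, gg = gg, p = p, us = us,
                          H = H, W = W, Ld = dim(p)[3])
  list(gateH = gateH, gateW = gateW)
}

star_bwd <- function(st, dgateH, dgateW) {
  ca <- st$star_cache
  H <- ca$H; W <- ca$W; L <- H + W
  d <- dim(dgateH); M <- d[1]; K <- d[2]
  dup <- array(0, c(M, K, L, 1))
  dup[, , 1:H, 1] <- dgateH
  dup[, , (H + 1):L, 1] <- array(dgateW, c(M, K, W))
  dp <- strip_upsample_bwd(dup, ca$us, ca$Ld, st$upsample)
  ds <- dp * ca$p * (1 - ca$p)
  df <- ds * ca$gg
  dg <- ds * ca$f * gelu_grad(ca$g)
  ddn <- conv_bwd(st$star_f, df) + conv_bwd(st$star_g, dg)
  du <- conv_bwd(st$star_down, ddn)
  st$star_cache <- NULL
  list(dxH = du[, , 1:H, , drop = FALSE],
       dxW = array(du[, , (H + 1):L, 1], c(M, K, 1, W)))
}

#' Star-shape gate structure
#'
#' Concatenates the axial descriptors into an H+W strip, downsamples it with a
#' stride-2 1x1 convolution, applies the star operation (the elementwise
#' product of two 1x1-convolved copies, one through GELU -- an implicit
#' high-dimensional nonlinear feature map), squashes through a sigmoid,
#' restores full length by interpolation and splits the strip back into a
#' per-height and a per-width gate, each with entries strictly in (0, 1).
#'
#' @param module a [StarMAAttention-class].
#' @param xH,xW axial descriptors from [axialPool()].
#' @return list with `gateH` (M, K, H, 1) and `gateW` (M, K, 1, W).
#' @export
starStructure <- function(module, xH, xW) {
  star_fwd(module@state, xH, xW, training = FALSE)
}

## CCIB ------------------------------------------------------------------------

ccib_fwd <- function(st, xg, training = FALSE) {
  d <- dim(xg); M <- d[1]; K <- d[2]; H <- d[3]; W <- d[4]
  ap <- axialPool(xg)
  sh <- sigmoid(ap$xH)                              # (M, K, H, 1)
  sw <- sigmoid(ap$xW)                              # (M, K, 1, W)
  if (st$flags$sss) {
    gates <- star_fwd(st, ap$xH, ap$xW, training)
    FH <- sh * gates$gateH
    FW <- sw * gates$gateW
  } else {
    FH <- sh
    FW <- sw
  }
  A <- as.vector(FH)                                # recycles over W
  Bfull <- expand_over_h(FW, M, K, H, W)
  P <- A * Bfull
  x1 <- xg * P
  if (!isFALSE(training))
    st$ccib_cache <- list(xg = xg, sh = sh, sw = sw, FH = FH, FW = FW,
                          P = P, Bfull = Bfull, dims = d)
  x1
}

ccib_bwd <- function(st, dx1) {
  ca <- st$ccib_cache
  d <- ca$dims; M <- d[1]; K <- d[2]; H <- d[3]; W <- d[4]
  dxg <- dx1 * ca$P
  dP <- dx1 * ca$xg
  Afull <- as.vector(ca$FH)
  dFH <- rowSums(matrix(dP * ca$Bfull, M * K * H, W))
  dim(dFH) <- c(M, K, H, 1)
  dFWfull <- dP * Afull
  dFW <- colSums(aperm(array(dFWfull, c(M * K, H, W)), c(2, 1, 3)))
  dim(dFW) <- c(M, K, 1, W)
  if (st$flags$sss) {
    gH <- ca$FH / ca$sh                             # = gateH
    gW <- ca$FW / ca$sw
    dsh <- dFH * gH
    dsw <- dFW * gW
    dgH <- dFH * ca$sh
    dgW <- dFW * ca$sw
    sb <- star_bwd(st, dgH, dgW)
    dxH <- dsh * ca$sh * (1 - ca$sh) + sb$dxH
    dxW <- dsw * ca$sw * (1 - ca$sw) + sb$dxW
  } else {
    dxH <- dFH * ca$sh * (1 - ca$sh)
    dxW <- dFW * ca$sw * (1 - ca$sw)
  }
  # adjoint of the axial means
  dxg <- dxg + as.vector(dxH) / W
  dxg <- dxg + expand_over_h(dxW, M, K, H, W) / H
  st$ccib_cache <- NULL
  dxg
}

#' Cross-channel information interaction branch
#'
#' Re-weights a grouped feature map with four broadcast gate factors, all in
#' (0, 1): the sigmoids of the two axial descriptors and (when the star-shape
#' structure is enabled) the two star gates, so `|x1| <= |x_group|`
#' elementwise.
#'
#' @param module a [StarMAAttention-class].
#' @param xg grouped (M, K, H, W) feature map.
#' @return the gated map `x1`, same shape.
#' @export
ccib <- function(module, xg) ccib_fwd(module@state, xg, training = FALSE)

## SCB -------------------------------------------------------------------------

scb_fwd <- function(st, xg, training = FALSE) {
  h1 <- conv_fwd(st$scb1, xg, training)
  h2 <- conv_fwd(st$scb2, h1, training)
  h3 <- conv_fwd(st$scb3, h2, training)
  FF <- pnorm(h3)
  if (!isFALSE(training)) st$scb_cache <- list(grad = FF + h3 * dnorm(h3))
  h3 * FF
}

scb_bwd <- function(st, dx2) {
  dh3 <- dx2 * st$scb_cache$grad
  st$scb_cache <- NULL
  conv_bwd(st$scb1, conv_bwd(st$scb2, conv_bwd(st$scb3, dh3)))
}

#' Stacked convolution branch
#'
#' Three same-padding, stride-1, width-preserving convolutions (kernel sizes
#' 1, 5, 7 by default, applied in that order) followed by GELU; the stacked
#' receptive field supplies the multi-scale spatial context complementary to
#' the axial branch.
#'
#' @inheritParams ccib
#' @return the branch output `x2`, same shape as `xg`.
#' @export
scb <- function(module, xg) scb_fwd(module@state, xg, training = FALSE)

## CSFA ------------------------------------------------------------------------

# Channel-softmax descriptor of a branch: softmax over K of the global
# spatial mean (optionally after per-channel GroupNorm).
.channel_descr <- function(x, M, K, S) {
  m <- matrix(rowMeans(matrix(x, M * K, S)), M, K)
  row_softmax(m)
}

csfa_fwd <- function(st, x1, x2, xg, training = FALSE) {
  d <- dim(xg); M <- d[1]; K <- d[2]; H <- d[3]; W <- d[4]; S <- H * W
  if (!identical(dim(x1), d) || !identical(dim(x2), d))
    stop("x1, x2 and xg must share the grouped shape (",
         paste(d, collapse = ", "), ")")
  gnx <- gn_fwd(st$gn, x1, training)
  x11 <- .channel_descr(gnx, M, K, S)               # (M, K), rows sum to 1
  x22 <- .channel_descr(x2, M, K, S)
  x12 <- sum_over_k(x2 * as.vector(x11), M, K, S)   # (M, S)
  x21 <- sum_over_k(x1 * as.vector(x22), M, K, S)
  weight <- x12 + x21
  gate <- sigmoid(weight)
  Eg <- expand_over_k(gate, M, K, S)
  out <- xg * Eg
  dim(out) <- d
  if (!isFALSE(training))
    st$csfa_cache <- list(x1 = x1, x2 = x2, xg = xg, x11 = x11, x22 = x22,
                          gate = gate, Eg = Eg, dims = d)
  out
}

csfa_bwd <- function(st, dout) {
  ca <- st$csfa_cache
  d <- ca$dims; M <- d[1]; K <- d[2]; S <- d[3] * d[4]
  dxg <- dout * ca$Eg
  dgate <- sum_over_k(dout * as.vector(ca$xg), M, K, S)
  dweight <- dgate * ca$gate * (1 - ca$gate)        # (M, S)
  Edw <- expand_over_k(dweight, M, K, S)
  # x12 = x11 . x2 ; x21 = x22 . x1
  dx11 <- matrix(sum_over_s(as.vector(ca$x2) * Edw, M * K, S), M, K)
  dx22 <- matrix(sum_over_s(as.vector(ca$x1) * Edw, M * K, S), M, K)
  dx2 <- array(as.vector(ca$x11) * Edw, d)
  dx1 <- array(as.vector(ca$x22) * Edw, d)
  # softmax + spatial-mean adjoints
  dm1 <- ca$x11 * (dx11 - rowSums(ca$x11 * dx11))
  dm2 <- ca$x22 * (dx22 - rowSums(ca$x22 * dx22))
  dgn <- array(rep(as.vector(dm1) / S, times = S), d)
  dx2 <- dx2 + array(rep(as.vector(dm2) / S, times = S), d)
  dx1 <- dx1 + gn_bwd(st$gn, dgn)
  st$csfa_cache <- NULL
  list(dx1 = dx1, dx2 = dx2, dxg = dxg)
}

#' Cross-spatial feature aggregation
#'
#' Fuses the two branch outputs into one spatial attention map: the
#' channel-softmax descriptor of GroupNorm(x1) weights the spatial maps of
#' x2 (and vice versa, without GroupNorm), the two weighted maps are summed,
#' squashed through a sigmoid, and broadcast over channels to gate the
#' grouped input.  With constant branch maps `x1 = c1`, `x2 = c2` the output
#' reduces to `sigmoid(c1 + c2) * xg`.
#'
#' @param module a [StarMAAttention-class].
#' @param x1 CCIB branch output.
#' @param x2 SCB branch output.
#' @param xg the grouped input both branches came from.
#' @return gated grouped map, same shape as `xg`.
#' @export
csfa <- function(module, x1, x2, xg) {
  csfa_fwd(module@state, x1, x2, xg, training = FALSE)
}

## single-branch and no-CSFA fusion variants ----------------------------------

# Self-weighted fusion used when only one branch is enabled: the branch's own
# channel-softmax descriptor (through GroupNorm for the CCIB branch, matching
# the dual-branch wiring) weights its spatial maps, and the sigmoid of that
# map gates the input.
single_fwd <- function(st, xb, xg, use_gn, training = FALSE) {
  d <- dim(xg); M <- d[1]; K <- d[2]; S <- d[3] * d[4]
  gnx <- if (use_gn) gn_fwd(st$gn, xb, training) else xb
  xkk <- .channel_descr(gnx, M, K, S)
  wmap <- sum_over_k(xb * as.vector(xkk), M, K, S)
  gate <- sigmoid(wmap)
  Eg <- expand_over_k(gate, M, K, S)
  out <- xg * Eg
  dim(out) <- d
  if (!isFALSE(training))
    st$single_cache <- list(xb = xb, xg = xg, xkk = xkk, gate = gate,
                            Eg = Eg, use_gn = use_gn, dims = d)
  out
}

single_bwd <- function(st, dout) {
  ca <- st$single_cache
  d <- ca$dims; M <- d[1]; K <- d[2]; S <- d[3] * d[4]
  dxg <- dout * ca$Eg
  dgate <- sum_over_k(dout * as.vector(ca$xg), M, K, S)
  dwmap <- dgate * ca$gate * (1 - ca$gate)
  Edw <- expand_over_k(dwmap, M, K, S)
  dxkk <- matrix(sum_over_s(as.vector(ca$xb) * Edw, M * K, S), M, K)
  dxb <- array(as.vector(ca$xkk) * Edw, d)
  dm <- ca$xkk * (dxkk - rowSums(ca$xkk * dxkk))
  dpool <- array(rep(as.vector(dm) / S, times = S), d)
  if (ca$use_gn) dxb <- dxb + gn_bwd(st$gn, dpool) else dxb <- dxb + dpool
  st$single_cache <- NULL
  list(dxb = dxb, dxg = dxg)
}

sum_fuse_fwd <- function(st, x1, x2, xg, training = FALSE) {
  gate <- sigmoid(x1 + x2)
  out <- xg * gate
  if (!isFALSE(training)) st$sum_cache <- list(xg = xg, gate = gate)
  out
}

sum_fuse_bwd <- function(st, dout) {
  ca <- st$sum_cache
  dxg <- dout * ca$gate
  dw <- dout * ca$xg * ca$gate * (1 - ca$gate)
  st$sum_cache <- NULL
  list(dx1 = dw, dx2 = dw, dxg = dxg)
}

## full module forward / backward ---------------------------------------------

att_forward <- function(st, x, training = FALSE) {
  xg <- groupFeatures(x, st$G)
  fl <- st$flags
  x1 <- if (fl$ccib) ccib_fwd(st, xg, training) else NULL
  x2 <- if (fl$scb) scb_fwd(st, xg, training) else NULL
  if (fl$ccib && fl$scb) {
    out <- if (fl$csfa) csfa_fwd(st, x1, x2, xg, training)
           else sum_fuse_fwd(st, x1, x2, xg, training)
  } else if (fl$ccib) {
    out <- single_fwd(st, x1, xg, use_gn = TRUE, training = training)
  } else {
    out <- single_fwd(st, x2, xg, use_gn = FALSE, training = training)
  }
  ungroupFeatures(out, st$G)
}

att_backward <- function(st, dy) {
  dout <- groupFeatures(dy, st$G)
  fl <- st$flags
  if (fl$ccib && fl$scb) {
    b <- if (fl$csfa) csfa_bwd(st, dout) else sum_fuse_bwd(st, dout)
    dxg <- b$dxg + ccib_bwd(st, b$dx1) + scb_bwd(st, b$dx2)
  } else if (fl$ccib) {
    b <- single_bwd(st, dout)
    dxg <- b$dxg + ccib_bwd(st, b$dxb)
  } else {
    b <- single_bwd(st, dout)
    dxg <- b$dxg + scb_bwd(st, b$dxb)
  }
  ungroupFeatures(dxg, st$G)
}

#' @describeIn forwardPass apply a StarMA attention block to a (B, C, H, W)
#'   feature map; returns a re-weighted map of identical shape.
#' @export
setMethod("forwardPass", "StarMAAttention", function(object, x, training = FALSE) {
  if (!all(is.finite(x))) stop("feature map contains non-finite entries")
  att_forward(object@state, x, training)
})

setMethod("show", "StarMAAttention", function(object) {
  st <- object@state
  cat("StarMAAttention block\n")
  cat("  channels:", object@channels, " groups:", st$G,
      " (", st$K, "channels/group )\n")
  fl <- st$flags
  cat("  branches: CCIB =", fl$ccib, "(SSS =", fl$sss, "), SCB =", fl$scb,
      ", fusion =", if (fl$csfa) "CSFA" else "sum", "\n")
  cat("  parameters:", sum(vapply(attention_layers(st),
                                  function(L) sum(vapply(L$par, length, 0)), 0)), "\n")
})
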