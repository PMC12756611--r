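# Independent straight-line oracles, written as explicit loops and matrix
# products so they share no code path with the package implementation.

# naive sliding-window cross-correlation (same semantics as a conv layer)
naive_conv2d <- function(x, W, b = NULL, sh = 1, sw = 1, ph = 0, pw = 0) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  dw <- dim(W); cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  Ho <- (H + 2 * ph - kh) %/% sh + 1
  Wo <- (Wd + 2 * pw - kw) %/% sw + 1
  y <- array(0, c(B, cout, Ho, Wo))
  for (bb in 1:B) for (co in 1:cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in 1:C) for (i in 1:kh) for (j in 1:kw) {
      h <- (ho - 1) * sh - ph + i
      w <- (wo - 1) * sw - pw + j
      if (h >= 1 && h <= H && w >= 1 && w <= Wd)
        acc <- acc + W[co, ci, i, j] * x[bb, ci, h, w]
    }
    y[bb, co, ho, wo] <- acc
  }
  y
}

o_sigmoid <- function(x) 1 / (1 + exp(-x))
o_gelu <- function(x) x * pnorm(x)

# explicit double-loop axial means
oracle_axial <- function(xg) {
  d <- dim(xg)
  xH <- array(0, c(d[1], d[2], d[3], 1))
  xW <- array(0, c(d[1], d[2], 1, d[4]))
  for (m in 1:d[1]) for (k in 1:d[2]) {
    for (h in 1:d[3]) xH[m, k, h, 1] <- mean(xg[m, k, h, ])
    for (w in 1:d[4]) xW[m, k, 1, w] <- mean(xg[m, k, , w])
  }
  list(xH = xH, xW = xW)
}

# straight-line star-shape structure using the module's weights as explicit
# (K x K) matrix products
oracle_star <- function(mod, xH, xW) {
  st <- mod@state
  d <- dim(xH); M <- d[1]; K <- d[2]; H <- d[3]; W <- dim(xW)[4]
  L <- H + W
  Wd <- matrix(st$star_down$par$W, K, K); bd <- st$star_down$par$b
  Wf <- matrix(st$star_f$par$W, K, K); bf <- st$star_f$par$b
  Wg <- matrix(st$star_g$par$W, K, K); bg <- st$star_g$par$b
  Ld <- length(seq(1, L, by = 2))
  gateH <- array(0, c(M, K, H, 1)); gateW <- array(0, c(M, K, 1, W))
  for (m in 1:M) {
    u <- matrix(0, K, L)
    for (k in 1:K) {
      u[k, 1:H] <- xH[m, k, , 1]
      u[k, (H + 1):L] <- xW[m, k, 1, ]
    }
    dn <- Wd %*% u[, seq(1, L, by = 2), drop = FALSE] + bd
    f <- Wf %*% dn + bf
    g <- Wg %*% dn + bg
    p <- o_sigmoid(f * o_gelu(g))
    up <- matrix(0, K, L)
    for (i in 1:L) up[, i] <- p[, floor((i - 1) * Ld / L) + 1]
    for (k in 1:K) {
      gateH[m, k, , 1] <- up[k, 1:H]
      gateW[m, k, 1, ] <- up[k, (H + 1):L]
    }
  }
  list(gateH = gateH, gateW = gateW)
}

# CCIB by loops: x1 = xg . sig(xh) . sig(xw) [. gate_h . gate_w]
oracle_ccib <- function(mod, xg, use_sss = TRUE) {
  d <- dim(xg)
  ap <- oracle_axial(xg)
  g <- if (use_sss) oracle_star(mod, ap$xH, ap$xW) else NULL
  x1 <- array(0, d)
  for (m in 1:d[1]) for (k in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4]) {
    v <- xg[m, k, h, w] * o_sigmoid(ap$xH[m, k, h, 1]) *
      o_sigmoid(ap$xW[m, k, 1, w])
    if (use_sss) v <- v * g$gateH[m, k, h, 1] * g$gateW[m, k, 1, w]
    x1[m, k, h, w] <- v
  }
  x1
}

oracle_scb <- function(mod, xg) {
  st <- mod@state
  h1 <- naive_conv2d(xg, st$scb1$par$W, st$scb1$par$b)
  k2 <- st$scb2$meta$kh; k3 <- st$scb3$meta$kh
  h2 <- naive_conv2d(h1, st$scb2$par$W, st$scb2$par$b,
                     ph = (k2 - 1) %/% 2, pw = (k2 - 1) %/% 2)
  h3 <- naive_conv2d(h2, st$scb3$par$W, st$scb3$par$b,
                     ph = (k3 - 1) %/% 2, pw = (k3 - 1) %/% 2)
  o_gelu(h3)
}

# line-by-line scale-fusion transcription (loops for pooling, softmax and the
# two matrix products); GroupNorm feeds only the first channel descriptor
oracle_csfa <- function(mod, x1, x2, xg) {
  st <- mod@state
  d <- dim(xg); M <- d[1]; K <- d[2]; H <- d[3]; W <- d[4]
  eps <- 1e-5
  gamma <- st$gn$par$gamma; beta <- st$gn$par$beta
  gn <- array(0, d)
  for (m in 1:M) for (k in 1:K) {
    v <- x1[m, k, , ]
    mu <- mean(v); va <- mean((v - mu)^2)
    gn[m, k, , ] <- gamma[k] * (v - mu) / sqrt(va + eps) + beta[k]
  }
  out <- array(0, d)
  x11m <- matrix(0, M, K); x22m <- matrix(0, M, K)
  for (m in 1:M) {
    p1 <- numeric(K); p2 <- numeric(K)
    for (k in 1:K) { p1[k] <- mean(gn[m, k, , ]); p2[k] <- mean(x2[m, k, , ]) }
    x11 <- exp(p1 - max(p1)); x11 <- x11 / sum(x11)
    x22 <- exp(p2 - max(p2)); x22 <- x22 / sum(x22)
    x11m[m, ] <- x11; x22m[m, ] <- x22
    x12 <- matrix(0, H, W); x21 <- matrix(0, H, W)
    for (k in 1:K) {
      x12 <- x12 + x11[k] * x2[m, k, , ]
      x21 <- x21 + x22[k] * x1[m, k, , ]
    }
    weight <- x12 + x21
    gate <- o_sigmoid(weight)
    for (k in 1:K) out[m, k, , ] <- gate * xg[m, k, , ]
  }
  list(out = out, x11 = x11m, x22 = x22m)
}

# explicit index-bookkeeping channel grouping
oracle_group <- function(x, G) {
  d <- dim(x); B <- d[1]; K <- d[2] %/% G
  xg <- array(0, c(B * G, K, d[3], d[4]))
  for (b in 1:B) for (g in 1:G) for (k in 1:K)
    xg[b + B * (g - 1), k, , ] <- x[b, (g - 1) * K + k, , ]
  xg
}

oracle_ungroup <- function(xg, G) {
  d <- dim(xg); B <- d[1] %/% G; K <- d[2]
  x <- array(0, c(B, K * G, d[3], d[4]))
  for (b in 1:B) for (g in 1:G) for (k in 1:K)
    x[b, (g - 1) * K + k, , ] <- xg[b + B * (g - 1), k, , ]
  x
}

# full attention block: group -> (CCIB || SCB) -> CSFA -> ungroup
oracle_starma <- function(mod, x) {
  G <- mod@state$G
  xg <- oracle_group(x, G)
  x1 <- oracle_ccib(mod, xg)
  x2 <- oracle_scb(mod, xg)
  oracle_ungroup(oracle_csfa(mod, x1, x2, xg)$out, G)
}

# brute-force binary metrics straight from the printed formulas
oracle_binary <- function(TP, FN, FP, TN) {
  prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
  sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
  mden <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  s <- TP + TN + FP + FN
  p0 <- (TP + TN) / s
  pe <- ((TP + FN) * (TP + FP) + (TN + FP) * (TN + FN)) / s^2
  list(accuracy = (TP + TN) / s,
       precision = prec, sensitivity = sens,
       specificity = if (TN + FP == 0) 0 else TN / (TN + FP),
       f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
       mcc = if (mden == 0) 0 else (TP * TN - FP * FN) / mden,
       kappa = (p0 - pe) / (1 - pe))
}

# Mann-Whitney pair-counting AUC
oracle_auc_pairs <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}

make_attention <- function(channels, groups, seed = 1L, ...) {
  starmaAttention(channels, starMAConfig(groups = groups, seed = seed, ...))
}
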