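# Trainable layer primitives.
#
# Every layer is a reference-semantics environment holding `par` (named list of
# parameter arrays), `grad` (same shapes, written by the backward pass), and a
# forward cache.  Activations are (B, C, H, W) numeric arrays.  Convolutions
# run as one GEMM per layer over an im2col patch matrix built in C++; all
# backward passes are hand-derived adjoints.

new_layer <- function(kind, par, meta = list()) {
  L <- new.env(parent = emptyenv())
  L$kind <- kind
  L$par <- par
  L$grad <- lapply(par, function(p) p * 0)
  L$meta <- meta
  L$cache <- NULL
  L$opt <- NULL
  L
}

zero_grads <- function(layers) {
  for (L in layers)
    L$grad <- lapply(L$par, function(p) p * 0)
  invisible(NULL)
}

## ---- convolution -----------------------------------------------------------

conv_new <- function(cin, cout, kh, kw = kh, sh = 1, sw = sh,
                     ph = (kh - 1) %/% 2, pw = (kw - 1) %/% 2, bias = TRUE) {
  W <- array(trunc_normal(cout * cin * kh * kw), c(cout, cin, kh, kw))
  par <- list(W = W)
  if (bias) par$b <- numeric(cout)
  new_layer("conv", par,
            meta = list(cin = cin, cout = cout, kh = kh, kw = kw,
                        sh = sh, sw = sw, ph = ph, pw = pw, bias = bias))
}

conv_fwd <- function(L, x, training = FALSE) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  m <- L$meta
  stopifnot(C == m$cin)
  cols <- cpp_im2col(x, B, C, H, W, m$kh, m$kw, m$ph, m$pw, m$sh, m$sw)
  Ho <- (H + 2 * m$ph - m$kh) %/% m$sh + 1
  Wo <- (W + 2 * m$pw - m$kw) %/% m$sw + 1
  Wm <- matrix(L$par$W, m$cout, m$cin * m$kh * m$kw)
  y <- Wm %*% cols
  if (m$bias) y <- y + L$par$b
  y <- aperm(array(y, c(m$cout, B, Ho, Wo)), c(2, 1, 3, 4))
  if (!isFALSE(training)) L$cache <- list(cols = cols, in_dim = d, out_hw = c(Ho, Wo))
  y
}

conv_bwd <- function(L, dy) {
  m <- L$meta; ca <- L$cache
  B <- ca$in_dim[1]
  dyc <- aperm(dy, c(2, 1, 3, 4))
  dim(dyc) <- c(m$cout, length(dyc) / m$cout)
  L$grad$W <- L$grad$W + array(tcrossprod(dyc, ca$cols), dim(L$par$W))
  if (m$bias) L$grad$b <- L$grad$b + rowSums(dyc)
  dcols <- crossprod(matrix(L$par$W, m$cout, m$cin * m$kh * m$kw), dyc)
  dx <- cpp_col2im(dcols, ca$in_dim[1], ca$in_dim[2], ca$in_dim[3], ca$in_dim[4],
                   m$kh, m$kw, m$ph, m$pw, m$sh, m$sw)
  L$cache <- NULL
  dx
}

## ---- batch normalization ---------------------------------------------------

bn_new <- function(C, momentum = 0.1, eps = 1e-5) {
  L <- new_layer("bn", list(gamma = rep(1, C), beta = rep(0, C)),
                 meta = list(C = C, momentum = momentum, eps = eps))
  L$buffers <- list(running_mean = rep(0, C), running_var = rep(1, C))
  L
}

# per-channel sums of a (B, C, H, W) array -> length-C vector
.chan_sum <- function(x, B, C) {
  colSums(matrix(rowSums(matrix(x, B * C, length(x) / (B * C))), B, C))
}

# `training` is FALSE (eval, no cache), TRUE (batch statistics, running-stat
# update, cache) or "grad" (running statistics but with a cache so gradients
# can flow through the frozen affine map, used by Grad-CAM).
bn_fwd <- function(L, x, training = FALSE) {
  d <- dim(x); B <- d[1]; C <- d[2]; n <- B * d[3] * d[4]
  m <- L$meta
  if (isTRUE(training)) {
    mu <- .chan_sum(x, B, C) / n
    xc <- x - rep(mu, each = B)                    # recycles over H, W
    v <- .chan_sum(xc * xc, B, C) / n
    invstd <- 1 / sqrt(v + m$eps)
    xhat <- xc * rep(invstd, each = B)
    L$buffers$running_mean <- (1 - m$momentum) * L$buffers$running_mean + m$momentum * mu
    vub <- if (n > 1) v * n / (n - 1) else v
    L$buffers$running_var <- (1 - m$momentum) * L$buffers$running_var + m$momentum * vub
    L$cache <- list(xhat = xhat, invstd = invstd, n = n, B = B, C = C)
  } else {
    invstd <- 1 / sqrt(L$buffers$running_var + m$eps)
    xhat <- (x - rep(L$buffers$running_mean, each = B)) * rep(invstd, each = B)
    if (!isFALSE(training))
      L$cache <- list(xhat = xhat, invstd = invstd, n = n, B = B, C = C,
                      frozen = TRUE)
  }
  y <- xhat * rep(L$par$gamma, each = B) + rep(L$par$beta, each = B)
  dim(y) <- d
  y
}

bn_bwd <- function(L, dy) {
  ca <- L$cache; B <- ca$B; C <- ca$C; n <- ca$n
  L$grad$gamma <- L$grad$gamma + .chan_sum(dy * ca$xhat, B, C)
  L$grad$beta <- L$grad$beta + .chan_sum(dy, B, C)
  dxhat <- dy * rep(L$par$gamma, each = B)
  if (isTRUE(ca$frozen)) {             # running statistics: affine map only
    dx <- dxhat * rep(ca$invstd, each = B)
    dim(dx) <- dim(dy)
    L$cache <- NULL
    return(dx)
  }
  s1 <- .chan_sum(dxhat, B, C)
  s2 <- .chan_sum(dxhat * ca$xhat, B, C)
  dx <- rep(ca$invstd / n, each = B) *
    (n * dxhat - rep(s1, each = B) - ca$xhat * rep(s2, each = B))
  dim(dx) <- dim(dy)
  L$cache <- NULL
  dx
}

## ---- group normalization (one group per channel) ---------------------------

gn_new <- function(C, eps = 1e-5) {
  new_layer("gn", list(gamma = rep(1, C), beta = rep(0, C)),
            meta = list(C = C, eps = eps))
}

gn_fwd <- function(L, x, training = FALSE) {
  d <- dim(x); M <- d[1]; K <- d[2]; S <- d[3] * d[4]
  xm <- matrix(x, M * K, S)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + L$meta$eps)
  xhat <- xc * invstd
  y <- xhat * rep(L$par$gamma, each = M) + rep(L$par$beta, each = M)
  dim(y) <- d
  if (!isFALSE(training)) L$cache <- list(xhat = xhat, invstd = invstd, M = M, K = K, S = S)
  y
}

gn_bwd <- function(L, dy) {
  ca <- L$cache; M <- ca$M; K <- ca$K; S <- ca$S
  dym <- matrix(dy, M * K, S)
  L$grad$gamma <- L$grad$gamma + colSums(matrix(rowSums(dym * ca$xhat), M, K))
  L$grad$beta <- L$grad$beta + colSums(matrix(rowSums(dym), M, K))
  dxhat <- dym * rep(L$par$gamma, each = M)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * ca$xhat)
  dx <- (ca$invstd / S) * (S * dxhat - s1 - ca$xhat * s2)
  dim(dx) <- dim(dy)
  L$cache <- NULL
  dx
}

## ---- fully connected -------------------------------------------------------

lin_new <- function(cin, cout, bias = TRUE) {
  par <- list(W = array(trunc_normal(cout * cin), c(cout, cin)))
  if (bias) par$b <- numeric(cout)
  new_layer("linear", par, meta = list(cin = cin, cout = cout, bias = bias))
}

lin_fwd <- function(L, x, training = FALSE) {
  y <- tcrossprod(x, L$par$W)
  if (L$meta$bias) y <- sweep(y, 2, L$par$b, "+")
  if (!isFALSE(training)) L$cache <- list(x = x)
  y
}

lin_bwd <- function(L, dy) {
  L$grad$W <- L$grad$W + crossprod(dy, L$cache$x)
  if (L$meta$bias) L$grad$b <- L$grad$b + colSums(dy)
  dx <- dy %*% L$par$W
  L$cache <- NULL
  dx
}

## ---- parameter-free stages -------------------------------------------------

gelu_stage_new <- function() new_layer("gelu", list())
gelu_stage_fwd <- function(L, x, training = FALSE) {
  FF <- pnorm(x)
  if (!isFALSE(training)) L$cache <- list(grad = FF + x * dnorm(x))
  x * FF
}
gelu_stage_bwd <- function(L, dy) {
  dx <- dy * L$cache$grad
  L$cache <- NULL
  dx
}

maxpool_new <- function() new_layer("maxpool", list())
maxpool_fwd <- function(L, x, training = FALSE) {
  d <- dim(x)
  if (d[3] < 2 || d[4] < 2)
    stop("max pooling needs spatial dimensions of at least 2, got ",
         d[3], "x", d[4])
  r <- cpp_maxpool2(x, d[1], d[2], d[3], d[4])
  if (!isFALSE(training)) L$cache <- list(argmax = r$argmax, in_dim = d)
  r$y
}
maxpool_bwd <- function(L, dy) {
  d <- L$cache$in_dim
  dx <- cpp_maxpool2_backward(dy, L$cache$argmax, d[1], d[2], d[3], d[4])
  L$cache <- NULL
  dx
}

# Stochastic depth: drops the whole feature map of a sample with probability
# `rate` during training and rescales survivors by 1/(1-rate).
droppath_new <- function(rate = 0) new_layer("droppath", list(), meta = list(rate = rate))
droppath_fwd <- function(L, x, training = FALSE) {
  r <- L$meta$rate
  if (!isTRUE(training) || r <= 0) {
    L$cache <- list(mask = NULL)
    return(x)
  }
  B <- dim(x)[1]
  keep <- L$meta$forced_mask %||% (runif(B) >= r)
  mask <- as.numeric(keep) / (1 - r)
  L$cache <- list(mask = mask)
  x * mask                                        # batch index is fastest
}
droppath_bwd <- function(L, dy) {
  mask <- L$cache$mask
  L$cache <- NULL
  if (is.null(mask)) dy else dy * mask
}

gap_new <- function() new_layer("gap", list())
gap_fwd <- function(L, x, training = FALSE) {
  d <- dim(x)
  if (!isFALSE(training)) L$cache <- list(in_dim = d)
  y <- rowMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(y, d[1], d[2])
}
gap_bwd <- function(L, dy) {
  d <- L$cache$in_dim
  L$cache <- NULL
  dx <- array(as.vector(dy) / (d[3] * d[4]), d)   # constant over H, W
  dx
}

## ---- optimizer -------------------------------------------------------------

# One AdamW step over a list of layers.  Decoupled weight decay applies to
# convolution/linear weight matrices only (not biases or normalization
# affines), the common convention.
adamw_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01, t = 1,
                       decoupled = TRUE) {
  for (L in layers) {
    if (length(L$par) == 0) next
    if (is.null(L$opt))
      L$opt <- list(m = lapply(L$par, function(p) p * 0),
                    v = lapply(L$par, function(p) p * 0))
    for (nm in names(L$par)) {
      g <- L$grad[[nm]]
      L$opt$m[[nm]] <- beta1 * L$opt$m[[nm]] + (1 - beta1) * g
      L$opt$v[[nm]] <- beta2 * L$opt$v[[nm]] + (1 - beta2) * g * g
      mhat <- L$opt$m[[nm]] / (1 - beta1^t)
      vhat <- L$opt$v[[nm]] / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      if (decoupled && weight_decay > 0 && nm == "W" &&
          L$kind %in% c("conv", "linear"))
        upd <- upd + weight_decay * L$par[[nm]]
      L$par[[nm]] <- L$par[[nm]] - lr * upd
    }
  }
  invisible(NULL)
}
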