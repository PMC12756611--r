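# Internal helpers: seeded RNG scoping, broadcasting, small numerics.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All stochastic code in the package funnels
# through this so a single integer seed pins every result.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  force(expr)
}

# Truncated-normal initializer (resampled beyond 2 sd), the usual conv/linear
# weight init for attention-style networks.
trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# Broadcast helpers for (M, K, H, W) arrays stored column-major (M fastest).
# A height-indexed factor (M, K, H) recycles naturally over the trailing W
# dimension; a width-indexed factor needs an explicit expansion.

# (M*K, W) or (M, K, 1, W) -> full (M, K, H, W)
expand_over_h <- function(fw, M, K, H, W) {
  a <- array(fw, c(M * K, W, H))      # replicates the (M*K, W) block H times
  a <- aperm(a, c(1, 3, 2))
  dim(a) <- c(M, K, H, W)
  a
}

# (M, S) map expanded over the channel axis -> (M, K, S...) flat array
expand_over_k <- function(g, M, K, S) {
  a <- array(g, c(M, S, K))           # replicates the (M, S) block K times
  a <- aperm(a, c(1, 3, 2))
  dim(a) <- NULL
  a
}

# sum over the 2nd dimension of an (M, K, S) view of `v`
sum_over_k <- function(v, M, K, S) {
  a <- array(v, c(M, K, S))
  colSums(aperm(a, c(2, 1, 3)))       # (M, S)
}

# sum over the 3rd dimension (S) of an (MK, S) view
sum_over_s <- function(v, MK, S) {
  rowSums(matrix(v, MK, S))
}

# row-wise softmax of an (n, k) matrix
row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Simple non-cryptographic content hash (FNV-1a over the serialized object);
# used to stamp artifacts with the configuration that produced them.
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  h <- 21661366
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", h)
}

# Bilinear resize of a single-channel (H, W) matrix.
bilinear_resize <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  if (in_h == out_h && in_w == out_w) return(img)
  sy <- in_h / out_h; sx <- in_w / out_w
  yc <- (seq_len(out_h) - 0.5) * sy - 0.5
  xc <- (seq_len(out_w) - 0.5) * sx - 0.5
  y0 <- pmin(pmax(floor(yc), 0), in_h - 1)
  x0 <- pmin(pmax(floor(xc), 0), in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  a <- img[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx)
  b <- img[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx)
  cc <- img[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
  d <- img[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  a + b + cc + d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
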