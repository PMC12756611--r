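# StarMA attention block: grouping, axial pooling, star gates, branches,
# fusion, and the end-to-end module against independent loop oracles.

test_that("channel grouping splits contiguously and round-trips bit-exactly", {
  set.seed(1)
  x <- array(rnorm(2 * 8 * 3 * 3), c(2, 8, 3, 3))
  # G = 1 is the identity
  expect_identical(groupFeatures(x, 1), x)
  # contiguous split: group g holds source channels (g-1)*K + 1..K
  x4 <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
  xg <- groupFeatures(x4, 2)
  expect_equal(dim(xg), c(2, 2, 2, 2))
  expect_identical(xg[1, 1, , ], x4[1, 1, , ])
  expect_identical(xg[1, 2, , ], x4[1, 2, , ])
  expect_identical(xg[2, 1, , ], x4[1, 3, , ])
  expect_identical(xg[2, 2, , ], x4[1, 4, , ])
  # round-trip against the explicit index-bookkeeping oracle
  g4 <- groupFeatures(x, 4)
  expect_identical(g4, oracle_group(x, 4))
  expect_identical(ungroupFeatures(g4, 4), x)
  expect_error(groupFeatures(x, 3), "not divisible")
})

test_that("axial pooling averages each axis correctly", {
  xc <- array(2.5, c(1, 2, 3, 4))
  ap <- axialPool(xc)
  expect_true(all(ap$xH == 2.5) && all(ap$xW == 2.5))
  # hand-computed 2x2 case
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)  # rows (1,2) and (3,4)
  ap <- axialPool(x)
  expect_equal(as.vector(ap$xH), c(1.5, 3.5))
  expect_equal(as.vector(ap$xW), c(2, 3))
  # loop oracle on a random map
  set.seed(2)
  xr <- array(rnorm(1 * 3 * 5 * 7), c(1, 3, 5, 7))
  o <- oracle_axial(xr)
  a <- axialPool(xr)
  expect_lt(max(abs(a$xH - o$xH)), 1e-6)
  expect_lt(max(abs(a$xW - o$xW)), 1e-6)
})

test_that("star-shape structure produces (0,1) gates and matches its straight-line oracle", {
  mod <- make_attention(8, 4, seed = 11)
  K <- 2
  # zero descriptors with zero biases: pre-sigmoid product is 0, gates 0.5
  zH <- array(0, c(4, K, 4, 1)); zW <- array(0, c(4, K, 1, 6))
  g0 <- starStructure(mod, zH, zW)
  expect_true(all(g0$gateH == 0.5) && all(g0$gateW == 0.5))
  # gate codomain on arbitrary finite inputs
  set.seed(3)
  xH <- array(rnorm(4 * K * 4, sd = 3), c(4, K, 4, 1))
  xW <- array(rnorm(4 * K * 6, sd = 3), c(4, K, 1, 6))
  g <- starStructure(mod, xH, xW)
  expect_true(all(g$gateH > 0 & g$gateH < 1))
  expect_true(all(g$gateW > 0 & g$gateW < 1))
  # straight-line oracle: strip, stride-2 subsample, star product, sigmoid,
  # nearest upsample
  o <- oracle_star(mod, xH, xW)
  expect_lt(max(abs(g$gateH - o$gateH)), 1e-10)
  expect_lt(max(abs(g$gateW - o$gateW)), 1e-10)
  expect_error(starStructure(mod, array(0, c(1, K, 1, 1))[, , integer(0), ,
                                                          drop = FALSE],
                             array(0, c(1, K, 1, 1))[, , , integer(0),
                                                     drop = FALSE]),
               "degenerate")
})

test_that("CCIB attenuates the grouped input and matches the loop-broadcast oracle", {
  mod <- make_attention(8, 4, seed = 5)
  set.seed(4)
  x <- array(rnorm(1 * 8 * 4 * 4), c(1, 8, 4, 4))
  xg <- groupFeatures(x, 4)
  # zero input maps to zero regardless of weights
  expect_true(all(ccib(mod, xg * 0) == 0))
  x1 <- ccib(mod, xg)
  expect_equal(dim(x1), dim(xg))
  expect_lte(max(abs(x1)), max(abs(xg)))
  expect_true(all(abs(x1) <= abs(xg)))
  o <- oracle_ccib(mod, xg)
  expect_lt(max(abs(x1 - o)), 1e-10)
})

test_that("SCB preserves shape, maps zero to zero, and matches naive convolution", {
  mod <- make_attention(8, 2, seed = 6)
  set.seed(5)
  xg <- array(rnorm(2 * 4 * 7 * 5), c(2, 4, 7, 5))
  x2 <- scb(mod, xg)
  expect_equal(dim(x2), dim(xg))
  expect_true(all(scb(mod, xg * 0) == 0))   # zero biases at init, GELU(0)=0
  # naive sliding-window oracle on a single-channel module
  mod1 <- make_attention(1, 1, seed = 7)
  x1c <- array(rnorm(1 * 1 * 3 * 3), c(1, 1, 3, 3))
  expect_lt(max(abs(scb(mod1, x1c) - oracle_scb(mod1, x1c))), 1e-5)
  expect_lt(max(abs(scb(mod, xg) - oracle_scb(mod, xg))), 1e-5)
})

test_that("CSFA reduces to closed forms on constant branches", {
  mod <- make_attention(6, 2, seed = 8)
  set.seed(6)
  xg <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  c1 <- 0.7; c2 <- -0.3
  x1 <- array(c1, dim(xg)); x2 <- array(c2, dim(xg))
  out <- csfa(mod, x1, x2, xg)
  # constant maps: softmax uniform; x12 = c2, x21 = c1; gate = sig(c1+c2)
  expect_lt(max(abs(out - o_sigmoid(c1 + c2) * xg)), 1e-12)
  out0 <- csfa(mod, x1 * 0, x2 * 0, xg)
  expect_lt(max(abs(out0 - 0.5 * xg)), 1e-12)
  expect_error(csfa(mod, x1[, , 1:2, , drop = FALSE], x2, xg), "share")
})

test_that("CSFA matches the line-by-line scale-fusion oracle and its softmax rows sum to 1", {
  mod <- make_attention(6, 2, seed = 9)
  set.seed(7)
  d <- c(2, 3, 4, 4)
  x1 <- array(rnorm(prod(d)), d)
  x2 <- array(rnorm(prod(d)), d)
  xg <- array(rnorm(prod(d)), d)
  o <- oracle_csfa(mod, x1, x2, xg)
  expect_lt(max(abs(csfa(mod, x1, x2, xg) - o$out)), 1e-5)
  expect_true(all(abs(rowSums(o$x11) - 1) < 1e-6))
  expect_true(all(abs(rowSums(o$x22) - 1) < 1e-6))
})

test_that("the full attention block preserves shape, kills zero input, and attenuates", {
  mod <- make_attention(16, 8, seed = 10)
  set.seed(8)
  x <- array(rnorm(2 * 16 * 8 * 8), c(2, 16, 8, 8))
  y <- forwardPass(mod, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(forwardPass(mod, x * 0) == 0))
  expect_true(all(abs(y) <= abs(x)))
  expect_true(all((abs(y) < abs(x))[x != 0]))
  # determinism: identical input, identical output, bit for bit
  expect_identical(y, forwardPass(mod, x))
})

test_that("module output matches the composed straight-line oracle across shapes and seeds", {
  x66 <- with(list(), { set.seed(9); array(rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6)) })
  mod <- make_attention(8, 2, seed = 12)
  expect_lt(max(abs(forwardPass(mod, x66) - oracle_starma(mod, x66))), 1e-5)
  shapes <- list(c(2, 16, 8, 8), c(1, 32, 7, 5), c(3, 8, 14, 14))
  worst <- 0
  for (si in seq_along(shapes)) {
    d <- shapes[[si]]
    for (seed in 1:2) {
      set.seed(100 * si + seed)
      x <- array(rnorm(prod(d)), d)
      mod <- make_attention(d[2], 4, seed = 100 * si + seed)
      worst <- max(worst, max(abs(forwardPass(mod, x) - oracle_starma(mod, x))))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("ablation switches rewire the block as documented", {
  set.seed(10)
  x <- array(rnorm(2 * 8 * 6 * 6), c(2, 8, 6, 6))
  full <- make_attention(8, 2, seed = 13)
  y_full <- forwardPass(full, x)
  # all flags on is the default wiring
  flagged <- make_attention(8, 2, seed = 13)
  flagged@state$flags <- list(ccib = TRUE, sss = TRUE, scb = TRUE, csfa = TRUE)
  expect_identical(forwardPass(flagged, x), y_full)
  # disabling the star structure removes exactly the star-gate factors
  nosss <- make_attention(8, 2, seed = 13)
  nosss@state$flags$sss <- FALSE
  xg <- groupFeatures(x, 2)
  expect_lt(max(abs(ccib(nosss, xg) - oracle_ccib(nosss, xg, use_sss = FALSE))),
            1e-10)
  # no CSFA: output = o_sigmoid(x1 + x2) . x_group
  nocsfa <- make_attention(8, 2, seed = 13)
  nocsfa@state$flags$csfa <- FALSE
  x1 <- ccib(nocsfa, xg); x2 <- scb(nocsfa, xg)
  expected <- ungroupFeatures(o_sigmoid(x1 + x2) * xg, 2)
  expect_lt(max(abs(forwardPass(nocsfa, x) - expected)), 1e-10)
})

test_that("every attention parameter receives a gradient after one backward pass", {
  ns <- asNamespace("starmanet")
  mod <- make_attention(8, 2, seed = 14)
  set.seed(11)
  x <- array(rnorm(2 * 8 * 5 * 5), c(2, 8, 5, 5))
  y <- ns$att_forward(mod@state, x, training = TRUE)
  layers <- ns$attention_layers(mod@state)
  ns$zero_grads(layers)
  invisible(ns$att_backward(mod@state, array(1, dim(y))))
  for (L in layers)
    for (nm in names(L$grad))
      expect_true(all(is.finite(L$grad[[nm]])))
  gmax <- vapply(layers, function(L) max(vapply(L$grad, function(g)
    max(abs(g)), 0)), 0)
  expect_true(all(gmax > 0))
})
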