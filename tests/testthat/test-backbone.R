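# Backbone assembly: Base Blocks, StarMA Blocks, spatial schedule, ablation
# variants and width scaling.

slim_cfg <- function(numClasses = 2L, ...) {
  backboneConfig(numClasses = numClasses, widthMultiplier = 0.25, ...)
}

tiny_cfg <- function(...) {
  backboneConfig(stemWidths = c(8, 8), stageWidths = c(8, 8, 16),
                 trunkWidth = 16, mlpRatio = 2, outWidths = c(16, 16),
                 starma = starMAConfig(groups = 2, seed = 4), ...)
}

test_that("a Base Block halves the spatial size and is deterministic at dropPath 0", {
  ns <- asNamespace("starmanet")
  conv <- ns$conv_new(4L, 8L, 3)
  bn <- ns$bn_new(8L)
  pool <- ns$maxpool_new()
  set.seed(30)
  x <- array(rnorm(1 * 4 * 56 * 56), c(1, 4, 56, 56))
  run <- function() ns$maxpool_fwd(pool, ns$gelu(ns$bn_fwd(bn, ns$conv_fwd(conv, x))))
  y <- run()
  expect_equal(dim(y), c(1, 8, 28, 28))
  expect_identical(y, run())
})

test_that("Base Block computation equals BN/GELU followed by explicit 2x2 block maxima", {
  ns <- asNamespace("starmanet")
  conv <- ns$conv_new(1L, 1L, 3)
  # identity-like kernel: center tap 1, all else 0, no bias
  conv$par$W[] <- 0; conv$par$W[1, 1, 2, 2] <- 1; conv$par$b[] <- 0
  bn <- ns$bn_new(1L)                       # eval mode: running stats (0, 1)
  x <- array(as.numeric(1:16), c(1, 1, 4, 4))
  img <- ns$gelu(ns$bn_fwd(bn, ns$conv_fwd(conv, x)))
  pooled <- ns$maxpool_fwd(ns$maxpool_new(), img)
  expected <- array(0, c(1, 1, 2, 2))
  for (i in 1:2) for (j in 1:2)
    expected[1, 1, i, j] <- max(img[1, 1, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_lt(max(abs(pooled - expected)), 1e-12)
})

test_that("the StarMA Block matches a straight-line transcription of its equations", {
  ns <- asNamespace("starmanet")
  cfg <- backboneConfig(starma = starMAConfig(groups = 2, seed = 31))
  blk <- starmanet:::with_seed(31, ns$smblock_new(16L, 32L, cfg))
  set.seed(31)
  x <- array(rnorm(1 * 16 * 7 * 7), c(1, 16, 7, 7))
  y <- ns$smblock_fwd(blk, x, training = FALSE)
  expect_equal(dim(y), dim(x))
  # transcription: x_a = Conv(GELU(StarMA(BN(Conv(Conv(x)))))); x_attn = x_a + x;
  # M = mlp2(GELU(mlp1(x_attn))); out = GELU(M + x_attn).  BN in eval mode is
  # the affine map with running statistics (0, 1).
  cv <- function(L, z) naive_conv2d(z, L$par$W, L$par$b,
                                    ph = L$meta$ph, pw = L$meta$pw)
  a <- cv(blk$conv2, cv(blk$conv1, x))
  a <- a / sqrt(1 + 1e-5)                    # BN: gamma 1, beta 0, var 1
  mod_wrap <- new("StarMAAttention", channels = 16L,
                  config = cfg@starma, state = blk$att)
  at <- oracle_starma(mod_wrap, a)
  xa <- cv(blk$conv3, o_gelu(at))
  xattn <- xa + x
  m <- cv(blk$mlp2, o_gelu(cv(blk$mlp1, xattn)))
  expect_lt(max(abs(y - o_gelu(m + xattn))), 1e-5)
})

test_that("forcing both DropPath branches off reduces the block to GELU(x)", {
  ns <- asNamespace("starmanet")
  cfg <- backboneConfig(dropPath = 0.5, starma = starMAConfig(groups = 2, seed = 32))
  blk <- starmanet:::with_seed(32, ns$smblock_new(16L, 32L, cfg))
  blk$dp_attn$meta$forced_mask <- rep(FALSE, 2)
  blk$dp_mlp$meta$forced_mask <- rep(FALSE, 2)
  set.seed(32)
  x <- array(rnorm(2 * 16 * 5 * 5), c(2, 16, 5, 5))
  y <- ns$smblock_fwd(blk, x, training = TRUE)
  expect_lt(max(abs(y - o_gelu(x))), 1e-12)
})

test_that("the assembled network follows the documented spatial schedule", {
  ns <- asNamespace("starmanet")
  net <- buildStarMANet(slim_cfg())
  set.seed(33)
  x <- array(runif(1 * 3 * 224 * 224), c(1, 3, 224, 224))
  sizes <- integer(0)
  for (s in net@state$stages) {
    x <- ns$stage_fwd(s, x, FALSE)
    if (s$kind %in% c("conv", "maxpool", "smblock") && length(dim(x)) == 4)
      sizes <- c(sizes, dim(x)[3])
  }
  # stem stride-2 then three pools then constant trunk then output stride-2
  expect_equal(sizes[1], 112)
  expect_true(all(c(56, 28, 14, 7) %in% sizes))
  expect_equal(sum(sizes == 14), 6)   # 1 base conv output + 4 blocks + normal
  expect_equal(dim(x), c(1, 2))
})

test_that("any input size divisible by 32 yields valid logits and zero dropPath is deterministic", {
  net <- buildStarMANet(tiny_cfg())
  set.seed(34)
  x <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  lg <- forwardPass(net, x)
  expect_equal(dim(lg), c(2, 2))
  expect_true(all(is.finite(lg)))
  expect_identical(lg, forwardPass(net, x))
  x96 <- array(runif(1 * 3 * 96 * 96), c(1, 3, 96, 96))
  expect_equal(dim(forwardPass(net, x96)), c(1, 2))
})

test_that("ablation flags reproduce the full model when all on and run all switch rows", {
  set.seed(35)
  x <- array(runif(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  base <- tiny_cfg()
  full <- buildStarMANet(base)
  same <- applyAblation(base, useCcib = TRUE, useSss = TRUE,
                        useScb = TRUE, useCsfa = TRUE)
  expect_identical(forwardPass(full, x), forwardPass(same, x))
  rows <- list(c(TRUE, TRUE, FALSE, FALSE),   # CCIB + SSS only
               c(FALSE, FALSE, TRUE, FALSE),  # SCB only
               c(TRUE, TRUE, TRUE, FALSE),    # both branches, no CSFA
               c(TRUE, FALSE, TRUE, TRUE),    # no star structure
               c(TRUE, TRUE, TRUE, TRUE))     # full
  outs <- lapply(rows, function(r) {
    m <- applyAblation(base, r[1], r[2], r[3], r[4])
    forwardPass(m, x)
  })
  for (o in outs) expect_true(all(is.finite(o)))
  # disabling a sub-module changes the function
  expect_gt(max(abs(outs[[4]] - outs[[5]])), 0)
  expect_error(applyAblation(base, useCcib = FALSE, useScb = FALSE),
               "at least one")
})

test_that("width halving cuts parameters by roughly the quadratic factor", {
  p1 <- countParams(starmaNetArch(backboneConfig()))
  p5 <- countParams(starmaNetArch(backboneConfig(widthMultiplier = 0.5)))
  ratio <- p1 / p5
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("backbone configurations round-trip through YAML", {
  cfg <- tiny_cfg(numClasses = 5L, dropPath = 0.1)
  path <- tempfile(fileext = ".yaml")
  writeBackboneConfig(cfg, path)
  back <- readBackboneConfig(path)
  for (sn in slotNames(cfg))
    if (sn != "starma") expect_equal(slot(back, sn), slot(cfg, sn))
  expect_equal(back@starma@groups, cfg@starma@groups)
  expect_equal(back@starma@scbKernels, cfg@starma@scbKernels)
})
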