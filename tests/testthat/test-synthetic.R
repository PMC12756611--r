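# Synthetic lesion-image generator: determinism, construction guarantees,
# class separability, stratified splitting and image-folder round trips.

small_spec <- function(...) {
  syntheticImageSpec(nClasses = 2L, counts = c(10L, 10L),
                     imageSize = c(32L, 32L), seed = 7L, ...)
}

test_that("identical spec and seed give bit-identical datasets", {
  d1 <- generateLesionImages(small_spec())
  d2 <- generateLesionImages(small_spec())
  expect_identical(d1@images, d2@images)
  expect_identical(d1@masks, d2@masks)
  expect_identical(d1@split, d2@split)
  # a different seed changes the pixels
  d3 <- generateLesionImages(syntheticImageSpec(nClasses = 2L,
                                                counts = c(10L, 10L),
                                                imageSize = c(32L, 32L),
                                                seed = 8L))
  expect_false(identical(d1@images, d3@images))
})

test_that("with noise and texture off, lesion pixels exceed background by exactly the contrast", {
  params <- lapply(1:2, function(k)
    list(radiusRange = c(4, 6) * k, eccRange = c(1, 1), contrast = 0.35,
         textureFreq = 4, textureAmp = 0))
  spec <- syntheticImageSpec(nClasses = 2L, counts = c(5L, 5L),
                             imageSize = c(48L, 48L), classParams = params,
                             speckleVar = 0, gaussianSd = 0, seed = 9L)
  ds <- generateLesionImages(spec)
  for (i in seq_len(10)) {
    m <- ds@masks[i, , ]
    diff <- mean(ds@images[i, , ][m]) - mean(ds@images[i, , ][!m])
    expect_equal(diff, 0.35, tolerance = 1e-12)
  }
})

test_that("classes are separable by lesion size from the stored masks", {
  spec <- syntheticImageSpec(nClasses = 2L, counts = c(50L, 50L),
                             imageSize = c(64L, 64L), seed = 10L)
  ds <- generateLesionImages(spec)
  area <- apply(ds@masks, 1, sum)
  thr <- mean(c(max(area[ds@labels == 0]), min(area[ds@labels == 1])))
  pred <- as.integer(area > thr)
  expect_gte(mean(pred == ds@labels), 0.99)
})

test_that("impossible lesion geometry is rejected at spec construction", {
  params <- list(list(radiusRange = c(30, 40), eccRange = c(1, 1),
                      contrast = 0.3, textureFreq = 2, textureAmp = 0.05),
                 list(radiusRange = c(2, 3), eccRange = c(1, 1),
                      contrast = 0.3, textureFreq = 2, textureAmp = 0.05))
  expect_error(syntheticImageSpec(nClasses = 2L, counts = c(2L, 2L),
                                  imageSize = c(32L, 32L),
                                  classParams = params),
               "does not fit")
})

test_that("stratified splits follow the 7:1.5:1.5 rounding rule", {
  # one class, 100 samples: exact 70/15/15
  spec <- syntheticImageSpec(nClasses = 2L, counts = c(100L, 100L),
                             imageSize = c(16L, 16L), seed = 11L,
                             classParams = lapply(1:2, function(k)
                               list(radiusRange = c(2, 3), eccRange = c(1, 1),
                                    contrast = 0.3, textureFreq = 2,
                                    textureAmp = 0)))
  ds <- generateLesionImages(spec)
  for (k in 0:1) {
    tab <- table(ds@split[ds@labels == k])
    expect_equal(as.numeric(tab[c("train", "val", "test")]), c(70, 15, 15))
  }
  # 780 samples in one class: round(0.15*780) = 117 each, remainder 546 to train
  one <- new("LabeledImageSet", images = array(0, c(780, 4, 4)),
             labels = rep(0L, 780), masks = array(FALSE, c(780, 4, 4)),
             classNames = "c0", split = rep("train", 780), spec = NULL)
  sp <- splitDataset(one, seed = 3L)
  expect_equal(sum(sp@split == "train"), 546)
  expect_equal(sum(sp@split == "val"), 117)
  expect_equal(sum(sp@split == "test"), 117)
  # deterministic under seed, permuted under another seed, same sizes
  sp2 <- splitDataset(one, seed = 3L)
  expect_identical(sp@split, sp2@split)
  sp3 <- splitDataset(one, seed = 4L)
  expect_false(identical(sp@split, sp3@split))
  expect_equal(table(sp@split), table(sp3@split))
  # classes too small to split go entirely to train, with a warning
  tiny <- new("LabeledImageSet", images = array(0, c(2, 4, 4)),
              labels = c(0L, 0L), masks = array(FALSE, c(2, 4, 4)),
              classNames = "c0", split = rep("train", 2), spec = NULL)
  expect_warning(spt <- splitDataset(tiny), "too few")
  expect_true(all(spt@split == "train"))
})

test_that("image-folder export/import round-trips labels and pixel content", {
  ds <- generateLesionImages(small_spec())
  root <- file.path(tempdir(), "synth_tree")
  unlink(root, recursive = TRUE)
  exportImageFolder(ds, root)
  pngs <- list.files(root, pattern = "\\.png$", recursive = TRUE)
  expect_equal(length(pngs), 20)
  expect_true(all(c("train", "val", "test") %in% list.dirs(root, FALSE, FALSE)))
  back <- importImageFolder(root)
  expect_equal(length(back@labels), 20)
  expect_equal(sort(table(back@labels)), sort(table(ds@labels)),
               ignore_attr = TRUE)
  # pixel content preserved up to 8-bit quantization
  i <- which(ds@split == "train")[1]
  cl <- ds@classNames[ds@labels[i] + 1]
  f <- list.files(file.path(root, "train", cl), full.names = TRUE)[1]
  reread <- png::readPNG(f)
  orig_in_class <- ds@images[ds@split == "train" & ds@labels == ds@labels[i], , ,
                             drop = FALSE]
  errs <- apply(orig_in_class, 1, function(im) max(abs(im - reread)))
  expect_lt(min(errs), 1 / 255)
  # empty dataset: empty tree, no error
  empty <- new("LabeledImageSet", images = array(0, c(0, 4, 4)),
               labels = integer(0), masks = array(FALSE, c(0, 4, 4)),
               classNames = character(0), split = character(0), spec = NULL)
  root2 <- file.path(tempdir(), "empty_tree")
  expect_no_error(exportImageFolder(empty, root2))
  expect_true(dir.exists(root2))
})
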