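# IDX ingestion, delimited round-trips, synthetic generation, truncation
# and label shuffling.

writeIDXPair <- function(pixels, labels, dir = NULL,
                         rows = NULL, cols = NULL) {
  # pixels: list of integer matrices (rows x cols), values 0..255
  if (is.null(dir)) {
    dir <- tempfile("idx")
    dir.create(dir)
  }
  rows <- rows %||% nrow(pixels[[1]])
  cols <- cols %||% ncol(pixels[[1]])
  imgPath <- file.path(dir, "images.idx")
  labPath <- file.path(dir, "labels.idx")
  con <- file(imgPath, "wb")
  writeBin(c(2051L, length(pixels), rows, cols), con, size = 4L,
           endian = "big")
  for (p in pixels) # row-major pixel order
    writeBin(as.raw(as.integer(t(p))), con)
  close(con)
  con <- file(labPath, "wb")
  writeBin(c(2049L, length(labels)), con, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  close(con)
  list(images = imgPath, labels = labPath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("IDX reader scales pixels to [0,1] and flattens row-major", {
  px <- list(matrix(c(0L, 255L, 0L, 255L), 2, byrow = TRUE),
             matrix(c(255L, 0L, 255L, 0L), 2, byrow = TRUE))
  paths <- writeIDXPair(px, c(3L, 7L))
  lm <- readIDX(paths$images, paths$labels)
  expect_equal(dim(features(lm)), c(2L, 4L))
  expect_equal(features(lm)[1, ], c(0, 1, 0, 1))
  expect_equal(features(lm)[2, ], c(1, 0, 1, 0))
  expect_equal(labels(lm), c(3L, 7L))
})

test_that("IDX reader reproduces an exact hand-built byte fixture", {
  # 3 images, 2x3 pixels, bytes chosen so each flattened row is distinct
  px <- list(matrix(0:5, 2, 3, byrow = TRUE),
             matrix(c(10L, 20L, 30L, 40L, 50L, 60L), 2, 3, byrow = TRUE),
             matrix(rep(255L, 6), 2, 3))
  paths <- writeIDXPair(px, c(0L, 1L, 2L))
  lm <- readIDX(paths$images, paths$labels)
  expect_equal(features(lm)[1, ], (0:5) / 255)
  expect_equal(features(lm)[2, ], c(10, 20, 30, 40, 50, 60) / 255)
  expect_equal(features(lm)[3, ], rep(1, 6))
})

test_that("IDX reader rejects bad magic numbers and count mismatches", {
  px <- list(matrix(0L, 2, 2))
  paths <- writeIDXPair(px, 1L)
  bad <- file.path(withr::local_tempdir(), "bad.idx")
  con <- file(bad, "wb")
  writeBin(c(1234L, 1L, 2L, 2L), con, size = 4L, endian = "big")
  writeBin(as.raw(rep(0L, 4)), con)
  close(con)
  expect_error(readIDX(bad, paths$labels), "magic")
  paths2 <- writeIDXPair(px, c(1L, 2L)) # 1 image, 2 labels
  expect_error(readIDX(paths2$images, paths2$labels), "mismatch")
})

test_that("delimited read/write round-trips at full precision", {
  ds <- makeToyData(k = 2L, n = 3L, perClass = 4L, standardize = FALSE)
  path <- file.path(withr::local_tempdir(), "toy.csv")
  writeDelimited(ds$train, path)
  back <- readDelimited(path, "label")
  expect_equal(features(back), features(ds$train))
  expect_equal(labels(back), labels(ds$train))
  expect_equal(classCount(back), 2L)
})

test_that("delimited reader validates labels and rejects missing cells", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.csv")
  writeLines(c("f1,f2,label", "1.5,2.0,0", "0.5,,1"), path)
  expect_error(readDelimited(path, "label"), "missing|numeric")
  path2 <- file.path(dir, "toy2.csv")
  writeLines(c("f1,f2,label", "1,2,0.5"), path2)
  expect_error(readDelimited(path2, "label"), "integer")
})

test_that("delimited standardization gives per-feature mean 0 and SD 1", {
  ds <- makeToyData(k = 2L, n = 5L, perClass = 10L, standardize = FALSE)
  path <- file.path(withr::local_tempdir(), "toy.csv")
  writeDelimited(ds$train, path)
  std <- readDelimited(path, "label", standardize = TRUE)
  X <- features(std)
  expect_equal(colMeans(X), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(X, 2, sd), rep(1, 5), tolerance = 1e-12)
})

test_that("synthetic generator is deterministic and balanced", {
  a <- generateSynthetic(3, 20, 5, seed = 42)
  b <- generateSynthetic(3, 20, 5, seed = 42)
  expect_identical(features(a$train), features(b$train))
  expect_identical(features(a$test), features(b$test))
  expect_equal(as.integer(table(labels(a$train))), rep(5L, 3))
  c <- generateSynthetic(3, 20, 5, seed = 43)
  expect_false(identical(features(a$train), features(c$train)))
})

test_that("noise-free, nuisance-free trials coincide with their prototype", {
  ds <- generateSynthetic(3, 10, 4, noiseSd = 0, irrelevantScale = 0,
                          seed = 7)
  X <- features(ds$train); y <- labels(ds$train)
  for (cls in 0:2) {
    Xc <- X[y == cls, , drop = FALSE]
    expect_equal(max(dist(Xc)), 0) # within-class distances exactly 0
  }
})

test_that("structureless data has near-zero input class specificity", {
  ds <- generateSynthetic(10, 50, 100, prototypeScale = 0,
                          irrelevantScale = 0, noiseSd = 1, seed = 9)
  cs <- classSpecificity(features(ds$train), labels(ds$train))
  expect_lt(abs(cs), 0.05)
})

test_that("generator rejects degenerate specs", {
  expect_error(generateSynthetic(3, 10, 1), "exemplarsPerClass")
  expect_error(generateSynthetic(3, 10, 4, irrelevantRank = 10), ".")
})

test_that("truncation is stratified, deterministic, and exact at 98%", {
  ds <- generateSynthetic(4, 8, 50, seed = 3)
  tr <- truncateData(ds$train, 0.5, replicate = 1L, seed = 11)
  expect_equal(as.integer(table(labels(tr))), rep(25L, 4))
  tr2 <- truncateData(ds$train, 0.5, replicate = 1L, seed = 11)
  expect_identical(features(tr), features(tr2))
  tr3 <- truncateData(ds$train, 0.5, replicate = 2L, seed = 11)
  expect_false(identical(features(tr), features(tr3)))
  expect_identical(truncateData(ds$train, 0), ds$train)
  expect_error(truncateData(ds$train, 0.999), "empty class")
})

test_that("stratified truncation preserves balance within one exemplar", {
  ds <- generateSynthetic(5, 6, 21, seed = 13)
  for (frac in c(0.1, 0.3, 0.7, 0.9)) {
    kept <- table(labels(truncateData(ds$train, frac, seed = 5)))
    expect_lte(diff(range(kept)), 1)
  }
})

test_that("label shuffling permutes labels, preserves marginals, fixes features", {
  ds <- generateSynthetic(4, 10, 10, seed = 5)
  sh <- shuffleLabels(ds$train, seed = 21)
  expect_identical(features(sh), features(ds$train))
  expect_equal(table(labels(sh)), table(labels(ds$train)))
  expect_false(identical(labels(sh), labels(ds$train)))
  sh2 <- shuffleLabels(ds$train, seed = 21)
  expect_identical(labels(sh), labels(sh2))
  one <- subsetTrials(ds$train, 1L)
  expect_identical(labels(shuffleLabels(one, seed = 1)), labels(one))
})

test_that("LabeledMatrix validates labels and remaps 1-based input", {
  expect_error(LabeledMatrix(matrix(NA_real_, 2, 2), c(0, 1)), ".")
  lm <- LabeledMatrix(matrix(rnorm(8), 4), labels = c(1, 1, 2, 2))
  expect_equal(labels(lm), c(0L, 0L, 1L, 1L))
  expect_equal(classCount(lm), 2L)
})
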