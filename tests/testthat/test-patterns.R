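# Synthetic dataset generators, noise corruption, image fixtures, IDX files.

test_that("RAND patterns have exact per-row activity and reproduce bit-identically", {
  s <- gen_rand(200, 50, 0.35, seed = 1)
  expect_true(all(rowSums(as.matrix(s)) == 70))
  expect_identical(as.matrix(gen_rand(200, 50, 0.35, seed = 1)), as.matrix(s))
  expect_false(identical(as.matrix(gen_rand(200, 50, 0.35, seed = 2)),
                         as.matrix(s)))

  # all-ones edge and degenerate activity
  expect_true(all(as.matrix(gen_rand(10, 3, 0.96, seed = 1)) == 1))
  expect_error(gen_rand(10, 3, 0.04, seed = 1), "zero active")

  # near-zero mean pairwise correlation for uncorrelated patterns
  m <- as.matrix(gen_rand(200, 200, 0.35, seed = 3))
  cm <- cor(t(m))
  expect_lt(abs(mean(cm[upper.tri(cm)])), 0.05)
})

test_that("RAND-CORR consecutive correlation matches the closed form", {
  # flipping f = 0.05*n of each polarity: P(1,1) = 0.30,
  # corr = (0.30 - 0.35^2) / (0.35 * 0.65) = 0.78022
  s <- gen_rand_corr(1000, 100, 0.35, 0.1, seed = 11)
  m <- as.matrix(s)
  cc <- vapply(1:99, function(t) as.numeric(pearson(m[t, ], m[t + 1, ])),
               numeric(1))
  expect_equal(mean(cc), (0.30 - 0.35^2) / (0.35 * 0.65), tolerance = 0.01)
  expect_true(all(rowSums(m) == 350))

  # zero flips: constant sequence
  s0 <- gen_rand_corr(100, 5, 0.35, 0, seed = 2)
  expect_true(all(apply(as.matrix(s0), 2, function(col) length(unique(col))) == 1))

  expect_error(gen_rand_corr(20, 5, 0.1, 0.9, seed = 1), "flip count")
})

test_that("RAND-CORR correlation decays monotonically with lag", {
  lags <- c(1, 2, 5, 10)
  acc <- matrix(0, 10, length(lags))
  for (i in 1:10) {
    m <- as.matrix(gen_rand_corr(400, 60, 0.35, 0.1, seed = 100 + i))
    acc[i, ] <- vapply(lags, function(d) {
      mean(vapply(1:(60 - d), function(t)
        as.numeric(pearson(m[t, ], m[t + d, ])), numeric(1)))
    }, numeric(1))
  }
  avg <- colMeans(acc)
  expect_true(all(diff(avg) < 0))
})

test_that("binary noise conserves activity and flips exactly 2k units", {
  x <- as.matrix(gen_rand(200, 1, 0.35, seed = 5))[1, ]
  expect_identical(add_binary_noise(x, 0, seed = 1), x)
  for (pct in c(0.1, 0.2, 0.5)) {
    y <- add_binary_noise(x, pct, seed = 9)
    k <- round(pct * 70)
    expect_equal(sum(y), sum(x))
    expect_equal(sum(y != x), 2 * k)
  }
  expect_error(add_binary_noise(c(1, 1, 1, 0), 1, seed = 1), "cannot flip")

  # expected on-unit overlap after noise: 1 - k/n_on exactly (k on-units off)
  y <- add_binary_noise(x, 0.2, seed = 33)
  expect_equal(sum(x * y) / sum(x), 1 - 14 / 70)
})

test_that("synthetic images are near-binary with bounded foreground", {
  imgs <- gen_synthetic_images(20, 16, 16, seed = 4)
  px <- imgs$images
  expect_equal(dim(px), c(20, 16, 16))
  expect_true(min(px) >= 0 && max(px) <= 1)
  expect_gte(mean(px <= 0.1 | px >= 0.9), 0.6)
  fg <- apply(px > 0.5, 1, mean)
  expect_true(all(fg >= 0.1 & fg <= 0.5))
  expect_identical(gen_synthetic_images(20, 16, 16, seed = 4)$images, px)

  one <- gen_synthetic_images(1, 8, 12, seed = 1)
  expect_equal(dim(one$images), c(1, 8, 12))
})

test_that("IDX files round-trip bit-identically and reject bad magic", {
  imgs <- gray_image_set(array(round(runif(2 * 5 * 4) , 2), c(2, 5, 4)),
                         labels = c(3L, 7L))
  ipath <- withr::local_tempfile(fileext = ".idx")
  lpath <- withr::local_tempfile(fileext = ".idx")
  hipposeq:::write_idx_images(imgs, ipath)
  hipposeq:::write_idx_labels(imgs$labels, lpath)
  back <- load_mnist(ipath, lpath)
  expect_equal(dim(back$images), c(2, 5, 4))
  expect_equal(back$images, round(imgs$images * 255) / 255)
  expect_identical(back$labels, c(3L, 7L))

  # label file offered as an image file: magic mismatch
  expect_error(load_mnist(lpath), "magic")
  # truncated payload
  bad <- withr::local_tempfile()
  con <- file(bad, "wb")
  writeBin(c(2051L, 2L, 5L, 4L), con, size = 4L, endian = "big")
  writeBin(as.raw(1:10), con)
  close(con)
  expect_error(load_mnist(bad), "truncated")
})

test_that("sequences export to CSV with positions", {
  s <- gen_rand(10, 4, 0.3, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence_csv(s, path)
  df <- read.csv(path)
  expect_equal(df$position, 1:4)
  expect_equal(unname(as.matrix(df[, -1])), unname(as.matrix(s)))
})
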