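blob_image <- function(nr, nc, pixels, fg = 1, bg = 0) {
  img <- matrix(bg, nr, nc)
  for (p in pixels) img[p[1], p[2]] <- fg
  img
}

test_that("binarization thresholds and filters pixel islands", {
  expect_error(binarize_and_clean(matrix(0, 8, 8), threshold = 0.5),
               class = "shapelength_empty_image")

  # one 5x20 blob plus a 3-pixel island: only the blob survives
  img <- matrix(0, 30, 40)
  img[10:14, 5:24] <- 1
  img[25, 30] <- img[25, 31] <- img[26, 30] <- 1
  bi <- binarize_and_clean(img, threshold = 0.5, min_island = 5)
  expect_identical(sum(bi$mask), 100L)
  expect_identical(count_components(bi$mask), 1L)

  # salt noise: isolated pixels vanish, component count drops to one
  set.seed(301)
  noisy <- img
  salt <- cbind(sample(1:30, 12), sample(1:40, 12))
  for (i in 1:12) noisy[salt[i, 1], salt[i, 2]] <- 1
  before <- count_components(noisy > 0.5)
  bi2 <- binarize_and_clean(noisy, threshold = 0.5, min_island = 5)
  expect_gte(before, 1L)
  expect_identical(count_components(bi2$mask), 1L)

  # automatic (Otsu) threshold separates a bimodal image
  gray <- matrix(rnorm(900, 0.2, 0.03), 30, 30)
  gray[10:20, 5:25] <- rnorm(11 * 21, 0.8, 0.03)
  bi3 <- binarize_and_clean(gray, min_island = 5)
  expect_identical(sum(bi3$mask), 11L * 21L)
})

test_that("thinning reduces a wide bar to its midline path", {
  img <- matrix(0, 12, 30)
  img[5:7, 4:23] <- 1   # 3-pixel-wide horizontal bar, length 20
  path <- thin_and_debranch(binarize_and_clean(img, threshold = 0.5))
  expect_true(is_single_width(path))
  # path runs along the middle row (y = 12 - 6 = 6), possibly shortened by
  # an end pixel or two
  expect_true(all(abs(path$y - 6) <= 1))
  expect_gte(nrow(path), 17)
  expect_true(all(trace_chain_code(path) %in% c(0L, 1L, 7L)) ||
                all(trace_chain_code(path) %in% c(4L, 3L, 5L)))
})

test_that("debranching keeps the longest arm pair of a plus-shaped blob", {
  img <- matrix(0, 21, 21)
  img[11, 3:19] <- 1   # long horizontal arm (17 px)
  img[7:15, 11] <- 1   # short vertical arm (9 px)
  path <- thin_and_debranch(img > 0.5)
  expect_true(is_single_width(path))

  # oracle: exhaustive longest simple path over the skeleton graph
  skel <- which(shapelength:::cpp_thin(img > 0.5), arr.ind = TRUE)
  adj <- lapply(seq_len(nrow(skel)), function(i) {
    which(abs(skel[, 1] - skel[i, 1]) <= 1 & abs(skel[, 2] - skel[i, 2]) <= 1 &
            !(skel[, 1] == skel[i, 1] & skel[, 2] == skel[i, 2]))
  })
  # longest simple path that stays single-width: an extension may touch
  # only its immediate predecessor among the pixels already on the path
  longest <- 0L
  dfs <- function(v, trail) {
    longest <<- max(longest, length(trail))
    for (w in adj[[v]]) {
      if (w %in% trail) next
      touches <- adj[[w]][adj[[w]] %in% trail]
      if (!identical(touches, v)) next
      dfs(w, c(trail, w))
    }
  }
  for (s in seq_len(nrow(skel))) dfs(s, s)
  expect_identical(nrow(path), as.integer(longest))
  # the retained path is the horizontal arm
  expect_true(all(abs(path$y - 10) <= 1))
})

test_that("closed loops are rejected as unsupported topology", {
  img <- matrix(0, 15, 15)
  img[4:12, 4:12] <- 1
  img[6:10, 6:10] <- 0   # square annulus
  expect_error(thin_and_debranch(img > 0.5),
               class = "shapelength_unsupported_topology")
  # two disjoint blobs are rejected too (clean the image first)
  img2 <- matrix(0, 10, 20)
  img2[3:5, 2:8] <- 1
  img2[7:8, 14:18] <- 1
  expect_error(thin_and_debranch(img2 > 0.5),
               class = "shapelength_unsupported_topology")
})

test_that("paths and masks round-trip through CSV and PNG", {
  set.seed(302)
  cc <- random_valid_chain(25)
  path <- follow_chain_code(cc, origin = c(5L, 9L))
  f <- tempfile(fileext = ".csv")
  write_path_csv(path, f)
  back <- read_path_csv(f)
  expect_identical(back$x, path$x)
  expect_identical(back$y, path$y)

  img <- matrix(0, 10, 12)
  img[4:6, 3:9] <- 1
  bi <- binarize_and_clean(img, threshold = 0.5)
  p <- tempfile(fileext = ".png")
  write_mask_png(bi, p)
  re <- read_strand_image(p)
  expect_identical(dim(re), dim(img))
  expect_identical(re > 0.5, bi$mask)
})

test_that("image-derived and simulator-derived paths chain-code identically", {
  # rasterized contour re-painted into an image and re-extracted gives a
  # backbone with the same shape tallies
  set.seed(303)
  w <- generate_wlc(200, 50)
  sp <- rasterize_contour(w, 5.1)
  px <- sp$x - min(sp$x)
  py <- sp$y - min(sp$y)
  img <- matrix(0, max(py) + 3, max(px) + 3)
  for (i in seq_len(nrow(sp))) img[nrow(img) - py[i] - 1, px[i] + 2] <- 1
  path <- thin_and_debranch(img > 0.5)
  expect_true(is_single_width(path))
  t1 <- shape_tally(trace_chain_code(sp))
  t2 <- shape_tally(trace_chain_code(path))
  expect_identical(as.matrix(t1[paste0("k", 1:12)]),
                   as.matrix(t2[paste0("k", 1:12)]))
})
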