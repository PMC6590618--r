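# Image preprocessing: thresholding, island filtering, thinning, debranching.
#
# The pipeline mirrors the standard AFM workflow: a grayscale image of a
# single strand is binarized, isolated pixel islands are removed, the
# remaining blob is thinned to a skeleton and debranched to an ordered
# single-width backbone.  Coordinates use (x, y) with y increasing upward;
# image rows are converted on read (y = height - row).

#' Read a grayscale strand image
#'
#' Reads 8/16-bit grayscale PNG or TIFF into a numeric matrix in \[0, 1\];
#' colour images are averaged across channels.
#'
#' @param file Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix (rows = image rows, top first).
#' @export
read_strand_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = tiff::readTIFF(file),
    abort(paste0("unsupported image format: .", ext),
          class = "shapelength_io_error")
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

otsu_threshold <- function(img, nbins = 256L) {
  v <- as.vector(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(
    pmin(nbins, 1L + floor((v - rng[1]) / (rng[2] - rng[1]) * nbins)),
    nbins
  )
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  kstar <- which.max(sigma_b)
  rng[1] + kstar / nbins * (rng[2] - rng[1])
}

#' Binarize a grayscale image and remove pixel islands
#'
#' Thresholds the image (Otsu's method by default, or a fixed fraction of
#' the intensity range), drops connected components smaller than
#' `min_island` pixels, and keeps the largest remaining component -- the
#' single strand the image is expected to contain.
#'
#' @param img Numeric matrix (grayscale intensities).
#' @param threshold `NULL` for automatic (Otsu), or a fraction in (0, 1) of
#'   the intensity range.
#' @param min_island Minimum component size in pixels to survive filtering.
#' @param pixel_size Pixel resolution r in nm/pixel, carried on the result.
#' @return An `sl_binary_image`: list with logical matrix `mask` and
#'   `pixel_size`.
#' @export
binarize_and_clean <- function(img, threshold = NULL, min_island = 5L,
                               pixel_size = 1) {
  stopifnot(is.matrix(img), length(img) > 0)
  thr <- if (is.null(threshold)) {
    otsu_threshold(img)
  } else {
    stopifnot(threshold > 0, threshold < 1)
    min(img) + threshold * (max(img) - min(img))
  }
  mask <- img > thr
  if (!any(mask)) {
    abort("no foreground pixels after thresholding",
          class = "shapelength_empty_image")
  }
  lab <- cpp_label(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_island)
  if (!length(keep)) {
    abort("no foreground component survives island filtering",
          class = "shapelength_empty_image")
  }
  largest <- keep[which.max(sizes[keep])]
  structure(list(mask = lab == largest, pixel_size = pixel_size),
            class = "sl_binary_image")
}

#' @export
print.sl_binary_image <- function(x, ...) {
  cat(sprintf(
    "<sl_binary_image> %d x %d, %d foreground pixels, r = %g nm/pixel\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), x$pixel_size
  ))
  invisible(x)
}

#' Thin a binary strand image and extract the debranched backbone
#'
#' Applies two-subiteration (Zhang-Suen) thinning until stable, then
#' retains the longest endpoint-to-endpoint simple path of the skeleton
#' (side branches pruned, ties broken by the lexicographically smallest
#' endpoint), ordered from one endpoint to the other.
#'
#' @param img An `sl_binary_image` from [binarize_and_clean()], or a
#'   logical matrix.
#' @return An `sl_path` tibble (`index`, `x`, `y`) with attribute
#'   `resolution`; fails with a classed error on closed loops
#'   (`shapelength_unsupported_topology`) or skeletons that stay wider than
#'   one pixel (`shapelength_degenerate_skeleton`).
#' @export
thin_and_debranch <- function(img) {
  if (inherits(img, "sl_binary_image")) {
    mask <- img$mask
    r <- img$pixel_size
  } else {
    stopifnot(is.matrix(img))
    mask <- img
    storage.mode(mask) <- "logical"
    r <- 1
  }
  skel <- cpp_thin(mask)
  res <- cpp_backbone(skel)
  if (res$status == 1L) {
    abort("empty image", class = "shapelength_empty_image")
  }
  if (res$status == 2L) {
    abort("image contains more than one connected component",
          class = "shapelength_unsupported_topology")
  }
  if (res$status == 3L) {
    abort("closed-loop molecules are not supported",
          class = "shapelength_unsupported_topology")
  }
  if (res$status == 4L) {
    abort("skeleton violates single-width after pruning",
          class = "shapelength_degenerate_skeleton")
  }
  out <- tibble(
    index = seq_len(nrow(res$path)) - 1L,
    x = res$path[, 2] - 1L,               # col -> x
    y = nrow(mask) - res$path[, 1]        # row -> y, flipped so y points up
  )
  structure(out, resolution = r, pruned = res$pruned,
            class = c("sl_path", class(out)))
}

#' Write a binary mask as PNG
#'
#' @param img An `sl_binary_image` or logical matrix.
#' @param file Output path.
#' @export
write_mask_png <- function(img, file) {
  mask <- if (inherits(img, "sl_binary_image")) img$mask else img
  png::writePNG(mask * 1, file)
  invisible(file)
}

#' Read / write a pixel path as CSV
#'
#' Plain CSV with columns `index`, `x`, `y`.
#'
#' @param path An `sl_path` (or any data frame with `index`, `x`, `y`).
#' @param file File path.
#' @export
write_path_csv <- function(path, file) {
  utils::write.csv(as.data.frame(path)[c("index", "x", "y")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(file) {
  d <- utils::read.csv(file)
  stopifnot(all(c("index", "x", "y") %in% names(d)))
  out <- tibble(index = as.integer(d$index), x = as.integer(d$x),
                y = as.integer(d$y))
  structure(out, class = c("sl_path", class(out)))
}
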