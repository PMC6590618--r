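# Worm-like-chain contour synthesis and rasterization.
#
# Contours are discrete 2D worm-like chains: unit steps of `step` nm whose
# heading performs a Gaussian random walk with increment variance step/l_p,
# so the in-plane tangent correlation decays as exp(-s / (2 l_p)) -- the 2D
# projection of a chain with persistence length l_p.  Self-intersecting
# realizations are rejected and redrawn, since a self-crossing strand cannot
# be skeletonized into a simple path.  Rasterization digitizes the curve
# directly to a single-pixel-width chain: the ordered sequence of pixels
# containing the curve at sub-pixel arc-length sampling, with staircase
# corner pixels shortcut away so the chain satisfies the strict single-width
# property; draws whose chain revisits or touches itself are rejected and
# redrawn.  Digitizing the curve itself -- rather than thinning a marked
# band -- preserves the staircase detail of the digitized contour, and with
# it the well-documented overestimation of the uncorrected Freeman estimate
# that the shape coefficients correct.

#' Generate a 2D worm-like-chain contour
#'
#' @param l_c True contour length in nm.
#' @param l_p Persistence length in nm (50 for double-stranded DNA).
#' @param step Discretization step in nm (default 1; keep well below `l_p`).
#' @param reject_self_intersection Redraw self-crossing realizations.
#' @param max_tries Redraw budget before failing.
#' @return An `sl_contour` tibble with `x`, `y` vertex coordinates in nm and
#'   attributes `true_length`, `persistence`, `step`.
#' @export
generate_wlc <- function(l_c, l_p = 50, step = 1,
                         reject_self_intersection = TRUE, max_tries = 1000L) {
  stopifnot(l_c > 0, l_p > 0, step > 0)
  if (step > l_p / 5) {
    warn("discretization step should be well below the persistence length")
  }
  m <- cpp_wlc(l_c, l_p, step, reject_self_intersection, as.integer(max_tries))
  out <- tibble(x = m[, 1], y = m[, 2])
  structure(out, true_length = l_c, persistence = l_p, step = step,
            class = c("sl_contour", class(out)))
}

#' Rasterize a continuous contour to a single-width pixel path
#'
#' Digitizes the curve at `r / subsample` arc-length sampling into the
#' ordered sequence of pixels it passes through, shortcutting staircase
#' corner pixels so the chain is strictly single-width.  Draws whose chain
#' revisits a pixel or touches itself (the curve approaching within about a
#' pixel of itself), or that span fewer than 4 pixels, are rejected with a
#' classed condition (`shapelength_rasterize_rejected`) so callers can
#' redraw.
#'
#' @param contour An `sl_contour` (or any matrix/data frame of `x`, `y` in nm).
#' @param r Pixel resolution in nm/pixel.
#' @param subsample Sub-pixel sampling factor (default 10).
#' @return An `sl_path` tibble (`index`, `x`, `y` in pixel units) with
#'   attributes `resolution` and `true_length`.
#' @export
rasterize_contour <- function(contour, r, subsample = 10L) {
  stopifnot(r > 0)
  p <- path_xy(contour)
  res <- cpp_rasterize(cbind(p$x, p$y), r, as.integer(subsample))
  if (res$status != 0L) {
    reason <- c("4" = "digitized chain touches or revisits itself",
                "5" = "contour spans fewer than 4 pixels")[as.character(res$status)]
    abort(paste0("rasterization rejected: ", reason),
          class = "shapelength_rasterize_rejected", status = res$status)
  }
  out <- tibble(index = seq_len(nrow(res$path)) - 1L,
                x = res$path[, 1], y = res$path[, 2])
  structure(out, resolution = r,
            true_length = attr(contour, "true_length"),
            class = c("sl_path", class(out)))
}

#' Simulate single-width skeleton samples of known length
#'
#' Draws worm-like chains and rasterizes them, redrawing on rejection,
#' until `n` clean single-width skeletons are produced.  Randomness comes
#' from R's RNG stream: call `set.seed()` first for reproducibility.
#'
#' @inheritParams generate_wlc
#' @inheritParams rasterize_contour
#' @param n Number of samples.
#' @param max_tries Per-sample redraw budget.
#' @return Tibble with one row per sample: `sample`, `true_length`,
#'   `resolution`, `n_pixels` and a `path` list-column of integer (x, y)
#'   matrices.  Attribute `"attempts"` counts all draws.
#' @export
simulate_skeletons <- function(n, l_c, r, l_p = 50, step = 1,
                               subsample = 10L, max_tries = 500L) {
  stopifnot(n >= 1, l_c > 0, r > 0, l_p > 0, step > 0)
  res <- cpp_simulate_batch(as.integer(n), l_c, l_p, step, r,
                            as.integer(subsample), as.integer(max_tries))
  out <- tibble(
    sample = seq_len(n),
    true_length = l_c,
    resolution = r,
    n_pixels = vapply(res$paths, nrow, integer(1)),
    path = res$paths
  )
  structure(out, attempts = res$attempts, class = class(out))
}

#' Simulated dataset over a grid of lengths and resolutions
#'
#' Emulates a calibration corpus: contour lengths 340--1020 nm in 34 nm
#' steps by resolutions 5.1--7.8 nm/pixel in 0.1 steps (21 x 28 = 588
#' cases) at `l_p = 50` nm, each case drawn from its own substream derived
#' deterministically from the master seed.
#'
#' @param lc_grid Contour lengths in nm.
#' @param r_grid Pixel resolutions in nm/pixel.
#' @param n_per_case Samples per (l_c, r) case.
#' @param seed Master seed (integer).
#' @param ... Passed on to [simulate_skeletons()].
#' @return Tibble with columns `case`, `l_c`, `r`, plus the per-sample
#'   columns of [simulate_skeletons()].
#' @export
generate_dataset <- function(lc_grid = seq(340, 1020, by = 34),
                             r_grid = seq(5.1, 7.8, by = 0.1),
                             n_per_case = 100L, seed = 1L, ...) {
  stopifnot(length(lc_grid) >= 1, length(r_grid) >= 1)
  cases <- tidyr::expand_grid(l_c = lc_grid, r = r_grid)
  cases$case <- seq_len(nrow(cases))
  dplyr::bind_rows(lapply(cases$case, function(ci) {
    set.seed(case_seed(seed, ci))
    s <- simulate_skeletons(n_per_case, cases$l_c[ci], cases$r[ci], ...)
    dplyr::bind_cols(tibble(case = ci, l_c = cases$l_c[ci], r = cases$r[ci]), s)
  }))
}

# deterministic per-case substream seed, kept inside 32-bit integer range
case_seed <- function(seed, case) {
  as.integer((as.double(seed) * 48271 + case * 16807) %% 2147483647)
}
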