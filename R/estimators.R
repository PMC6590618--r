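# Contour-length estimators.
#
# All estimators act on tallies of a backbone chain code and scale linearly
# with the pixel resolution r (nm/pixel).  The shape estimator weights each
# interior connection by a per-class correction coefficient k_j:
#
#   L_S = r * ( sum_j n_kj * k_j * l_kj + l_H + l_T )
#
# with l_kj the centre connection length of class j (1 or sqrt(2)) and
# l_H, l_T the uncorrected head/tail connection lengths.  With all k_j = 1
# this reduces exactly to the Freeman estimator r*(n_e + sqrt(2)*n_o).

#' Freeman chain-code length estimate
#'
#' `L_F = r * (n_even + sqrt(2) * n_odd)`.
#'
#' @param n_even,n_odd Counts of even (direct) and odd (diagonal) codes.
#' @param r Pixel resolution in nm/pixel.
#' @return Numeric length in nm.
#' @export
freeman_length <- function(n_even, n_odd, r) {
  stopifnot(all(n_even >= 0), all(n_odd >= 0), all(r > 0))
  r * (n_even + sqrt(2) * n_odd)
}

#' Kulpa length estimate
#'
#' `L_K = r * (0.948 * n_even + 1.343 * n_odd)`, the classical correction of
#' the Freeman weights for digital slope inclination.
#'
#' @inheritParams freeman_length
#' @return Numeric length in nm.
#' @export
kulpa_length <- function(n_even, n_odd, r) {
  stopifnot(all(n_even >= 0), all(n_odd >= 0), all(r > 0))
  r * (0.948 * n_even + 1.343 * n_odd)
}

#' Corner-count length estimate
#'
#' `L_C = r * (0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner)`, where
#' `n_corner` counts positions with unequal consecutive codes (see
#' [code_tallies()]); the corner term compensates tight turns.
#'
#' @inheritParams freeman_length
#' @param n_corner Count of adjacent unequal code pairs.
#' @return Numeric length in nm.
#' @export
corner_length <- function(n_even, n_odd, n_corner, r) {
  stopifnot(all(n_corner >= 0), all(r > 0))
  r * (0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner)
}

#' DNA correction-factor length estimate
#'
#' `L_DNA = r * C_f * (n_even + sqrt(2) * n_odd)`, the Freeman estimate
#' rescaled by a correction factor `C_f = <l_c> / <L_F>` obtained from
#' samples of known length (see [estimate_cf()]).
#'
#' @inheritParams freeman_length
#' @param cf Positive correction factor.
#' @return Numeric length in nm.
#' @export
dna_length <- function(n_even, n_odd, r, cf) {
  stopifnot(all(cf > 0))
  cf * freeman_length(n_even, n_odd, r)
}

coef_vector <- function(k) {
  if (inherits(k, "sl_coefficients")) k <- stats::setNames(k$k, k$shape)
  if (length(k) != 12L) {
    abort("need one coefficient for each of k1..k12",
          class = "shapelength_configuration_error")
  }
  if (is.null(names(k))) names(k) <- shape_labels
  if (!all(shape_labels %in% names(k))) {
    abort("need one coefficient for each of k1..k12",
          class = "shapelength_configuration_error")
  }
  k[shape_labels]
}

#' Shape-weighted length estimate
#'
#' Applies the per-class correction coefficients to a shape tally:
#' `L_S = r * (sum_j n_kj * k_j * l_kj + l_H + l_T)` with head/tail
#' connection lengths 1 (even boundary code) or `sqrt(2)` (odd).
#'
#' @param tally Tibble with columns `k1`..`k12`, `head_code`, `tail_code`
#'   (from [shape_tally()] or [skeleton_features()]); may have many rows.
#' @param k Named numeric vector of the 12 coefficients, or an
#'   `sl_coefficients` fit from [solve_coefficients()].
#' @param r Pixel resolution in nm/pixel.
#' @return Numeric length(s) in nm, one per tally row.
#' @export
shape_length <- function(tally, k, r) {
  stopifnot(all(r > 0))
  k <- coef_vector(k)
  counts <- as.matrix(tally[shape_labels])
  lw <- segment_lengths()
  boundary <- if ("boundary_length" %in% names(tally)) {
    tally$boundary_length
  } else {
    ifelse(tally$head_code %% 2L == 0L, 1, sqrt(2)) +
      ifelse(tally$tail_code %% 2L == 0L, 1, sqrt(2))
  }
  r * (as.vector(counts %*% (k * lw)) + boundary)
}

# ---------------------------------------------------------------------------
# coefficient line model k_j(r) = m_j * r + b_j
# ---------------------------------------------------------------------------

new_coef_model <- function(tbl, r_range) {
  stopifnot(all(c("shape", "m", "b") %in% names(tbl)))
  tbl <- tbl[match(shape_labels, tbl$shape), ]
  if (anyNA(tbl$shape)) {
    abort("coefficient model must cover k1..k12",
          class = "shapelength_configuration_error")
  }
  structure(as_tibble(tbl), r_range = r_range,
            class = c("sl_coef_model", class(as_tibble(tbl))))
}

#' Evaluate the coefficient line model at a resolution
#'
#' Each coefficient varies linearly with pixel resolution,
#' `k_j(r) = m_j * r + b_j`.  A warning is raised when `r` lies outside the
#' calibrated range (by default 5.1--7.8 nm/pixel).
#'
#' @param r Pixel resolution in nm/pixel.
#' @param model An `sl_coef_model` (default: the bundled calibration, see
#'   [default_coefficient_model()]).
#' @return Named numeric vector of the 12 coefficients at `r`.
#' @export
coefficients_at <- function(r, model = default_coefficient_model()) {
  stopifnot(length(r) == 1L, r > 0)
  rng <- attr(model, "r_range")
  if (!is.null(rng) && (r < rng[1] || r > rng[2])) {
    warn(sprintf(
      "r = %g nm/pixel is outside the calibrated range [%g, %g]; extrapolating",
      r, rng[1], rng[2]
    ))
  }
  stats::setNames(model$m * r + model$b, model$shape)
}

#' Bundled default coefficient model
#'
#' The package ships a per-shape linear coefficient model calibrated on
#' large simulated worm-like-chain corpora over resolutions 5.1--7.8
#' nm/pixel; use [fit_coefficient_lines()] to re-calibrate and override.
#'
#' @return An `sl_coef_model` tibble with columns `shape`, `m`, `b`.
#' @export
default_coefficient_model <- function() {
  if (is.null(the$default_model)) {
    path <- system.file("extdata", "coefficients_default.json",
                        package = "shapelength", mustWork = TRUE)
    the$default_model <- read_coefficient_model(path)
  }
  the$default_model
}

#' Read / write a coefficient line model as JSON
#'
#' The on-disk form is `{"k1": {"m": ..., "b": ...}, ..., "r_range": [lo, hi]}`.
#'
#' @param path File path.
#' @return `read_coefficient_model()` returns an `sl_coef_model`.
#' @export
read_coefficient_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rng <- if (!is.null(obj$r_range)) as.numeric(obj$r_range) else NULL
  rows <- lapply(shape_labels, function(lab) {
    if (is.null(obj[[lab]])) {
      abort(paste0("coefficient model is missing ", lab),
            class = "shapelength_configuration_error")
    }
    tibble(shape = lab, m = as.numeric(obj[[lab]]$m), b = as.numeric(obj[[lab]]$b))
  })
  new_coef_model(dplyr::bind_rows(rows), rng)
}

#' @rdname read_coefficient_model
#' @param model An `sl_coef_model`.
#' @export
write_coefficient_model <- function(model, path) {
  obj <- lapply(seq_len(nrow(model)), function(i) {
    list(m = model$m[i], b = model$b[i])
  })
  names(obj) <- model$shape
  rng <- attr(model, "r_range")
  if (!is.null(rng)) obj$r_range <- rng
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Contour length of a backbone by a chosen estimator
#'
#' High-level wrapper: traces the chain code of a pixel path (or takes a
#' chain code directly), tallies it, and applies one estimator.
#'
#' @param x A pixel path (matrix or data frame with `x`, `y`) or a chain
#'   code (integer vector / digit string).
#' @param r Pixel resolution in nm/pixel.
#' @param estimator One of `"shape"`, `"freeman"`, `"kulpa"`, `"corner"`,
#'   `"dna"`.
#' @param k Coefficients for the shape estimator; defaults to the bundled
#'   model evaluated at `r`.
#' @param coef_model Coefficient line model used when `k` is `NULL`.
#' @param cf Correction factor for the DNA estimator (required for it).
#' @return One-row tibble: `estimator`, `r`, `n_codes`, `n_even`, `n_odd`,
#'   `length_nm`.
#' @export
contour_length <- function(x, r,
                           estimator = c("shape", "freeman", "kulpa", "corner", "dna"),
                           k = NULL, coef_model = NULL, cf = NULL) {
  estimator <- match.arg(estimator)
  codes <- if (is.matrix(x) || is.data.frame(x)) trace_chain_code(x) else as_chain_code(x)
  ct <- code_tallies(codes)
  value <- switch(estimator,
    freeman = freeman_length(ct$n_even, ct$n_odd, r),
    kulpa = kulpa_length(ct$n_even, ct$n_odd, r),
    corner = corner_length(ct$n_even, ct$n_odd, ct$n_corner, r),
    dna = {
      if (is.null(cf)) {
        abort("the DNA estimator needs a correction factor `cf`",
              class = "shapelength_configuration_error")
      }
      dna_length(ct$n_even, ct$n_odd, r, cf)
    },
    shape = {
      if (is.null(k)) k <- coefficients_at(r, coef_model %||% default_coefficient_model())
      shape_length(shape_tally(codes), k, r)
    }
  )
  tibble(
    estimator = estimator, r = r, n_codes = ct$n_codes,
    n_even = ct$n_even, n_odd = ct$n_odd, length_nm = value
  )
}
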