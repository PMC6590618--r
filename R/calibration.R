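# Least-squares calibration of the twelve shape coefficients.
#
# Stacking the length equation of m samples of known contour length gives
# the linear system  r * N * D * K + B = L,  where N is the m-by-12
# occurrence matrix, D = diag(1, sqrt(2), 1, sqrt(2), sqrt(2), 1, sqrt(2),
# sqrt(2), sqrt(2), 1, sqrt(2), sqrt(2)) holds the centre connection
# lengths, B the head+tail boundary lengths (in nm) and L the true lengths.
# K is fitted by QR least squares; shapes never observed in the corpus are
# excluded from the solve and fixed at the Freeman weight k_j = 1.

#' Assemble the calibration system from sample features
#'
#' @param features Tibble from [skeleton_features()], one row per sample,
#'   all imaged at the same resolution.
#' @param true_length True contour length(s) in nm (scalar or one per row).
#' @param r Pixel resolution in nm/pixel.
#' @return An `sl_calib_system`: list with the occurrence matrix `N`,
#'   boundary vector `B` (nm), target vector `L` (nm), diagonal `D`, `r`,
#'   and a logical `observed` flag per shape.
#' @export
assemble_system <- function(features, true_length, r) {
  stopifnot(length(r) == 1L, r > 0)
  N <- as.matrix(features[shape_labels])
  storage.mode(N) <- "double"
  m <- nrow(N)
  if (m < 12L) {
    warn(sprintf("only %d samples for 12 coefficients; the system may be ill-posed", m))
  }
  L <- rep_len(as.numeric(true_length), m)
  stopifnot(all(L > 0))
  B <- r * features$boundary_length
  observed <- colSums(N) > 0
  if (any(!observed)) {
    warn(paste0(
      "shapes never observed (coefficient fixed at 1): ",
      paste(shape_labels[!observed], collapse = ", ")
    ))
  }
  structure(
    list(N = N, B = B, L = L, r = r, D = segment_lengths(), observed = observed),
    class = "sl_calib_system"
  )
}

#' Solve the calibration system for the shape coefficients
#'
#' Minimises `|| r * N * D * K + B - L ||^2` by QR (orthogonal
#' decomposition, no normal equations) over the observed shapes; never
#' observed shapes keep `k_j = 1`.
#'
#' @param sys An `sl_calib_system` from [assemble_system()].
#' @return An `sl_coefficients` tibble: `shape`, `k`, `se`,
#'   `n_occurrences`, `observed`; residual scale and sample size are
#'   available through [glance()].
#' @export
solve_coefficients <- function(sys) {
  stopifnot(inherits(sys, "sl_calib_system"))
  obs <- sys$observed
  X <- sweep(sys$N[, obs, drop = FALSE], 2, sys$D[obs], `*`) * sys$r
  y <- sys$L - sys$B
  fit <- stats::lm.fit(X, y)
  p <- sum(obs)
  if (fit$rank < p) {
    piv <- fit$qr$pivot
    deficient <- colnames(X)[piv[(fit$rank + 1):p]]
    abort(
      paste0("singular calibration system; deficient columns: ",
             paste(deficient, collapse = ", ")),
      class = "shapelength_singular_system"
    )
  }
  dfres <- length(y) - p
  sigma2 <- if (dfres > 0) sum(fit$residuals^2) / dfres else NA_real_
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  cov_unscaled <- chol2inv(R)
  se_obs <- rep(NA_real_, p)
  se_obs[fit$qr$pivot] <- sqrt(diag(cov_unscaled) * sigma2)

  k <- rep(1, 12L)
  se <- rep(NA_real_, 12L)
  k[obs] <- unname(fit$coefficients)
  se[obs] <- se_obs
  out <- tibble(
    shape = shape_labels,
    k = k,
    se = se,
    n_occurrences = colSums(sys$N),
    observed = obs
  )
  structure(out,
            sigma = sqrt(sigma2), n_samples = length(y), df_residual = dfres,
            r = sys$r, class = c("sl_coefficients", class(out)))
}

#' @export
tidy.sl_coefficients <- function(x, ...) {
  tibble(
    term = x$shape, estimate = x$k, std.error = x$se,
    n_occurrences = x$n_occurrences, observed = x$observed
  )
}

#' @export
glance.sl_coefficients <- function(x, ...) {
  tibble(
    sigma = attr(x, "sigma"),
    n_samples = attr(x, "n_samples"),
    df.residual = attr(x, "df_residual"),
    r = attr(x, "r"),
    n_observed_shapes = sum(x$observed)
  )
}

#' Fit per-shape coefficient lines over resolution
#'
#' Ordinary least-squares line `k_j(r) = m_j * r + b_j` for each shape from
#' coefficient sets calibrated at two or more resolutions.
#'
#' @param points Tibble with columns `r`, `shape`, `k` (e.g. stacked
#'   [solve_coefficients()] results), or a list of `sl_coefficients` whose
#'   calibration resolutions are taken from the fits themselves.
#' @return An `sl_coef_model` tibble (`shape`, `m`, `b`, `r_squared`,
#'   `n_points`), usable with [coefficients_at()].
#' @export
fit_coefficient_lines <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- dplyr::bind_rows(lapply(points, function(f) {
      tibble(r = attr(f, "r"), shape = f$shape, k = f$k)
    }))
  }
  stopifnot(all(c("r", "shape", "k") %in% names(points)))
  if (length(unique(points$r)) < 2L) {
    abort("need coefficients at two or more distinct resolutions",
          class = "shapelength_configuration_error")
  }
  fits <- points |>
    dplyr::group_by(.data$shape) |>
    dplyr::group_modify(function(d, key) {
      f <- stats::lm(k ~ r, data = d)
      ssr <- sum(stats::residuals(f)^2)
      sst <- sum((d$k - mean(d$k))^2)
      tibble(
        m = unname(coef(f)[2]), b = unname(coef(f)[1]),
        r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
        n_points = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  new_coef_model(fits, range(points$r))
}

#' @export
tidy.sl_coef_model <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.sl_coef_model <- function(x, ...) {
  rng <- attr(x, "r_range") %||% c(NA_real_, NA_real_)
  tibble(r_min = rng[1], r_max = rng[2], n_shapes = nrow(x))
}

#' Coefficient convergence over a growing sample stream
#'
#' Re-solves the calibration system on growing prefixes of a seeded sample
#' stream and reports the coefficient drift between successive checkpoints.
#' The headline drift is taken over the coefficients that are actually
#' estimable at the earlier checkpoint -- relative standard error below
#' `se_limit` -- because the checkpoint-to-checkpoint fluctuation of a
#' poorly supported coefficient measures its own sampling error, not
#' convergence of the calibration.  All per-shape values are reported.
#'
#' @param features Feature tibble (stream order = row order).
#' @param true_length True contour length(s) in nm.
#' @param r Pixel resolution in nm/pixel.
#' @param checkpoints Increasing sample counts at which to solve.
#' @param se_limit Maximum relative standard error (at the earlier
#'   checkpoint) for a coefficient to enter the headline drift figure
#'   (default 0.005).
#' @return Tibble with one row per (checkpoint, shape): `m`, `shape`, `k`,
#'   `se`, `n_occurrences`, `observed`.  Attribute `"changes"` (see
#'   [convergence_changes()]) holds per-interval drift summaries.
#' @export
convergence_curve <- function(features, true_length, r, checkpoints,
                              se_limit = 0.005) {
  checkpoints <- sort(unique(as.integer(checkpoints)))
  stopifnot(all(checkpoints >= 1), max(checkpoints) <= nrow(features))
  true_length <- rep_len(as.numeric(true_length), nrow(features))
  sols <- lapply(checkpoints, function(m) {
    f <- withCallingHandlers(
      solve_coefficients(assemble_system(features[seq_len(m), ], true_length[seq_len(m)], r)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble(m = m, shape = f$shape, k = f$k, se = f$se,
           n_occurrences = f$n_occurrences, observed = f$observed)
  })
  curve <- dplyr::bind_rows(sols)
  changes <- NULL
  if (length(checkpoints) >= 2) {
    changes <- dplyr::bind_rows(lapply(seq_len(length(checkpoints) - 1), function(i) {
      a <- sols[[i]]
      b <- sols[[i + 1]]
      rel <- abs(b$k - a$k) / abs(a$k)
      estimable <- a$observed & b$observed &
        is.finite(a$se) & a$se / abs(a$k) < se_limit
      tibble(
        from = checkpoints[i], to = checkpoints[i + 1],
        max_rel_change = if (any(estimable)) max(rel[estimable]) else NA_real_,
        max_rel_change_all = max(rel[a$observed & b$observed]),
        n_supported = sum(estimable)
      )
    }))
  }
  structure(curve, changes = changes,
            class = c("sl_convergence", class(curve)))
}

#' @rdname convergence_curve
#' @param curve Result of [convergence_curve()].
#' @export
convergence_changes <- function(curve) {
  attr(curve, "changes")
}

#' Correction factor for the DNA estimator
#'
#' `C_f = mean(l_c) / mean(L_F)` over samples sharing one true length and
#' one resolution.
#'
#' @param features Feature tibble of the samples.
#' @param true_length Shared true contour length in nm.
#' @param r Pixel resolution in nm/pixel.
#' @return A single positive number.
#' @export
estimate_cf <- function(features, true_length, r) {
  lf <- freeman_length(features$n_even, features$n_odd, r)
  mean(rep_len(as.numeric(true_length), nrow(features))) / mean(lf)
}

#' Error analysis of configured estimators on held-out samples
#'
#' For each requested estimator, computes the relative error of the mean
#' estimate (`|mean - l_c| / l_c * 100` in percent), the absolute error of
#' the mean (nm) and the per-sample standard deviation (nm).
#'
#' @param features Held-out feature tibble (one `(l_c, r)` cell).
#' @param true_length True contour length in nm.
#' @param r Pixel resolution in nm/pixel.
#' @param estimators Subset of `"shape"`, `"dna"`, `"freeman"`, `"kulpa"`,
#'   `"corner"`.
#' @param k Coefficients for the shape estimator (required if requested).
#' @param cf Correction factor for the DNA estimator (required if
#'   requested); calibrate it on separate training samples.
#' @return Tibble: `estimator`, `l_c`, `r`, `n`, `relative_pct`,
#'   `absolute_nm`, `std_nm`.
#' @export
evaluate_estimators <- function(features, true_length, r,
                                estimators = c("shape", "dna", "freeman"),
                                k = NULL, cf = NULL) {
  estimators <- match.arg(estimators,
                          c("shape", "dna", "freeman", "kulpa", "corner"),
                          several.ok = TRUE)
  lc <- as.numeric(true_length)
  stopifnot(length(lc) == 1L)
  values <- lapply(estimators, function(est) {
    switch(est,
      freeman = freeman_length(features$n_even, features$n_odd, r),
      kulpa = kulpa_length(features$n_even, features$n_odd, r),
      corner = corner_length(features$n_even, features$n_odd, features$n_corner, r),
      dna = {
        if (is.null(cf)) {
          abort("the DNA estimator needs `cf` calibrated on training samples",
                class = "shapelength_configuration_error")
        }
        dna_length(features$n_even, features$n_odd, r, cf)
      },
      shape = {
        if (is.null(k)) {
          abort("the shape estimator needs coefficients `k`",
                class = "shapelength_configuration_error")
        }
        shape_length(features, k, r)
      }
    )
  })
  out <- dplyr::bind_rows(lapply(seq_along(estimators), function(i) {
    v <- values[[i]]
    tibble(
      estimator = estimators[i], l_c = lc, r = r, n = length(v),
      relative_pct = abs(mean(v) - lc) / lc * 100,
      absolute_nm = abs(mean(v) - lc),
      std_nm = sd(v)
    )
  }))
  structure(out, class = c("sl_error_report", class(out)))
}
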