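make_features <- function(n, l_c, r, seed) {
  set.seed(seed)
  skeleton_features(simulate_skeletons(n, l_c, r))
}

test_that("a consistent noiseless linear system recovers its coefficients", {
  feats <- make_features(120, 340, 6.4, seed = 201)
  k_star <- seq(0.7, 1.2, length.out = 12)
  # construct target lengths exactly from the length equation
  L <- shape_length(feats, stats::setNames(k_star, paste0("k", 1:12)), 6.4)
  sys <- assemble_system(feats, L, 6.4)
  fit <- solve_coefficients(sys)
  expect_true(all(fit$observed))
  expect_lt(max(abs(fit$k - k_star) / k_star), 1e-9)

  # row structure: counts sum to n_codes - 2 and B holds boundary lengths
  expect_identical(unname(rowSums(sys$N)), as.numeric(feats$n_codes - 2L))
  expect_equal(sys$B, 6.4 * feats$boundary_length)
})

test_that("noisy systems recover coefficients within standard errors", {
  feats <- make_features(800, 340, 6.4, seed = 202)
  k_star <- stats::setNames(rep(1, 12), paste0("k", 1:12))
  set.seed(7)
  L <- shape_length(feats, k_star, 6.4) + rnorm(nrow(feats), sd = 2)
  fit <- solve_coefficients(assemble_system(feats, L, 6.4))
  obs <- fit$observed & fit$n_occurrences > 50
  z <- abs(fit$k[obs] - 1) / fit$se[obs]
  expect_lt(max(z), 4)

  # with unit true coefficients, shape and Freeman estimates agree in
  # expectation; the fitted coefficients leave only a sub-nm mean offset
  ls <- shape_length(feats, fit, 6.4)
  lf <- freeman_length(feats$n_even, feats$n_odd, 6.4)
  expect_lt(abs(mean(ls - lf)), 1)
})

test_that("never-observed shapes are excluded and fixed at one", {
  # straight chains only: every shape except k1 is unobserved
  feats <- skeleton_features(lapply(1:20, function(i) follow_chain_code(rep(0L, i + 5))))
  expect_warning(sys <- assemble_system(feats, freeman_length(feats$n_even, 0, 2), 2),
                 "never observed")
  fit <- solve_coefficients(sys)
  expect_identical(sum(fit$observed), 1L)
  expect_equal(fit$k[fit$shape == "k1"], 1, tolerance = 1e-9)
  expect_true(all(fit$k[fit$shape != "k1"] == 1))
})

test_that("coefficient lines are recovered from exact and fitted points", {
  # two resolutions determine a line exactly
  pts <- dplyr::bind_rows(
    tibble::tibble(r = 5.1, shape = paste0("k", 1:12), k = -0.00027806 * 5.1 + 0.7044),
    tibble::tibble(r = 7.8, shape = paste0("k", 1:12), k = -0.00027806 * 7.8 + 0.7044)
  )
  model <- fit_coefficient_lines(pts)
  expect_equal(model$m, rep(-0.00027806, 12), tolerance = 1e-9)
  expect_equal(model$b, rep(0.7044, 12), tolerance = 1e-9)

  # constant coefficients give zero slope
  flat <- fit_coefficient_lines(
    tidyr::expand_grid(r = c(5.1, 6.4, 7.7), shape = paste0("k", 1:12)) |>
      dplyr::mutate(k = 0.9)
  )
  expect_equal(flat$m, rep(0, 12), tolerance = 1e-12)

  expect_error(
    fit_coefficient_lines(tibble::tibble(r = 5.1, shape = "k1", k = 1)),
    class = "shapelength_configuration_error"
  )
})

test_that("correction factor is the ratio of true to Freeman mean length", {
  feats <- make_features(300, 340, 5.1, seed = 203)
  lf <- freeman_length(feats$n_even, feats$n_odd, 5.1)
  cf <- estimate_cf(feats, 340, 5.1)
  expect_equal(cf, 340 / mean(lf), tolerance = 1e-12)
  # a Freeman mean 3% above truth implies cf = 1/1.03 ~ 0.9709
  expect_equal(estimate_cf(feats, mean(lf) / 1.03, 5.1), 1 / 1.03,
               tolerance = 1e-12)
})

test_that("error reports summarise estimator accuracy per cell", {
  feats <- make_features(400, 340, 5.1, seed = 204)
  fit <- suppressWarnings(solve_coefficients(assemble_system(feats, 340, 5.1)))
  held <- make_features(400, 340, 5.1, seed = 205)
  cf <- estimate_cf(feats, 340, 5.1)
  rep <- evaluate_estimators(held, 340, 5.1,
                             estimators = c("shape", "dna", "freeman"),
                             k = fit, cf = cf)
  expect_identical(nrow(rep), 3L)
  expect_true(all(rep$std_nm > 0))
  # a perfect oracle estimator scores zero error
  perfect <- evaluate_estimators(
    dplyr::mutate(held, n_even = 340 / 5.1, n_odd = 0),
    340, 5.1, estimators = "freeman"
  )
  expect_equal(perfect$relative_pct, 0, tolerance = 1e-12)
  expect_equal(perfect$absolute_nm, 0, tolerance = 1e-10)
  # calibrated shape estimator beats the raw Freeman estimate
  expect_lt(rep$relative_pct[rep$estimator == "shape"],
            rep$relative_pct[rep$estimator == "freeman"])
})

test_that("calibration results are invariant to sample order", {
  feats <- make_features(200, 340, 6.4, seed = 206)
  set.seed(9)
  perm <- sample(nrow(feats))
  f1 <- suppressWarnings(solve_coefficients(assemble_system(feats, 340, 6.4)))
  f2 <- suppressWarnings(solve_coefficients(assemble_system(feats[perm, ], 340, 6.4)))
  expect_equal(f1$k, f2$k, tolerance = 1e-9)
  expect_equal(estimate_cf(feats, 340, 6.4), estimate_cf(feats[perm, ], 340, 6.4),
               tolerance = 1e-12)
})

test_that("convergence reporting tracks coefficient drift on prefixes", {
  feats <- make_features(600, 340, 6.4, seed = 207)
  curve <- convergence_curve(feats, 340, 6.4, checkpoints = c(150, 300, 600),
                             se_limit = 0.05)
  expect_identical(nrow(curve), 36L)
  ch <- convergence_changes(curve)
  expect_identical(nrow(ch), 2L)
  expect_true(all(ch$max_rel_change >= 0, na.rm = TRUE))

  # duplicated stream: identical coefficients at both checkpoints
  dup <- dplyr::bind_rows(feats[1:100, ], feats[1:100, ])
  curve2 <- convergence_curve(dup, 340, 6.4, checkpoints = c(100, 200),
                              se_limit = Inf)
  k1 <- curve2$k[curve2$m == 100]
  k2 <- curve2$k[curve2$m == 200]
  expect_equal(k1, k2, tolerance = 1e-9)
})

test_that("tidy and glance expose fits in rectangular form", {
  feats <- make_features(200, 340, 6.4, seed = 208)
  fit <- suppressWarnings(solve_coefficients(assemble_system(feats, 340, 6.4)))
  td <- tidy(fit)
  expect_identical(td$term, paste0("k", 1:12))
  gl <- glance(fit)
  expect_identical(gl$n_samples, 200L)
  expect_gt(gl$sigma, 0)

  model <- default_coefficient_model()
  expect_identical(nrow(tidy(model)), 12L)
  expect_equal(glance(model)$r_min, 5.1)
})
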