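test_that("blank subtraction removes the per-timepoint mean blank", {
  t <- seq(0, 20, by = 1)
  y <- matrix(100 + seq_along(t), ncol = 1)
  cv <- tht_curve(t, y, blanks = 100)
  expect_equal(as.vector(blank_subtract(cv)$signal), seq_along(t))

  # blanks equal to signal -> all-zero curve
  cv2 <- tht_curve(t, y, blanks = cbind(y, y))
  expect_true(all(blank_subtract(cv2)$signal == 0))

  # well-specific component survives subtraction of the common drift
  drift <- 50 + 3 * t
  well <- 10 * sin(t / 3)
  cv3 <- tht_curve(t, matrix(drift + well), blanks = cbind(drift, drift))
  expect_equal(as.vector(blank_subtract(cv3)$signal), well)

  expect_error(blank_subtract(tht_curve(t, y)), "no blanks")
  expect_error(tht_curve(t, y, blanks = matrix(0, 3, 2)), "blank rows")
  expect_error(tht_curve(c(1, 1, 2), matrix(0, 3, 1)), "strictly increasing")
})

test_that("noiseless sigmoids are recovered to high precision", {
  t <- seq(0, 144, by = 0.5)
  y <- 50 + 1000 / (1 + exp(-0.3 * (t - 35)))
  fit <- fit_tht_sigmoid(tht_curve(t, matrix(y)))
  expect_true(fit$converged)
  expect_equal(fit$T_half, 35, tolerance = 1e-6)
  expect_equal(fit$baseline, 50, tolerance = 1e-4)
  expect_equal(fit$plateau, 1050, tolerance = 1e-4)
  expect_equal(fit$slope, 0.3, tolerance = 1e-6)
  expect_true(fit$in_range)
})

test_that("flat signals give the no-aggregation call with zero speed", {
  t <- seq(0, 144, by = 0.5)
  fit <- fit_tht_sigmoid(tht_curve(t, matrix(rep(80, length(t)))))
  expect_false(fit$converged)
  expect_true(is.na(fit$T_half))
  expect_equal(aggregation_speed(fit), 0)

  set.seed(8)
  fit2 <- fit_tht_sigmoid(tht_curve(t, matrix(80 + rnorm(length(t), 0, 20))))
  expect_false(fit2$converged)
  expect_error(fit_tht_sigmoid(tht_curve(1:5, matrix(1:5))), "8 time points")
})

test_that("T_half recovery within 5% median error at 2% noise (100 seeds)", {
  t <- seq(0, 144, by = 0.5)
  truth <- 60
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 40 + 900 / (1 + exp(-0.25 * (t - truth))) +
      rnorm(length(t), 0, 0.02 * 900)
    f <- fit_tht_sigmoid(tht_curve(t, matrix(y)))
    abs(f$T_half - truth) / truth
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("simulated plates round-trip through the kinetics pipeline", {
  mt <- data.frame(id = c("fast", "slow", "none"),
                   T_half = c(25, 90, NA),
                   baseline = c(40, 60, 40),
                   plateau = c(940, 1060, 940),
                   slope = c(0.4, 0.2, 0.4))
  # zero noise: parameters recovered essentially exactly
  pl0 <- simulate_tht_plate(list(mutants = mt, noise_sigma_frac = 0,
                                 seed = 2))
  f_fast <- fit_tht_sigmoid(blank_subtract(plate_curves(pl0$plate, "fast")))
  expect_equal(f_fast$T_half, 25, tolerance = 1e-6)
  expect_equal(f_fast$slope, 0.4, tolerance = 1e-6)
  f_none <- fit_tht_sigmoid(blank_subtract(plate_curves(pl0$plate, "none")))
  expect_false(f_none$converged)

  # plates are seeded-reproducible
  pl_a <- simulate_tht_plate(list(mutants = mt, seed = 77))
  pl_b <- simulate_tht_plate(list(mutants = mt, seed = 77))
  expect_identical(pl_a$plate, pl_b$plate)

  # 2% noise: all wells fit, speeds ordered correctly
  pl <- simulate_tht_plate(list(mutants = mt, noise_sigma_frac = 0.02,
                                seed = 3))
  f1 <- fit_tht_sigmoid(blank_subtract(plate_curves(pl$plate, "fast")))
  f2 <- fit_tht_sigmoid(blank_subtract(plate_curves(pl$plate, "slow")))
  f3 <- fit_tht_sigmoid(blank_subtract(plate_curves(pl$plate, "none")))
  expect_equal(f1$T_half, 25, tolerance = 0.05)
  expect_equal(f2$T_half, 90, tolerance = 0.05)
  expect_gt(aggregation_speed(f1), aggregation_speed(f2))
  expect_equal(aggregation_speed(f3), 0)
  expect_equal(aggregation_speed(f1), 1 / f1$T_half)
})

test_that("correlation: limits, oracle equivalence, tie handling", {
  expect_equal(correlate(1:6, 2 * (1:6) + 3)$r, 1)
  expect_equal(correlate(1:6, rev(1:6))$r, -1)
  expect_error(correlate(1:2, 2:3), "at least 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero-variance")
  expect_error(correlate(c(a = 1, b = 2, c = 3), c(a = 1, d = 2, e = 3)),
               "names do not match")

  # Spearman equals the textbook tie-corrected formula on random tables
  set.seed(31)
  for (rep_i in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:5, n, replace = TRUE) + runif(n, 0, 0.01)
    y <- sample(1:4, n, replace = TRUE) + runif(n, 0, 0.01)
    # introduce exact ties half the time
    if (rep_i %% 2 == 0) { x <- round(x); y <- round(y) }
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(correlate(x, y)$r, spearman_textbook(x, y),
                 tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms (Spearman)
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  r0 <- correlate(x, y)$r
  expect_equal(correlate(exp(x), y)$r, r0)
  expect_equal(correlate(x, y^3 + 5 * y)$r, r0)

  # named alignment reorders correctly
  xv <- c(a = 1, b = 2, c = 3, d = 4)
  yv <- c(d = 8, c = 6, b = 4, a = 2)
  expect_equal(correlate(xv, yv)$r, 1)
})

test_that("hairpin-monotone libraries reproduce the kinetics sign pattern", {
  # generator: hairpin content increases with aggregation speed across a
  # synthetic library; expect hairpin-speed r > 0 and coil-speed r < 0
  rm_ <- tau_regions()
  hair_frac <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  T_half <- c(120, 80, 55, 35, 22)      # faster aggregation with more hairpin
  summaries <- NULL
  for (i in seq_along(hair_frac)) {
    rec <- list(sequence = tau295_sequence(),
                composition = c(even = hair_frac[i] * 2 / 3,
                                odd = hair_frac[i] / 3,
                                extended = 0,
                                coil = 1 - hair_frac[i]),
                n_frames = 40, noise_sigma = 0.05, seed = 300 + i)
    s <- summarize_ensemble(sample_ensemble(rec)$ensemble, rm_,
                            mutant_id = paste0("m", i))
    summaries <- rbind(summaries, s)
  }
  mt <- data.frame(id = summaries$mutant_id, T_half = T_half,
                   baseline = 50, plateau = 1050, slope = 0.3)
  pl <- simulate_tht_plate(list(mutants = mt, noise_sigma_frac = 0.02,
                                seed = 9))
  speeds <- vapply(mt$id, function(id)
    aggregation_speed(fit_tht_sigmoid(blank_subtract(
      plate_curves(pl$plate, id)))), numeric(1))
  hairpin <- summaries$f_even + summaries$f_odd
  expect_gt(correlate(hairpin, speeds)$r, 0)
  expect_lt(correlate(summaries$f_coil, speeds)$r, 0)
  expect_gt(correlate(summaries$S_xHAT, speeds)$r, 0)
})
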