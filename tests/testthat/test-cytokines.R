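test_that("forward and inverse 5PL are exact inverses mid-curve", {
  set.seed(11)
  for (i in 1:300) {
    A <- runif(1, 10, 100)
    D <- A + runif(1, 1000, 30000)
    C <- exp(runif(1, log(1), log(1000)))
    B <- runif(1, 0.7, 2.2)
    g <- exp(runif(1, log(0.5), log(2)))
    # concentrations spanning the quantifiable range:
    # (x/C)^(B*g) in [1e-3, 1e3]
    x <- C * (10^runif(4, -3, 3))^(1 / (B * g))
    y <- fivepl(x, A, D, C, B, g)
    inv <- fivepl_inverse(y, A, D, C, B, g)
    expect_true(all(inv$censored == "ok"))
    expect_lt(max(abs(inv$concentration - x) / x), 1e-9)
    # monotonicity: inverse preserves response ordering
    expect_identical(order(inv$concentration), order(x))
  }
})

test_that("out-of-range responses are censored, not extrapolated", {
  fitlike <- list(A = 50, D = 20000, C = 100, B = 1.2, g = 0.9)
  inv <- fivepl_inverse(c(49, 10, 20001, 30000), fitlike$A, fitlike$D,
                        fitlike$C, fitlike$B, fitlike$g)
  expect_equal(inv$censored, c("low", "low", "high", "high"))
  expect_true(all(is.na(inv$concentration)))
  # symmetric midpoint with g = 1: response halfway between A and D
  # inverts to exactly C
  ymid <- fivepl(100, 50, 20000, 100, 1.2, 1)
  expect_equal(ymid, (50 + 20000) / 2)
  inv2 <- fivepl_inverse(ymid, 50, 20000, 100, 1.2, 1)
  expect_equal(inv2$concentration, 100, tolerance = 1e-12)
})

test_that("zero-noise duplicate standards recover the generating curve", {
  p <- list(A = 55, D = 26000, C = 120, B = 1.15, g = 1.0)
  conc <- rep(10000 / 10^(0:5), each = 2)
  resp <- fivepl(conc, p$A, p$D, p$C, p$B, p$g)
  fit <- fit_5pl(conc, resp)
  for (nm in names(p)) {
    expect_lt(abs(fit[[nm]] - p[[nm]]) / abs(p[[nm]]), 1e-4)
  }
  expect_true(fit$converged)
})

test_that("fixing g = 1 reproduces a 4PL fit", {
  p <- list(A = 40, D = 22000, C = 60, B = 1.05)
  conc <- rep(10000 / 10^(0:5), each = 2)
  resp <- fivepl(conc, p$A, p$D, p$C, p$B, 1)
  fit <- fit_5pl(conc, resp, fix_g = 1)
  expect_equal(fit$g, 1)
  for (nm in names(p)) {
    expect_lt(abs(fit[[nm]] - p[[nm]]) / abs(p[[nm]]), 1e-4)
  }
})

test_that("degenerate or insufficient standards raise calibration errors", {
  conc <- rep(10000 / 10^(0:5), each = 2)
  expect_error(fit_5pl(conc, rep(100, 12), analyte = "IL6"), "IL6")
  expect_error(fit_5pl(c(1, 10, 100), c(5, 50, 500)), "6 distinct")
})

test_that("dilution and background correction follow the chain", {
  expect_equal(correct_sample(5, 2, 0), 10)
  expect_equal(correct_sample(5, 2, 10), 0)   # floored at zero
  expect_equal(correct_sample(0, 2, 0), 0)
  expect_equal(correct_sample(c(5, 1), 2, 3), c(7, 0))
})

test_that("n-fold against pooled control wells", {
  expect_equal(fold_change(10, c(4, 6)), 2)
  expect_equal(fold_change(5, c(4, 6)), 1)    # the "no difference" point
  nf <- fold_change(3, c(0, 0))
  expect_true(is.na(nf))
  expect_equal(attr(nf, "reason"), "zero_control_mean")
  expect_error(fold_change(3, numeric(0)), "control")
})

test_that("zero-noise plates invert to true concentrations end to end", {
  des <- plate_design(n_animals = 3, noise_cv = 0, bio_cv = 0)
  pd <- generate_cytokine_experiment(des, seed = 5)
  cal <- calibrate_plate(pd$standards, pd$samples)
  r <- cal$records[cal$records$role != "background", ]
  key <- paste(r$analyte, r$animal, r$treatment)
  tkey <- paste(pd$truth$analyte, pd$truth$animal, pd$truth$treatment)
  truth <- pd$truth$true_secreted[match(key, tkey)]
  expect_lt(max(abs(r$corrected - truth) / pmax(truth, 1e-9)), 1e-6)
  # n-fold recovers the programmed multipliers exactly at zero noise
  tt <- r$role == "treatment"
  mult <- pd$truth$multiplier[match(key, tkey)]
  expect_lt(max(abs(r$n_fold[tt] - mult[tt])), 1e-6)
})

test_that("replicate interpolation CV stays within twice the response CV", {
  des <- plate_design(n_animals = 2, noise_cv = 0.08, bio_cv = 0)
  cp <- des$curve_params
  pp <- cp[cp$analyte == "IL6", ]
  set.seed(21)
  sdlog <- sqrt(log(1 + 0.08^2))
  y <- fivepl(30, pp$A, pp$D, pp$C, pp$B, pp$g) *
    rlnorm(300, -sdlog^2 / 2, sdlog)
  fit <- list(A = pp$A, D = pp$D, C = pp$C, B = pp$B, g = pp$g)
  class(fit) <- "fivepl_fit"
  conc <- concentration_from_response(fit, y)$concentration
  cv <- stats::sd(conc) / mean(conc)
  expect_lt(cv, 0.08 * 2)
})
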