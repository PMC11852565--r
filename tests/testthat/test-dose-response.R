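doses_fix <- default_dose_grid()

make_curve <- function(bottom, top, ec50, hill, doses = doses_fix,
                       blank = 0.05, noise_sd = 0, seed = NULL) {
  sig <- fourpl(doses, bottom, top, ec50, hill)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- pmax(sig + rnorm(length(doses), 0, noise_sd), 0)
  }
  dose_response_curve("clone", "Cas9", doses, sig + blank, blank = blank)
}

test_that("unit conversion to nanomolar uses the molecular mass", {
  expect_equal(conc_to_nm(80, "ug_per_ml", 14), 80 * 1000 / 14)
  expect_equal(conc_to_nm(1, "uM"), 1000)
  expect_equal(conc_to_nm(1e-9, "M"), 1)
  expect_equal(conc_to_nm(300, "ng_per_ul", 15), 20000)
  expect_error(conc_to_nm(1, "furlongs"), "unknown")
  # the plate design: 12 points, 3-fold, ~80 ug/mL down to ~4.5e-4 ug/mL
  expect_equal(length(doses_fix), 12)
  expect_equal(max(doses_fix) / min(doses_fix), 3^11)
})

test_that("noiseless 4PL parameters are recovered to high precision", {
  f <- fit_4pl(make_curve(0.05, 1.8, 5, 1.2))
  expect_true(f$converged)
  expect_lt(abs(f$ec50 - 5) / 5, 1e-6)
  expect_lt(abs(f$hill - 1.2), 1e-5)
  expect_lt(abs(f$bottom - 0.05), 1e-6)
  expect_lt(abs(f$top - 1.8), 1e-6)
})

test_that("flat curves are flagged no-response, short designs error", {
  flat <- dose_response_curve("c", "a", doses_fix, rep(0.05, 12), blank = 0.05)
  f <- fit_4pl(flat)
  expect_true(f$no_response)
  expect_false(f$converged)
  expect_error(
    fit_4pl(dose_response_curve("c", "a", c(1, 3, 9), c(0.1, 0.5, 1))),
    ">= 4")
})

test_that("fitting is scale-equivariant in concentration", {
  f1 <- fit_4pl(make_curve(0, 1.5, 8, 1))
  cu2 <- dose_response_curve("c", "a", doses_fix * 37,
                             fourpl(doses_fix, 0, 1.5, 8, 1) + 0.05, blank = 0.05)
  f2 <- fit_4pl(cu2)
  expect_equal(f2$ec50 / f1$ec50, 37, tolerance = 1e-5)
})

test_that("EC50 ordering of noiseless curves is preserved", {
  grid <- c(2, 4.5, 6.6, 7.1, 9.1)
  fitted <- vapply(grid, function(e) fit_4pl(make_curve(0, 1.8, e, 1))$ec50,
                   numeric(1))
  expect_equal(order(fitted), order(grid))
  expect_equal(fitted, grid, tolerance = 1e-6)
})

test_that("EC50 recovery under noise stays within 15% for a tight binder", {
  errs <- vapply(1:100, function(s) {
    f <- fit_4pl(make_curve(0, 1.8, 2, 1, noise_sd = 0.02, seed = s))
    abs(f$ec50 - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  expect_gt(mean(errs <= 0.15), 0.9)
})

test_that("log-dose AUC matches analytic and dense-quadrature oracles", {
  # flat blank-level curve integrates to zero
  expect_equal(auc_logdose(make_curve(0, 0, 1, 1)), 0)
  # constant blank-subtracted signal h over two decades -> 2h
  cu <- dose_response_curve("c", "a", c(1, 10, 100), rep(0.75, 3), blank = 0.05)
  expect_equal(auc_logdose(cu), 2 * 0.7)
  # 12-point trapezoid vs 10,000-point quadrature of the generating 4PL
  pars <- list(bottom = 0, top = 1.6, ec50 = 12, hill = 1.3)
  cu12 <- make_curve(pars$bottom, pars$top, pars$ec50, pars$hill)
  lx <- seq(log10(min(doses_fix)), log10(max(doses_fix)), length.out = 10000)
  y <- fourpl(10^lx, pars$bottom, pars$top, pars$ec50, pars$hill)
  dense <- sum(diff(lx) * (head(y, -1) + y[-1]) / 2)
  expect_lt(abs(auc_logdose(cu12) - dense) / dense, 0.02)
  expect_error(auc_logdose(dose_response_curve("c", "a", 5, 0.3)), ">= 2")
})

test_that("AUC is additive over contiguous dose sub-ranges", {
  cu <- make_curve(0, 1.8, 5, 1)
  lo <- dose_response_curve("c", "a", cu$concentration[cu$concentration <= doses_fix[6]],
                            cu$a450[cu$concentration <= doses_fix[6]], blank = 0.05)
  hi <- dose_response_curve("c", "a", cu$concentration[cu$concentration >= doses_fix[6]],
                            cu$a450[cu$concentration >= doses_fix[6]], blank = 0.05)
  expect_equal(auc_logdose(lo) + auc_logdose(hi), auc_logdose(cu), tolerance = 1e-12)
})

test_that("apo vs RNP comparison applies the fold threshold", {
  f4 <- fit_4pl(make_curve(0, 1.8, 4, 1))
  f5 <- fit_4pl(make_curve(0, 1.8, 5, 1))
  f40 <- fit_4pl(make_curve(0, 1.8, 40, 1))
  cmp <- compare_apo_vs_rnp(f4, f5)
  expect_equal(cmp$fold, 1.25, tolerance = 1e-5)
  expect_true(cmp$similar)
  cmp2 <- compare_apo_vs_rnp(fit_4pl(make_curve(0, 1.8, 2, 1)), f40)
  expect_equal(cmp2$fold, 20, tolerance = 1e-4)
  expect_false(cmp2$similar)
  flat <- fit_4pl(dose_response_curve("c", "a", doses_fix, rep(0.05, 12), blank = 0.05))
  expect_error(compare_apo_vs_rnp(f4, flat), "converged")
})

test_that("paired equal-EC50 noisy curves are called similar in >= 95% of seeds", {
  similar <- vapply(1:100, function(s) {
    fa <- fit_4pl(make_curve(0, 1.8, 5, 1, noise_sd = 0.02, seed = s))
    fb <- fit_4pl(make_curve(0, 1.8, 5, 1, noise_sd = 0.02, seed = s + 1000))
    compare_apo_vs_rnp(fa, fb)$similar
  }, logical(1))
  expect_gte(sum(similar), 95)
})

test_that("cross-reactivity flags only antigens with real dose response", {
  set.seed(42)
  curves <- list(
    Cas9 = make_curve(0, 1.8, 5, 1),
    Cas3 = dose_response_curve("c", "Cas3", doses_fix,
                               0.05 + abs(rnorm(12, 0, 0.01)), blank = 0.05),
    Cas12 = dose_response_curve("c", "Cas12", doses_fix,
                                0.05 + abs(rnorm(12, 0, 0.01)), blank = 0.05))
  cr <- cross_reactivity(curves, blank_sd = 0.02)
  expect_true(cr$reactive[cr$antigen == "Cas9"])
  expect_false(cr$reactive[cr$antigen == "Cas3"])
  expect_false(cr$reactive[cr$antigen == "Cas12"])
})
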