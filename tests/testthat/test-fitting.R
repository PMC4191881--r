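xs <- exp(seq(log(2e-8), log(3e-6), length.out = 14))

test_that("the titration generator is exact, clipped and reproducible", {
  d0 <- simulate_titration(xs, core_total = 4e-7, kd_core = 1.3e-7)
  expect_equal(d0$y, holoenzyme_single(4e-7, xs, 1.3e-7) / 4e-7,
               tolerance = 1e-14)
  d1 <- simulate_titration(xs, 4e-7, 1.3e-7, noise_sd = 0.05, seed = 5)
  d2 <- simulate_titration(xs, 4e-7, 1.3e-7, noise_sd = 0.05, seed = 5)
  expect_identical(d1$y, d2$y)
  expect_true(all(d1$y >= 0))
  expect_false(identical(d1$y, d0$y))
  # the generator must not disturb the session RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_titration(xs, 4e-7, 1e-7,
                                            noise_sd = 0.1, seed = 9))
  expect_identical(runif(1), before)
  # multiplicative noise is unbiased: replicate means near the truth
  y_true <- d0$y[7]
  reps <- vapply(1:2000, function(s) {
    simulate_titration(xs, 4e-7, 1.3e-7, noise_sd = 0.02, seed = s)$y[7]
  }, numeric(1))
  se <- 0.02 * y_true / sqrt(2000)
  expect_lt(abs(mean(reps) - y_true), 3 * se)
})

test_that("binding titrations invert exactly without noise", {
  # truth values on the scale of measured sigma70 / sigmaS constants
  for (kd in c(1.3e-7, 2.5e-8)) {
    d <- simulate_titration(xs, 4e-7, kd)
    fit <- fit_binding_titration(d)
    expect_true(fit$converged)
    expect_lt(abs(tidy(fit)$estimate - kd) / kd, 1e-6)
  }
  # degenerate design: flagged, not raised
  flat <- simulate_titration(c(1e-7, 1e-7 * (1 + 1e-15), 1e-7 * (1 + 2e-15),
                               1e-7 * (1 + 3e-15)), 4e-7, 1e-7)
  flat$x <- rep(1e-7, 4)
  expect_true("non-identifiable" %in% fit_binding_titration(flat)$flags)
  expect_error(fit_binding_titration(simulate_titration(xs[1:3], 4e-7, 1e-7)),
               "at least 4")
})

test_that("transcription titrations recover Kd and Km jointly", {
  d <- simulate_titration(xs, 4e-7, kd_core = 2.45e-8, km = 2.11e-8)
  fit <- fit_transcription_titration(d)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est[["kd_core"]] - 2.45e-8) / 2.45e-8, 1e-4)
  expect_lt(abs(est[["km"]] - 2.11e-8) / 2.11e-8, 1e-4)
  # with km fixed the problem reduces to the binding fit
  fit2 <- fit_transcription_titration(d, km_fixed = 2.11e-8)
  expect_lt(abs(tidy(fit2)$estimate - 2.45e-8) / 2.45e-8, 1e-6)
  # flat response flagged
  d$y <- rep(0.5, nrow(d))
  expect_true("non-identifiable" %in%
                fit_transcription_titration(d)$flags)
})

test_that("fit residuals are orthogonal to the model gradient at the optimum", {
  d <- simulate_titration(xs, 4e-7, 1.3e-7, noise_sd = 0.02, seed = 21)
  fit <- fit_binding_titration(d)
  resid_fn <- function(lkd) {
    m <- holoenzyme_single(4e-7, d$x, exp(lkd)) / 4e-7
    (m - d$y) / m
  }
  J <- sigmacomp:::num_jacobian(resid_fn, fit$par_log)
  r <- resid_fn(fit$par_log)
  # first-order optimality: |J'r| small relative to |J||r|
  expect_lt(abs(crossprod(J, r)) / (sqrt(sum(J^2)) * sqrt(sum(r^2))), 1e-6)
})

test_that("relative-Kd fitting recovers a seven-species hierarchy", {
  kds <- c(s70 = 1e-9, sN = 2e-9, sS = 4e-9, sH = 8e-9,
           sF = 1.6e-8, sE = 3.2e-8, sFecI = 6.4e-8)
  mix <- simulate_titration(xs, core_total = 4e-7, kd_core = kds,
                            noise_sd = 0.02, seed = 13)
  fit <- fit_relative_kds(mix, reference = "s70")
  est <- tidy(fit)$estimate[-1]
  truth <- kds[-1] / kds[[1]]
  expect_true(fit$converged)
  expect_lt(max(abs(est - truth) / truth), 0.05)
  # two identical species: relative kd of exactly 1
  mix2 <- simulate_titration(xs, 4e-7, c(a = 5e-9, b = 5e-9))
  fit2 <- fit_relative_kds(mix2, ref_kd = 5e-9)
  expect_equal(tidy(fit2)$estimate[2], 1, tolerance = 1e-6)
  expect_error(fit_relative_kds(simulate_titration(xs, 4e-7,
                                                   c(only = 1e-9))),
               "at least 2")
})

test_that("only Kd ratios are identifiable: rescaling leaves predictions put", {
  # gauge property of the strong-binding mix: scaling every kd by the same
  # factor (while kd << core) barely moves the predicted curves
  kds <- c(a = 1e-10, b = 4e-10)
  p1 <- competition_prediction(kds, xs, 4e-7)
  p2 <- competition_prediction(kds * 2, xs, 4e-7)
  # exact only as kd -> 0: the titration knee softens on a sqrt(kd * core)
  # scale, so doubling 0.1 nM constants moves fractions by ~1e-2 at most
  expect_lt(max(abs(p1$fraction - p2$fraction)), 0.02)
  # equal kds split the cores evenly at every mix concentration
  peq <- competition_prediction(c(a = 2e-9, b = 2e-9), xs, 4e-7)
  expect_equal(peq$fraction[peq$species == "a"],
               peq$fraction[peq$species == "b"], tolerance = 1e-12)
  # single species matches the closed-form quadratic
  ps <- competition_prediction(c(a = 1.3e-7), xs, 4e-7)
  expect_equal(ps$holo, holoenzyme_single(4e-7, xs, 1.3e-7),
               tolerance = 1e-10)
  # the stronger binder holds the larger bound fraction at every x
  pd <- competition_prediction(c(s70 = 1.3e-7, sS = 2.5e-8), xs, 4e-7)
  expect_true(all(pd$fraction[pd$species == "sS"] >
                    pd$fraction[pd$species == "s70"]))
})

test_that("noisy-replicate recovery: small median error, calibrated SEs", {
  kd_true <- 1.3e-7
  errs <- covered <- numeric(50)
  for (s in 1:50) {
    d <- simulate_titration(xs, 4e-7, kd_true, noise_sd = 0.01, seed = s)
    fit <- fit_binding_titration(d)
    est <- tidy(fit)$estimate; se <- tidy(fit)$std.error
    errs[s] <- abs(est - kd_true) / kd_true
    covered[s] <- abs(est - kd_true) <= 2 * se
  }
  expect_lt(median(errs), 0.02)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
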