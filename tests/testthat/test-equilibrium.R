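ctx <- cell_context()

test_that("single-species holoenzyme quadratic is exact and stable", {
  # frozen high-precision quadratic-root values, 11400 cores / 5700 sigmas
  expect_equal(holoenzyme_single(11400, 5700, 1e-9, ctx), 5699.20529905,
               tolerance = 1e-10)
  expect_equal(holoenzyme_single(11400, 5700, 1e-6, ctx), 5064.54182938,
               tolerance = 1e-10)
  expect_identical(holoenzyme_single(0, 5700, 1e-9, ctx), 0)
  expect_identical(holoenzyme_single(11400, 0, 1e-9, ctx), 0)
  expect_error(holoenzyme_single(-1, 5, 1e-9), "core_total")
  expect_error(holoenzyme_single(1, 5, 0), "kd")
  # h is the root of (c-h)(s-h) = K h to 1e-12 relative: one Newton polish
  # of the mass-action polynomial does not move it
  for (K in 10^seq(-12, -5)) {
    c0 <- 1.2e-5; s0 <- 7.2e-6
    h <- holoenzyme_single(c0, s0, K)
    q <- (c0 - h) * (s0 - h) - K * h
    dq <- -(c0 - h) - (s0 - h) - K
    expect_lt(abs(q / dq) / h, 1e-12)
    expect_true(h >= 0 && h <= min(c0, s0))
  }
})

test_that("strong-binding limit: min() of the totals", {
  expect_equal(holoenzyme_strong_limit(11400, 7600), 7600)
  expect_equal(holoenzyme_strong_limit(5, 5), 5)
  # the deficit from min() scales as K*min/|c-s| once the totals are well
  # separated (near-equal totals approach the limit only as sqrt(K))
  withr::with_seed(11, {
    for (rep in 1:20) {
      s0 <- 10^runif(1, -7, -5)
      c0 <- s0 * runif(1, 1.5, 20)
      if (runif(1) < 0.5) { tmp <- c0; c0 <- s0; s0 <- tmp }
      K <- 1e-4 * min(c0, s0)
      h <- holoenzyme_single(c0, s0, K)
      expect_lt(abs(h - min(c0, s0)) / min(c0, s0), 1e-3)
    }
  })
})

test_that("anti-sigma partition solves its quadratic exactly", {
  # no anti-sigma: plain dilution by core binding
  p <- anti_sigma_partition(1e-6, 0, 1e-9, 2e-6, 1e-9)
  expect_equal(p$free_sigma, 1e-6 / (1 + 2e-6 / 1e-9), tolerance = 1e-12)
  # excess tight-binding anti-sigma wipes out holoenzyme formation
  p <- anti_sigma_partition(1e-6, 5e-6, 1e-12, 2e-6, 1e-9)
  expect_lt(p$free_sigma / 1e-6, 1e-4)
  expect_equal(p$complex, 1e-6, tolerance = 1e-3)
  # 5000 sigma + 5000 anti at 0.01 nM, no core: near-complete sequestration;
  # compare against an independent polyroot solution of the conservation laws
  S <- counts_to_molar(5000, ctx); A <- S; Ka <- 1e-11
  p <- anti_sigma_partition(S, A, Ka, 0, 1e-9)
  roots <- polyroot(c(-S * Ka, Ka + A - S, 1))
  f_exact <- max(Re(roots[abs(Im(roots)) < 1e-12 * abs(roots)]))
  expect_equal(p$free_sigma, f_exact, tolerance = 1e-10)
  # conservation of sigma and anti-sigma to 1e-12
  expect_lt(abs(p$free_sigma + p$complex - S) / S, 1e-12)
  expect_lt(abs(p$free_anti + p$complex - A) / A, 1e-12)
})

test_that("ratio law evaluates and guards the undefined case", {
  expect_equal(holoenzyme_ratio(1e-9, 1e-9, 2e-6, 2e-6), 1)
  expect_equal(holoenzyme_ratio(5e-10, 1e-9, 2e-6, 2e-6), 2)
  expect_error(holoenzyme_ratio(1e-9, 1e-9, 1e-6, 0), "undefined")
})

test_that("N-species solver reduces to the closed form and allocates cores", {
  # one species: identical to the quadratic
  sp <- sigma_species("s", 5700, kd_core = 1e-9)
  st <- solve_free_binding(sp, 11400)
  expect_equal(st$pools$total_holo, holoenzyme_single(11400, 5700, 1e-9, ctx),
               tolerance = 1e-10)
  # equal totals + equal kds -> equal holoenzymes
  st <- solve_free_binding(two_species(7600, 7600), 11400)
  expect_equal(st$pools$total_holo[1], st$pools$total_holo[2],
               tolerance = 1e-12)
  # strong binding, sigma excess: proportional allocation of cores
  st <- solve_free_binding(two_species(5700, 8000, 1e-12, 1e-12), 11400)
  expect_equal(st$pools$total_holo,
               11400 * c(5700, 8000) / 13700, tolerance = 1e-4)
  expect_error(solve_free_binding(sp[0, ], 100), "at least one")
})

test_that("solved states satisfy conservation and the ratio law", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(2:4, 1)
      sp <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        sigma_species(paste0("s", i), total = 10^runif(1, 2, 4.3),
                      kd_core = 10^runif(1, -9, -6))
      }))
      st <- solve_free_binding(sp, 10^runif(1, 3, 4.3))
      expect_lt(max(st$diagnostics$residual_sigma,
                    st$diagnostics$residual_core), 1e-9)
      expect_true(all(tidy(st, long = TRUE)$amount >= 0))
      # pairwise ratio law (the consistency check behind relative-Kd fits)
      h <- st$pools$free_holo; f <- st$pools$free_sigma
      for (i in 2:n) {
        pred <- holoenzyme_ratio(sp$kd_core[i], sp$kd_core[1], f[i], f[1])
        expect_lt(abs(h[i] / h[1] - pred) / pred, 1e-7)
      }
    }
  })
})

test_that("degenerate totals give the all-zero state, not an error", {
  st <- solve_free_binding(two_species(0, 0), 11400)
  expect_true(all(st$pools$total_holo == 0))
  expect_equal(st$free_core, 11400)
  st <- solve_free_binding(two_species(5700, 800), 0)
  expect_true(all(st$pools$total_holo == 0))
  expect_equal(st$pools$free_sigma, c(5700, 800))
})

test_that("species order is irrelevant: permuting inputs permutes outputs", {
  sp <- dplyr::bind_rows(
    sigma_species("a", 4000, kd_core = 2e-9),
    sigma_species("b", 7000, kd_core = 5e-8),
    sigma_species("c", 1000, kd_core = 1e-7, anti_total = 500,
                  kd_anti = 1e-10)
  )
  st1 <- solve_free_binding(sp, 9000)
  st2 <- solve_free_binding(sp[c(3, 1, 2), ], 9000)
  reord <- match(st1$pools$species, st2$pools$species)
  expect_identical(st1$pools$total_holo, st2$pools$total_holo[reord])
})

test_that("holoenzyme allocation responds monotonically to a competitor", {
  grid <- seq(0, 20000, by = 1000)
  sc <- competition_scan(two_species(5700, 0), 11400, "sigmaAlt", grid)
  h70 <- sc$total_holo[sc$species == "sigma70"]
  halt <- sc$total_holo[sc$species == "sigmaAlt"]
  expect_true(all(diff(h70) <= 1e-9))
  expect_true(all(diff(halt) >= -1e-9))
})

test_that("solver matches the mass-action ODE steady state", {
  skip_if_not_installed("deSolve")
  ctx_m <- cell_context(unit_mode = "molar")
  withr::with_seed(42, {
    for (rep in 1:5) {
      inst <- random_free_instance()
      sp <- dplyr::bind_rows(lapply(seq_along(inst$totals), function(i) {
        sigma_species(paste0("s", i), inst$totals[i],
                      kd_core = inst$kds[i])
      }))
      st <- solve_free_binding(sp, inst$core, context = ctx_m)
      ora <- ode_oracle(inst$totals, inst$kds, inst$core)
      scale <- max(inst$core, inst$totals)
      expect_rel_equal(st$pools$free_holo, ora$free_holo, 1e-6, scale)
      expect_rel_equal(st$free_core, ora$free_core, 1e-6, scale)
    }
  })
})
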