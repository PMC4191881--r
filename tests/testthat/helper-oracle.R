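# Independent steady-state oracle: integrate the explicit mass-action
# rate equations of the binding scheme (optionally with anti-sigma,
# non-specific sites, promoters and elongation) to stationarity with
# deSolve, and read off the pools. Entirely separate from the package's
# algebraic/root-finding solution path.

# All concentrations molar. Species i: S (free sigma), H (free holo),
# A (free anti), X (sigma-anti complex), HD (NS-bound holo); global E
# (free core), ED (NS-bound core). Promoter class g: Pf (free promoter),
# C (holo-promoter complex), T1 (elongating, sigma aboard), T2
# (elongating, core only) or Th (elongating as holoenzyme).
ode_oracle <- function(totals, kds, core,
                       anti_totals = rep(0, length(totals)),
                       kd_antis = rep(1e-9, length(totals)),
                       D = 0, kd_ns_holo = rep(1e-4, length(totals)),
                       kd_ns_core = 1e-4,
                       promoters = NULL, cog = integer(), p_conc = numeric(),
                       km = numeric(), kmax = numeric(),
                       tau_sigma = numeric(), tau_core = numeric(),
                       separate = logical(),
                       kon = 1e8, kon_a = 1e8, kon_ns = 1e5, koff_p = 1,
                       t_end = 2e6) {
  n <- length(totals)
  m <- length(p_conc)
  koff <- kon * kds
  koff_a <- kon_a * kd_antis
  kon_pr <- if (m) (koff_p + kmax) / km else numeric()
  idx <- function(base, i) base + i
  # state layout: E, ED, then per i: S,H,A,X,HD (5n), then per g: Pf,C,T1,T2
  y0 <- c(core, 0,
          as.vector(rbind(totals, 0, anti_totals, 0, 0)),
          if (m) as.vector(rbind(p_conc, 0, 0, 0)) else numeric())
  deriv <- function(t, y, parms) {
    E <- y[1]; ED <- y[2]
    S <- y[2 + 5 * (seq_len(n) - 1) + 1]
    H <- y[2 + 5 * (seq_len(n) - 1) + 2]
    A <- y[2 + 5 * (seq_len(n) - 1) + 3]
    X <- y[2 + 5 * (seq_len(n) - 1) + 4]
    HD <- y[2 + 5 * (seq_len(n) - 1) + 5]
    dE <- -sum(kon * E * S) + sum(koff * H) -
      (if (D > 0) kon_ns * D * E - kon_ns * kd_ns_core * ED else 0)
    dED <- if (D > 0) kon_ns * D * E - kon_ns * kd_ns_core * ED else 0
    dS <- -kon * E * S + koff * H - kon_a * S * A + koff_a * X
    dH <- kon * E * S - koff * H
    if (D > 0) {
      dH <- dH - kon_ns * D * H + kon_ns * kd_ns_holo * HD
      dHD <- kon_ns * D * H - kon_ns * kd_ns_holo * HD
    } else dHD <- rep(0, n)
    dA <- -kon_a * S * A + koff_a * X
    dX <- kon_a * S * A - koff_a * X
    dP <- numeric(0)
    if (m) {
      Pf <- y[2 + 5 * n + 4 * (seq_len(m) - 1) + 1]
      Cg <- y[2 + 5 * n + 4 * (seq_len(m) - 1) + 2]
      T1 <- y[2 + 5 * n + 4 * (seq_len(m) - 1) + 3]
      T2 <- y[2 + 5 * n + 4 * (seq_len(m) - 1) + 4]
      dPf <- dCg <- dT1 <- dT2 <- numeric(m)
      for (g in seq_len(m)) {
        i <- cog[g]
        bind <- kon_pr[g] * H[i] * Pf[g]
        unbind <- koff_p * Cg[g]
        init <- kmax[g] * Cg[g]
        dPf[g] <- -bind + unbind + init
        dCg[g] <- bind - unbind - init
        dH[i] <- dH[i] - bind + unbind
        if (separate[g]) {
          r1 <- T1[g] / tau_sigma[g]
          dT1[g] <- init - r1
          dS[i] <- dS[i] + r1
          if (tau_core[g] > tau_sigma[g]) {
            r2 <- T2[g] / (tau_core[g] - tau_sigma[g])
            dT2[g] <- r1 - r2
            dE <- dE + r2
          } else {
            dT2[g] <- 0
            dE <- dE + r1
          }
        } else {
          # sigma and core travel and are released together, as holoenzyme
          r1 <- T1[g] / tau_core[g]
          dT1[g] <- init - r1
          dH[i] <- dH[i] + r1
        }
      }
      dP <- as.vector(rbind(dPf, dCg, dT1, dT2))
    }
    list(c(dE, dED, as.vector(rbind(dS, dH, dA, dX, dHD)), dP))
  }
  out <- deSolve::ode(y = y0, times = c(0, t_end / 2, t_end), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-20, maxsteps = 5e5)
  fin <- out[nrow(out), -1]
  mid <- out[nrow(out) - 1, -1]
  scale <- max(core, totals)
  stopifnot(max(abs(fin - mid)) < 1e-8 * scale) # stationary
  res <- list(
    free_core = fin[1], ns_core = fin[2],
    free_sigma = fin[2 + 5 * (seq_len(n) - 1) + 1],
    free_holo = fin[2 + 5 * (seq_len(n) - 1) + 2],
    anti_complex = fin[2 + 5 * (seq_len(n) - 1) + 4],
    ns_holo = fin[2 + 5 * (seq_len(n) - 1) + 5]
  )
  if (m) {
    res$promoter_bound <- fin[2 + 5 * n + 4 * (seq_len(m) - 1) + 2]
    res$elong_sigma <- fin[2 + 5 * n + 4 * (seq_len(m) - 1) + 3]
    res$elong_core_only <- fin[2 + 5 * n + 4 * (seq_len(m) - 1) + 4]
  }
  res
}

# convenience: random small free-binding instance in molar
random_free_instance <- function() {
  n <- sample(1:4, 1)
  list(
    totals = 10^stats::runif(n, -8, -5),
    kds = 10^stats::runif(n, -9, -6),
    core = 10^stats::runif(1, -8, -5)
  )
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  s <- scale %||% pmax(abs(expected), .Machine$double.xmin)
  testthat::expect_lt(max(abs(actual - expected) / s), tol)
}

two_species <- function(t70 = 5700, talt = 8000, kd70 = 1e-9,
                        kdalt = 1e-9, ...) {
  dplyr::bind_rows(
    sigma_species("sigma70", t70, kd_core = kd70, ...),
    sigma_species("sigmaAlt", talt, kd_core = kdalt, ...)
  )
}
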