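# Dissociation-constant estimation from titration assays, and the
# synthetic titration generator used for parameter-recovery studies.
#
# The forward models are the exact single-species holoenzyme quadratic
# (binding assays, normalized to the plateau set by the fixed core
# amount) and the Michaelis-Menten occupancy of that holoenzyme
# (transcription assays). Fits minimize relative residuals (m - y)/m by
# Levenberg-Marquardt on log-scale parameters with a multi-start grid
# (the saturating regime can trap single starts in local minima);
# relative residuals are the natural objective under the multiplicative
# measurement noise these assays carry, and make the asymptotic standard
# errors calibrated.

# relative residual, guarded against a vanishing model value
rel_resid <- function(m, y) {
  (m - y) / pmax(m, 1e-12 * max(m, 1e-300))
}

run_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a titration dataset
#'
#' Evaluates the forward model of a titration assay -- fixed core RNAP,
#' varied total sigma -- and applies multiplicative Gaussian measurement
#' noise `y * (1 + eps)`, `eps ~ N(0, noise_sd^2)`, clipped at zero (the
#' gel/assay readouts such curves come from scale with signal).
#'
#' Supplying a *named vector* of dissociation constants generates an
#' equimolar competition mix: every species' total is set to `x` and the
#' N-species equilibrium is solved at each grid point.
#'
#' @param x Strictly increasing total sigma concentrations, molar (for a
#'   mix: the common equimolar concentration).
#' @param core_total Fixed core RNAP concentration, molar. The 400 nM
#'   default matches the classic holoenzyme reconstitution design.
#' @param kd_core Sigma-core dissociation constant(s), molar; a named
#'   vector yields a multi-species mix.
#' @param km Optional Michaelis constant: when given (single species
#'   only) the response is the normalized transcription rate
#'   `h / (km + h)` instead of the holoenzyme fraction `h / core_total`.
#' @param noise_sd Relative noise standard deviation (>= 0).
#' @param seed Optional integer seed; the global RNG state is left
#'   untouched.
#' @return A tibble of class `titration_data` with columns `x`, `y`,
#'   `species`, and attributes `core_total`, `y_kind`
#'   (`"binding"`/`"transcription"`), `noise_sd`, `seed`, `truth`.
#' @examples
#' d <- simulate_titration(seq(5e-8, 2e-6, length.out = 12),
#'                         core_total = 4e-7, kd_core = 1.3e-7,
#'                         noise_sd = 0.01, seed = 1)
#' @export
simulate_titration <- function(x, core_total = 4e-7, kd_core, km = NULL,
                               noise_sd = 0, seed = NULL) {
  check_pos(x, "x")
  if (is.unsorted(x, strictly = TRUE)) abort("`x` must be strictly increasing.")
  check_pos(core_total, "core_total")
  check_pos(kd_core, "kd_core")
  check_nonneg(noise_sd, "noise_sd")
  multi <- length(kd_core) > 1L
  if (multi && is.null(names(kd_core))) {
    abort("a multi-species `kd_core` must be named.")
  }
  if (multi && !is.null(km)) {
    abort("transcription titrations are single-species.")
  }
  if (multi) {
    pred <- competition_prediction(kd_core, x, core_total)
    out <- tibble(x = pred$x, y = pred$holo / core_total,
                  species = pred$species)
    y_kind <- "binding"
  } else {
    h <- holoenzyme_single(core_total, x, kd_core)
    y <- if (is.null(km)) h / core_total else h / (km + h)
    y_kind <- if (is.null(km)) "binding" else "transcription"
    out <- tibble(x = x, y = y,
                  species = names(kd_core) %||% "sigma")
  }
  if (noise_sd > 0) {
    out$y <- run_with_seed(seed, {
      pmax(out$y * (1 + rnorm(nrow(out), 0, noise_sd)), 0)
    })
  }
  structure(out, class = c("titration_data", class(out)),
            core_total = core_total, y_kind = y_kind,
            noise_sd = noise_sd, seed = seed,
            truth = list(kd_core = kd_core, km = km))
}

# numeric Jacobian of a residual function at par (central differences)
num_jacobian <- function(fn, par, rel = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    hstep <- max(abs(par[j]), 1) * rel
    pp <- pm <- par
    pp[j] <- par[j] + hstep; pm[j] <- par[j] - hstep
    J[, j] <- (fn(pp) - fn(pm)) / (2 * hstep)
  }
  J
}

# Shared LM multi-start driver on log-scale parameters.
# starts: list of numeric start vectors (log scale); resid_fn(par) -> residuals
lm_multistart <- function(resid_fn, starts) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed.")
  best
}

finish_fit <- function(best, resid_fn, term_names, data, flags = character(),
                       predict_fn = NULL) {
  par <- best$par
  n <- length(resid_fn(par))
  p <- length(par)
  rss <- best$deviance
  J <- num_jacobian(resid_fn, par)
  sv <- svd(J)$d
  if (min(sv) <= max(sv) * 1e-10) {
    flags <- c(flags, "weakly-identifiable")
    se_log <- rep(NA_real_, p)
  } else {
    sigma2 <- rss / max(n - p, 1)
    covm <- sigma2 * solve(crossprod(J))
    se_log <- sqrt(pmax(diag(covm), 0))
  }
  est <- exp(par)
  converged <- best$info %in% 1:4
  if (!converged) flags <- c(flags, "not-converged")
  structure(
    list(
      estimates = tibble(term = term_names, estimate = est,
                         std.error = est * se_log),
      rss = rss, converged = converged, iterations = best$niter,
      flags = flags, data = data, predict_fn = predict_fn,
      par_log = par
    ),
    class = "titration_fit"
  )
}

check_titration <- function(data, kind) {
  if (!inherits(data, "titration_data") &&
      !all(c("x", "y") %in% names(data))) {
    abort("`data` must be a titration dataset with columns x, y.")
  }
  if (!is.null(kind) && !is.null(attr(data, "y_kind")) &&
      attr(data, "y_kind") != kind) {
    abort(sprintf("`data` has y_kind '%s'; expected '%s'.",
                  attr(data, "y_kind"), kind))
  }
  invisible(data)
}

#' Fit a sigma-core dissociation constant from a binding titration
#'
#' Nonlinear least squares of the exact single-species holoenzyme curve,
#' normalized by its plateau (the fixed core amount), against measured
#' holoenzyme fractions, minimizing relative residuals (the natural
#' objective for the multiplicative noise of gel-based assays). The
#' plateau is computed from the model, not fitted. Multi-start from a log
#' grid of Kd values between 1e-12 and 1e-6 M; deterministic given the
#' data.
#'
#' @param data A `titration_data` tibble (y = holoenzyme fraction), or
#'   any data frame with columns `x`, `y` plus a `core_total` attribute
#'   or argument.
#' @param core_total Fixed core concentration, molar; defaults to the
#'   dataset attribute.
#' @param start_grid Kd multi-start values, molar.
#' @return A `titration_fit` object; see [tidy.titration_fit()] and
#'   [glance.titration_fit()]. Degenerate designs (no variation in `x`,
#'   boundary-pinned estimates) are flagged in `$flags` rather than
#'   raised.
#' @export
fit_binding_titration <- function(data, core_total = attr(data, "core_total"),
                                  start_grid = 10^seq(-12, -6)) {
  check_titration(data, "binding")
  if (length(unique(data$species %||% "sigma")) > 1L) {
    abort("multi-species data: use `fit_relative_kds()`.")
  }
  if (nrow(data) < 4) abort("need at least 4 titration points.")
  check_pos(core_total, "core_total")
  if (sd(data$x) == 0) {
    return(structure(
      list(estimates = tibble(term = "kd_core", estimate = NA_real_,
                              std.error = NA_real_),
           rss = NA_real_, converged = FALSE, iterations = 0L,
           flags = "non-identifiable", data = data, predict_fn = NULL,
           par_log = NA_real_),
      class = "titration_fit"
    ))
  }
  resid_fn <- function(par) {
    m <- holoenzyme_single(core_total, data$x, exp(par[1])) / core_total
    rel_resid(m, data$y)
  }
  best <- lm_multistart(resid_fn, as.list(log(start_grid)))
  flags <- character()
  kd_hat <- exp(best$par[1])
  if (kd_hat <= min(start_grid) * 1.01 || kd_hat >= max(start_grid) * 0.99) {
    flags <- "boundary"
  }
  finish_fit(best, resid_fn, "kd_core", data, flags,
             predict_fn = function(x) {
               holoenzyme_single(core_total, x, kd_hat) / core_total
             })
}

#' Jointly fit Kd and Michaelis constant from a transcription titration
#'
#' Least squares of `h / (km + h)` with `h` the exact holoenzyme curve,
#' fitting the sigma-core dissociation constant and the promoter
#' Michaelis constant simultaneously. On designs where the two constants
#' are exchangeable (nearly collinear gradients) the fit is flagged
#' `weakly-identifiable`.
#'
#' @inheritParams fit_binding_titration
#' @param data A `titration_data` tibble with y = normalized
#'   transcription rate.
#' @param km_fixed Optionally fix `km` and fit only the dissociation
#'   constant.
#' @return A `titration_fit` object with terms `kd_core` (and `km`).
#' @export
fit_transcription_titration <- function(data,
                                        core_total = attr(data, "core_total"),
                                        km_fixed = NULL,
                                        start_grid = 10^seq(-10, -6)) {
  check_titration(data, "transcription")
  if (nrow(data) < 4) abort("need at least 4 titration points.")
  check_pos(core_total, "core_total")
  if (sd(data$y) == 0 || sd(data$x) == 0) {
    return(structure(
      list(estimates = tibble(term = c("kd_core", "km"),
                              estimate = NA_real_, std.error = NA_real_),
           rss = NA_real_, converged = FALSE, iterations = 0L,
           flags = "non-identifiable", data = data, predict_fn = NULL,
           par_log = NA_real_),
      class = "titration_fit"
    ))
  }
  if (!is.null(km_fixed)) {
    check_pos(km_fixed, "km_fixed")
    resid_fn <- function(par) {
      h <- holoenzyme_single(core_total, data$x, exp(par[1]))
      rel_resid(h / (km_fixed + h), data$y)
    }
    best <- lm_multistart(resid_fn, as.list(log(start_grid)))
    kd_hat <- exp(best$par[1])
    return(finish_fit(best, resid_fn, "kd_core", data,
                      predict_fn = function(x) {
                        h <- holoenzyme_single(core_total, x, kd_hat)
                        h / (km_fixed + h)
                      }))
  }
  resid_fn <- function(par) {
    h <- holoenzyme_single(core_total, data$x, exp(par[1]))
    rel_resid(h / (exp(par[2]) + h), data$y)
  }
  starts <- unlist(lapply(log(start_grid), function(a) {
    lapply(log(start_grid), function(b) c(a, b))
  }), recursive = FALSE)
  best <- lm_multistart(resid_fn, starts)
  kd_hat <- exp(best$par[1]); km_hat <- exp(best$par[2])
  finish_fit(best, resid_fn, c("kd_core", "km"), data,
             predict_fn = function(x) {
               h <- holoenzyme_single(core_total, x, kd_hat)
               h / (km_hat + h)
             })
}

#' Fit relative dissociation constants from an equimolar competition mix
#'
#' In a mixed reconstitution assay every sigma species is present at the
#' same total concentration and competes for a fixed pool of core RNAP.
#' Because the holoenzyme ratio of any species pair depends only on the
#' inverse ratio of their dissociation constants, such data identify the
#' Kd *hierarchy* -- the vector of constants relative to a reference
#' species -- but not the absolute scale when binding is strong. The
#' reference Kd is therefore pinned (1 nM by default, deep in the
#' strong-binding regime relative to the core amount) and the remaining
#' log-ratios are fitted to all species' curves simultaneously.
#'
#' @param mix_data Long-format `titration_data` with >= 2 species.
#' @param reference Reference species label; defaults to the first.
#' @param ref_kd Pinned reference dissociation constant, molar.
#' @inheritParams fit_binding_titration
#' @return A `titration_fit` whose terms are `kd_<species>/kd_<reference>`
#'   ratios (the reference itself reported as exactly 1 with no error).
#' @export
fit_relative_kds <- function(mix_data,
                             core_total = attr(mix_data, "core_total"),
                             reference = NULL, ref_kd = 1e-9) {
  check_titration(mix_data, "binding")
  check_pos(core_total, "core_total")
  check_pos(ref_kd, "ref_kd")
  sps <- unique(mix_data$species)
  if (length(sps) < 2) abort("need at least 2 species to fit relative Kds.")
  reference <- reference %||% sps[1]
  if (!reference %in% sps) abort("`reference` must be one of the species.")
  others <- setdiff(sps, reference)
  xs <- sort(unique(mix_data$x))
  predict_mix <- function(rel) {
    kds <- setNames(ref_kd * c(1, rel), c(reference, others))
    pred <- competition_prediction(kds, xs, core_total)
    pred$fraction_of_core <- pred$holo / core_total
    pred
  }
  resid_fn <- function(par) {
    pred <- predict_mix(exp(par))
    key_p <- paste(pred$species, pred$x)
    key_d <- paste(mix_data$species, mix_data$x)
    m <- pred$fraction_of_core[match(key_d, key_p)]
    rel_resid(m, mix_data$y)
  }
  # crude ratio-law start: invert h_i/h_ref at a mid-grid concentration
  x_mid <- xs[ceiling(length(xs) / 2)]
  y_mid <- vapply(sps, function(sp) {
    ys <- mix_data$y[mix_data$species == sp & mix_data$x == x_mid]
    if (length(ys)) mean(ys) else NA_real_
  }, numeric(1))
  start2 <- if (all(is.finite(y_mid)) && all(y_mid > 0)) {
    log(pmin(pmax(y_mid[reference] / y_mid[others], 1e-3), 1e3))
  } else NULL
  starts <- list(rep(0, length(others)))
  if (!is.null(start2)) starts <- c(starts, list(unname(start2)))
  best <- lm_multistart(resid_fn, starts)
  rel_hat <- exp(best$par)
  fit <- finish_fit(best, resid_fn,
                    paste0("kd_", others, "/kd_", reference), mix_data,
                    predict_fn = function(x) {
                      kds <- setNames(ref_kd * c(1, rel_hat),
                                      c(reference, others))
                      competition_prediction(kds, x, core_total)
                    })
  fit$estimates <- dplyr::bind_rows(
    tibble(term = paste0("kd_", reference, "/kd_", reference),
           estimate = 1, std.error = 0),
    fit$estimates
  )
  fit$reference <- reference
  fit
}

#' Predict holoenzyme fractions in an equimolar competition mix
#'
#' Forward N-species equilibrium solve at each mix concentration, with no
#' refitting: dissociation constants determined from single-species
#' titrations predict the outcome of the competition assay.
#'
#' @param kds Named vector of dissociation constants, molar.
#' @param grid Equimolar total sigma concentrations, molar.
#' @param core_total Fixed core concentration, molar.
#' @return A tibble with `x`, `species`, `holo` (molar) and `fraction`
#'   (fraction of that species' sigma bound in holoenzyme).
#' @export
competition_prediction <- function(kds, grid, core_total) {
  check_pos(kds, "kds")
  check_pos(grid, "grid")
  check_pos(core_total, "core_total")
  if (is.null(names(kds))) names(kds) <- paste0("sigma", seq_along(kds))
  n <- length(kds)
  rows <- purrr::map(grid, function(x) {
    eng <- partition_engine(
      totals = rep(x, n), kds = unname(kds),
      anti_totals = rep(0, n), kd_antis = rep(NA_real_, n),
      r_holo = rep(0, n), r_core = 0, core_total = core_total
    )
    tibble(x = x, species = names(kds), holo = eng$free_holo,
           fraction = ifelse(x > 0, eng$free_holo / x, 0))
  })
  dplyr::bind_rows(rows)
}
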