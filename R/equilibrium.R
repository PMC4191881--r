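# Core binding equilibrium: partition core RNAP among N sigma species.
#
# Everything here works in molar. The N-species problem reduces to a single
# scalar root-find on the free core concentration x: given x, each species'
# free sigma follows in closed form (a quadratic when an anti-sigma factor
# shares the sigma), and the core conservation law
#   E_tot = x * (1 + D/K_NS,core) + sum_i h_i(x) * (1 + D/K_NS,holo_i)
# is monotone increasing in x, so the root on [0, E_tot] is unique.

#' Holoenzyme formation for a single sigma species
#'
#' Exact solution of the single-species binding equilibrium
#' `(c - h)(s - h) = K h`, evaluated in the numerically stable form
#' `h = 2cs / (c + s + K + sqrt((c + s + K)^2 - 4cs))` that avoids
#' catastrophic cancellation for strong binding (`K` much smaller than the
#' totals).
#'
#' @param core_total,sigma_total Total core and sigma concentrations
#'   (molar), or copy numbers when `context` is supplied.
#' @param kd Sigma-core dissociation constant, molar (> 0).
#' @param context Optional [cell_context()]; when given, `core_total` and
#'   `sigma_total` are interpreted as copies per cell and the result is
#'   returned in copies per cell.
#' @return The holoenzyme concentration (or count), between 0 and
#'   `min(core_total, sigma_total)`.
#' @examples
#' # 11400 cores, 5700 sigmas in a 1.32 fL cell, Kd = 1 nM:
#' holoenzyme_single(11400, 5700, 1e-9, context = cell_context())
#' @export
holoenzyme_single <- function(core_total, sigma_total, kd, context = NULL) {
  check_nonneg(core_total, "core_total")
  check_nonneg(sigma_total, "sigma_total")
  check_pos(kd, "kd")
  if (!is.null(context)) {
    core_total <- counts_to_molar(core_total, context)
    sigma_total <- counts_to_molar(sigma_total, context)
  }
  b <- core_total + sigma_total + kd
  disc <- b^2 - 4 * core_total * sigma_total
  h <- 2 * core_total * sigma_total / (b + sqrt(pmax(disc, 0)))
  if (!is.null(context)) h <- molar_to_counts(h, context)
  h
}

#' Strong-binding limit of holoenzyme formation
#'
#' In the limit of very strong sigma-core binding every possible complex
#' forms, so the holoenzyme amount is simply the smaller of the two totals.
#'
#' @inheritParams holoenzyme_single
#' @return `min(core_total, sigma_total)`, elementwise.
#' @export
holoenzyme_strong_limit <- function(core_total, sigma_total) {
  check_nonneg(core_total, "core_total")
  check_nonneg(sigma_total, "sigma_total")
  pmin(core_total, sigma_total)
}

#' Partition one sigma species between core RNAP and its anti-sigma factor
#'
#' Solves, for a fixed free-core concentration, the coupled equilibrium of
#' one sigma with core (holoenzyme formation) and with an anti-sigma factor
#' that has its own conservation law. Eliminating free anti-sigma leaves a
#' quadratic in free sigma, solved in a cancellation-safe form.
#'
#' @param sigma_total,anti_total Totals (molar), >= 0.
#' @param kd_anti Sigma--anti-sigma dissociation constant (molar, > 0).
#' @param free_core Free core concentration (molar, >= 0), held fixed.
#' @param kd_core Sigma-core dissociation constant (molar, > 0).
#' @param ns_factor Optional multiplier `(1 + D/K_NS,holo)` accounting for
#'   non-specifically bound holoenzyme drawing on the same sigma pool
#'   (default 1 = no DNA).
#' @return A list with `free_sigma`, `free_anti`, `complex` (sigma bound in
#'   the anti-sigma complex), and `holo` (free holoenzyme at this
#'   `free_core`).
#' @export
anti_sigma_partition <- function(sigma_total, anti_total, kd_anti, free_core,
                                 kd_core, ns_factor = 1) {
  check_nonneg(sigma_total, "sigma_total")
  check_nonneg(anti_total, "anti_total")
  check_nonneg(free_core, "free_core")
  check_pos(kd_core, "kd_core")
  # core-binding burden per unit free sigma: holo (free + NS-bound)
  b <- 1 + (free_core / kd_core) * ns_factor
  if (anti_total == 0) {
    f <- sigma_total / b
    return(list(free_sigma = f, free_anti = 0, complex = 0,
                holo = free_core * f / kd_core))
  }
  check_pos(kd_anti, "kd_anti")
  # sigma conservation with anti-sigma eliminated:
  #   b f^2 + (b Ka + A - S) f - S Ka = 0,  f = free sigma
  B <- b * kd_anti + anti_total - sigma_total
  q <- B^2 + 4 * b * sigma_total * kd_anti
  f <- if (B >= 0) {
    2 * sigma_total * kd_anti / (B + sqrt(q))
  } else {
    (-B + sqrt(q)) / (2 * b)
  }
  free_anti <- anti_total / (1 + f / kd_anti)
  list(free_sigma = f, free_anti = free_anti,
       complex = f * free_anti / kd_anti,
       holo = free_core * f / kd_core)
}

#' Ratio law for two holoenzyme species
#'
#' At equilibrium the ratio of two holoenzyme concentrations depends only
#' on the free sigma concentrations and the inverse ratio of the
#' dissociation constants: `h_i / h_j = (K_j / K_i) (s_i / s_j)`. This
#' holds regardless of how many further species compete, which is what
#' makes pairwise relative-Kd estimation from mixed assays possible.
#'
#' @param kd_i,kd_j Dissociation constants (molar, > 0).
#' @param free_sigma_i,free_sigma_j Free sigma concentrations (>= 0;
#'   `free_sigma_j` must be positive).
#' @return The dimensionless predicted ratio `h_i / h_j`.
#' @export
holoenzyme_ratio <- function(kd_i, kd_j, free_sigma_i, free_sigma_j) {
  check_pos(kd_i, "kd_i")
  check_pos(kd_j, "kd_j")
  check_nonneg(free_sigma_i, "free_sigma_i")
  check_nonneg(free_sigma_j, "free_sigma_j")
  if (any(free_sigma_j == 0)) {
    abort("`free_sigma_j` is 0: the holoenzyme ratio is undefined.")
  }
  (kd_j / kd_i) * (free_sigma_i / free_sigma_j)
}

# ---- internal partition engine ------------------------------------------

# Solve the N-species partition in molar.
#   totals, kds, kon, anti_totals, kd_antis: per-species vectors
#   r_holo: per-species (D / K_NS,holo); r_core: scalar (D / K_NS,core)
# Returns per-species pools plus free core and diagnostics.
partition_engine <- function(totals, kds, anti_totals, kd_antis,
                             r_holo, r_core, core_total,
                             tol = 1e-12, maxiter = 200L) {
  n <- length(totals)
  pools_at <- function(x) {
    f <- h <- cx <- fa <- numeric(n)
    for (i in seq_len(n)) {
      p <- anti_sigma_partition(totals[i], anti_totals[i],
                                if (anti_totals[i] > 0) kd_antis[i] else 1,
                                x, kds[i], ns_factor = 1 + r_holo[i])
      f[i] <- p$free_sigma; h[i] <- p$holo
      cx[i] <- p$complex; fa[i] <- p$free_anti
    }
    list(f = f, h = h, complex = cx, free_anti = fa)
  }
  core_used <- function(x) {
    p <- pools_at(x)
    x * (1 + r_core) + sum(p$h * (1 + r_holo))
  }
  if (core_total <= 0 || sum(totals) == 0) {
    x <- if (core_total <= 0) 0 else core_total / (1 + r_core)
    p <- pools_at(x)
    iter <- 0L
  } else {
    xmax <- core_total / (1 + r_core)
    g <- function(x) core_used(x) - core_total
    root <- uniroot(g, interval = c(0, xmax), f.lower = -core_total,
                    tol = xmax * tol, maxiter = maxiter)
    x <- root$root
    p <- pools_at(x)
    # polish: core conservation is exactly linear in x given the h's scale
    # with x only weakly near the root; one Newton-free correction step via
    # re-bracketing is unnecessary -- uniroot at rel tol 1e-12 suffices.
    iter <- root$iter
  }
  residual_core <- abs(x * (1 + r_core) + sum(p$h * (1 + r_holo)) -
                         core_total) / max(core_total, .Machine$double.xmin)
  list(free_core = x, ns_core = x * r_core,
       free_sigma = p$f, free_holo = p$h, ns_holo = p$h * r_holo,
       anti_complex = p$complex, free_anti = p$free_anti,
       iterations = iter, residual_core = residual_core)
}

# Assemble a holo_state object from engine output (all molar in, reported
# per context$unit_mode).
build_state <- function(species, eng, context, core_total_molar,
                        extra = NULL, class = "holo_state") {
  n <- nrow(species)
  zero <- numeric(n)
  pb <- extra$promoter_bound %||% zero
  el <- extra$elongating %||% zero
  ret <- extra$retained %||% zero
  keff <- extra$effective_kd %||% species$kd_core
  conv <- function(x) {
    if (context$unit_mode == "counts") molar_to_counts(x, context) else x
  }
  pools <- tibble(
    species = species$name,
    free_sigma = conv(eng$free_sigma),
    free_holo = conv(eng$free_holo),
    ns_bound_holo = conv(eng$ns_holo),
    promoter_bound_holo = conv(pb),
    elongating_cores = conv(el),
    retained_sigmas = conv(ret),
    anti_bound_sigma = conv(eng$anti_complex),
    total_holo = conv(eng$free_holo + eng$ns_holo),
    effective_kd = keff
  )
  sigma_sum <- eng$free_sigma + eng$free_holo + eng$ns_holo + pb + ret +
    eng$anti_complex
  res_sigma <- abs(sigma_sum - species$total_molar) /
    pmax(species$total_molar, .Machine$double.xmin)
  core_sum <- eng$free_core + eng$ns_core +
    sum(eng$free_holo + eng$ns_holo + pb + el)
  res_core <- abs(core_sum - core_total_molar) /
    max(core_total_molar, .Machine$double.xmin)
  structure(
    list(
      pools = pools,
      free_core = conv(eng$free_core),
      ns_bound_core = conv(eng$ns_core),
      core_total = conv(core_total_molar),
      promoters = extra$promoters,
      diagnostics = list(
        residual_sigma = setNames(res_sigma, species$name),
        residual_core = res_core,
        iterations = eng$iterations + (extra$outer_iterations %||% 0L),
        converged = extra$converged %||% TRUE
      ),
      context = context
    ),
    class = c(class, "holo_state")
  )
}

#' Solve the sigma-core binding equilibrium (no DNA)
#'
#' Partitions a shared pool of core RNAP among any number of sigma
#' species, with optional anti-sigma sequestration, in the absence of DNA.
#' The coupled conservation laws are reduced to a bracketed scalar
#' root-find on the free core concentration; the solution is deterministic
#' and satisfies every conservation law to near machine precision.
#'
#' @param species Species table (see [sigma_species()]); `total` is in
#'   copies per cell when `context$unit_mode == "counts"` (the default),
#'   molar otherwise.
#' @param core_total Total core RNAP (same units as species totals).
#' @param context A [cell_context()].
#' @return An object of class `holo_state` with elements `pools` (a tibble
#'   of per-species pools), `free_core`, `ns_bound_core`, and solver
#'   `diagnostics`. Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' species <- dplyr::bind_rows(
#'   sigma_species("sigma70", 5700, kd_core = 1e-9),
#'   sigma_species("sigmaAlt", 8000, kd_core = 1e-9)
#' )
#' st <- solve_free_binding(species, core_total = 11400)
#' tidy(st)
#' @export
solve_free_binding <- function(species, core_total, context = cell_context()) {
  species <- as_species_table(species)
  check_nonneg(core_total, "core_total")
  to_molar <- function(x) {
    if (context$unit_mode == "counts") counts_to_molar(x, context) else x
  }
  species$total_molar <- to_molar(species$total)
  species$anti_molar <- to_molar(species$anti_total)
  core_molar <- to_molar(core_total)
  eng <- partition_engine(
    totals = species$total_molar, kds = species$kd_core,
    anti_totals = species$anti_molar, kd_antis = species$kd_anti,
    r_holo = rep(0, nrow(species)), r_core = 0, core_total = core_molar
  )
  build_state(species, eng, context, core_molar)
}
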