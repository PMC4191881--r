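# The full sigma cycle at steady state: holoenzymes bind promoters,
# initiate, and the elongating complex releases sigma after the retention
# length and core at the terminator. Differential release adds an active
# separation pathway to the binding equilibrium, inflating the sigma-core
# dissociation constant to an effective value
#   K_eff = K + alpha / (k_on * h),
# where alpha is the initiation flux per volume drained through the
# cognate promoters and h the free holoenzyme concentration. Elongation
# also sequesters subunits: by Little's law a steady flux alpha holds
# alpha * tau_core cores and alpha * tau_sigma sigmas in elongating
# complexes.

#' Sigma and core retention times of a promoter class
#'
#' `tau_sigma = retention_length / elongation_speed` (how long sigma rides
#' the elongating complex before its stochastic release) and
#' `tau_core = operon_length / elongation_speed` (commitment of core until
#' the terminator). With the default 300 nt retention at 55 nt/s sigma is
#' held for about 5 s, while a 1500-6000 nt operon commits core for
#' roughly 30-120 s.
#'
#' @param promoter One row of a promoter table ([promoter_class()]).
#' @return A list with `tau_sigma` and `tau_core`, seconds.
#' @export
retention_times <- function(promoter) {
  list(tau_sigma = promoter$retention_length / promoter$elongation_speed,
       tau_core = promoter$operon_length / promoter$elongation_speed)
}

#' Effective sigma-core dissociation constant under active transcription
#'
#' Transcription initiation separates sigma from core in addition to
#' spontaneous unbinding, so the apparent dissociation constant becomes
#' `K_eff = K + alpha / (kon * h)`: the per-holoenzyme initiation rate
#' `alpha / h` acts as an extra off-rate. Equivalently, with the
#' Michaelis-Menten flux `alpha = kmax [P] h / (km + h)`, one has
#' `K_eff = K + kmax [P] / (kon (km + h))`. `K_eff -> K` as the flux
#' vanishes or binding becomes fast.
#'
#' @param kd Equilibrium dissociation constant, molar (> 0).
#' @param kon Sigma-core association rate, /M/s (> 0).
#' @param alpha_per_volume Initiation flux per volume, M/s (>= 0).
#' @param holo_free Free holoenzyme concentration, molar.
#' @return The effective dissociation constant, molar; always `>= kd`.
#' @export
effective_kd <- function(kd, kon, alpha_per_volume, holo_free) {
  check_pos(kd, "kd")
  check_pos(kon, "kon")
  check_nonneg(alpha_per_volume, "alpha_per_volume")
  check_nonneg(holo_free, "holo_free")
  if (alpha_per_volume > 0 && holo_free == 0) {
    abort("inconsistent state: positive initiation flux with no free holoenzyme.")
  }
  if (alpha_per_volume == 0) return(kd)
  kd + alpha_per_volume / (kon * holo_free)
}

#' Solve the self-consistent transcription-cycle steady state
#'
#' Couples the binding equilibrium (optionally with non-specific DNA
#' binding) to promoter occupancy and transcript elongation by damped
#' fixed-point iteration: (a) partition the *available* subunits --
#' totals minus promoter-bound and elongating amounts -- using the
#' current effective dissociation constants, then (b) recompute
#' occupancies, initiation fluxes, sequestered pools and `K_eff` from the
#' resulting free holoenzymes, until all pools are stationary.
#'
#' Promoter classes with `release_mode = "holoenzyme_release"` return
#' sigma and core to the pool together, so their binding keeps the
#' equilibrium `kd` and sigma rides the full operon; `"separate_release"`
#' classes release sigma after the retention length and contribute to
#' `K_eff`.
#'
#' @inheritParams solve_with_ns
#' @param promoters Promoter table ([promoter_class()] rows); may be
#'   empty, in which case the result equals [solve_free_binding()] /
#'   [solve_with_ns()].
#' @param ns Optional [ns_params()]; `NULL` disables non-specific binding.
#' @param damping Fixed-point damping factor in (0, 1]; 0.5 by default.
#'   Smaller values help when the `K_eff` feedback is strong.
#' @param tol Relative convergence tolerance on all pools.
#' @param max_iter Iteration cap.
#' @return An object of class `cycle_state` (a `holo_state` with
#'   per-promoter fluxes in `$promoters` and per-species `effective_kd`,
#'   `promoter_bound_holo`, `elongating_cores`, `retained_sigmas` pools).
#' @export
solve_cycle <- function(species, promoters, core_total, ns = NULL,
                        context = cell_context(), damping = 0.5,
                        tol = 1e-9, max_iter = 10000L) {
  species <- as_species_table(species)
  promoters <- as_promoter_table(promoters, species$name)
  check_nonneg(core_total, "core_total")
  stopifnot(damping > 0, damping <= 1)
  to_molar <- function(x) {
    if (context$unit_mode == "counts") counts_to_molar(x, context) else x
  }
  species$total_molar <- to_molar(species$total)
  species$anti_molar <- to_molar(species$anti_total)
  core_molar <- to_molar(core_total)
  n <- nrow(species)
  m <- nrow(promoters)
  if (is.null(ns)) {
    r_holo <- rep(0, n); r_core <- 0
  } else {
    D <- ns_sites_molar(context)
    r_holo <- D / species$kd_ns_holo
    r_core <- D / ns$kd_ns_core
  }
  cog <- match(promoters$cognate_sigma, species$name)
  p_conc <- counts_to_molar(promoters$count, context)
  tau_sigma <- promoters$retention_length / promoters$elongation_speed
  tau_core <- promoters$operon_length / promoters$elongation_speed
  separate <- promoters$release_mode == "separate_release"
  # sigma rides the whole operon when released as holoenzyme
  tau_sigma_eff <- ifelse(separate, tau_sigma, tau_core)

  # pools below ~1e-12 of the system scale are far below one molecule;
  # treat changes there as absolute so they cannot stall convergence
  floor_c <- max(core_molar, species$total_molar, .Machine$double.xmin) * 1e-12
  pb <- alpha <- rep(0, m)
  keff <- species$kd_core
  h_prev <- rep(NA_real_, n)
  converged <- m == 0L
  iter <- 0L
  prev_change <- Inf
  worse <- 0L
  eng <- NULL
  repeat {
    iter <- iter + 1L
    seq_sigma <- seq_core_tot <- 0
    if (m > 0) {
      seq_sigma <- vapply(seq_len(n), function(i) {
        sum((pb + alpha * tau_sigma_eff)[cog == i])
      }, numeric(1))
      seq_core_tot <- sum(pb + alpha * tau_core)
    } else {
      seq_sigma <- rep(0, n)
    }
    eng <- partition_engine(
      totals = pmax(species$total_molar - seq_sigma, 0),
      kds = keff,
      anti_totals = species$anti_molar, kd_antis = species$kd_anti,
      r_holo = r_holo, r_core = r_core,
      core_total = max(core_molar - seq_core_tot, 0)
    )
    if (m == 0L) { converged <- TRUE; break }
    h <- eng$free_holo
    new_pb <- p_conc * h[cog] / (promoters$km + h[cog])
    new_alpha <- promoters$kmax * new_pb
    # the proposed occupancies cannot sequester more sigma (or core) than
    # exists; rescale transient overshoots, which otherwise oscillate
    # against the availability clamp for scarce species
    for (i in seq_len(n)) {
      g <- cog == i
      demand <- sum((new_pb + new_alpha * tau_sigma_eff)[g])
      if (demand > species$total_molar[i] && demand > 0) {
        fac <- species$total_molar[i] / demand
        new_pb[g] <- new_pb[g] * fac
        new_alpha[g] <- new_alpha[g] * fac
      }
    }
    core_demand <- sum(new_pb + new_alpha * tau_core)
    if (core_demand > core_molar && core_demand > 0) {
      fac <- core_molar / core_demand
      new_pb <- new_pb * fac
      new_alpha <- new_alpha * fac
    }
    change <- max(abs(new_pb - pb) / pmax(abs(pb), floor_c),
                  abs(new_alpha - alpha) / pmax(abs(alpha), floor_c),
                  if (all(is.finite(h_prev))) {
                    abs(h - h_prev) / pmax(abs(h_prev), floor_c)
                  } else Inf)
    pb <- pb + damping * (new_pb - pb)
    alpha <- alpha + damping * (new_alpha - alpha)
    keff <- vapply(seq_len(n), function(i) {
      a_sep <- sum(alpha[separate & cog == i])
      if (a_sep == 0 || h[i] == 0) return(species$kd_core[i])
      effective_kd(species$kd_core[i], species$kon_core[i], a_sep, h[i])
    }, numeric(1))
    h_prev <- h
    if (change < tol) { converged <- TRUE; break }
    # stall/oscillation detection: no new best residual for 30 iterations
    if (change < prev_change * 0.97) {
      prev_change <- change
      worse <- 0L
    } else {
      worse <- worse + 1L
    }
    if (worse > 30L) {
      # oscillation: the local fixed-point map is too steep for this
      # damping (scarce species under heavy promoter load); relax it
      if (damping > 1e-3) {
        damping <- damping / 2
        worse <- 0L
        prev_change <- change
      } else {
        abort(sprintf(paste0(
          "solve_cycle: oscillating fixed-point iteration ",
          "(relative change %.3g after %d iterations) even at minimal ",
          "damping; supply a smaller `damping` factor or check the ",
          "scenario."), change, iter))
      }
    }
    if (iter >= max_iter) {
      abort(sprintf(paste0(
        "solve_cycle: no convergence after %d iterations ",
        "(last relative change %.3g)."), iter, change))
    }
  }

  if (m > 0L) {
    # re-partition once with the final sequestered pools so the reported
    # state satisfies the conservation laws to the inner solver tolerance
    seq_sigma <- vapply(seq_len(n), function(i) {
      sum((pb + alpha * tau_sigma_eff)[cog == i])
    }, numeric(1))
    eng <- partition_engine(
      totals = pmax(species$total_molar - seq_sigma, 0),
      kds = keff,
      anti_totals = species$anti_molar, kd_antis = species$kd_anti,
      r_holo = r_holo, r_core = r_core,
      core_total = max(core_molar - sum(pb + alpha * tau_core), 0)
    )
  }

  per_species <- function(v) {
    vapply(seq_len(n), function(i) sum(v[cog == i]), numeric(1))
  }
  extra <- list(
    promoter_bound = if (m > 0) per_species(pb) else rep(0, n),
    elongating = if (m > 0) per_species(alpha * tau_core) else rep(0, n),
    retained = if (m > 0) per_species(alpha * tau_sigma_eff) else rep(0, n),
    effective_kd = keff,
    converged = converged,
    outer_iterations = iter
  )
  conv <- function(x) {
    if (context$unit_mode == "counts") molar_to_counts(x, context) else x
  }
  if (m > 0) {
    extra$promoters <- tibble(
      name = promoters$name,
      cognate_sigma = promoters$cognate_sigma,
      occupancy = pb / p_conc,
      flux = alpha,
      initiations_per_cell = alpha * AVOGADRO * context$volume * 1e-15,
      bound_holo = conv(pb),
      elongating_cores = conv(alpha * tau_core),
      retained_sigmas = conv(alpha * tau_sigma_eff),
      tau_sigma = tau_sigma,
      tau_core = tau_core,
      release_mode = promoters$release_mode
    )
  }
  build_state(species, eng, context, core_molar, extra = extra,
              class = "cycle_state")
}
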