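# Parameter scans, competition-onset detection, and response-factor
# (hypersensitivity) analysis.

solve_level <- function(species, core_total, level, promoters, ns, context) {
  switch(level,
    free = solve_free_binding(species, core_total, context = context),
    ns = solve_with_ns(species, core_total, ns = ns %||% ns_params(),
                       context = context),
    cycle = solve_cycle(species, promoters, core_total, ns = ns,
                        context = context),
    abort(sprintf("unknown model level '%s'.", level))
  )
}

set_control <- function(species, core_total, control, value) {
  if (control == "core_total") {
    list(species = species, core_total = value)
  } else {
    if (!control %in% species$name) {
      abort(sprintf("`control` '%s' is neither 'core_total' nor a species name.",
                    control))
    }
    species$total[species$name == control] <- value
    list(species = species, core_total = core_total)
  }
}

#' Scan a model over a grid of one control quantity
#'
#' Solves the configured model (free binding, with non-specific DNA, or
#' the full transcription cycle) at every value of a control quantity --
#' a species total or the core total -- and returns a tidy tibble of
#' per-species pools, plus normalized transcription rates for species
#' with a cognate promoter class.
#'
#' @inheritParams solve_cycle
#' @param control `"core_total"` or the name of a species whose total is
#'   varied.
#' @param grid Strictly increasing vector of control values (same units
#'   as the totals).
#' @param level Model level: `"free"`, `"ns"`, or `"cycle"`.
#' @return A tibble of class `sigma_scan` with columns `control`,
#'   `species`, `free_sigma`, `free_holo`, `total_holo` and (when a
#'   cognate promoter exists) `normalized_rate`; attributes record the
#'   control name and level. [autoplot()] draws the holoenzyme curves.
#' @examples
#' species <- dplyr::bind_rows(
#'   sigma_species("sigma70", 5700), sigma_species("sigmaAlt", 0)
#' )
#' sc <- competition_scan(species, 11400, control = "sigmaAlt",
#'                        grid = seq(0, 20000, by = 2000))
#' @export
competition_scan <- function(species, core_total, control, grid,
                             level = c("free", "ns", "cycle"),
                             promoters = NULL, ns = NULL,
                             context = cell_context()) {
  level <- match.arg(level)
  species <- as_species_table(species)
  if (length(grid) < 1 || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing.")
  }
  if (level == "cycle") {
    promoters <- as_promoter_table(promoters, species$name)
  }
  rows <- purrr::map(grid, function(x) {
    inp <- set_control(species, core_total, control, x)
    st <- tryCatch(
      solve_level(inp$species, inp$core_total, level, promoters, ns, context),
      error = function(e) {
        abort(sprintf("scan failed at %s = %g: %s", control, x,
                      conditionMessage(e)))
      }
    )
    out <- st$pools[, c("species", "free_sigma", "free_holo", "total_holo")]
    out$control <- x
    if (!is.null(promoters) && nrow(promoters) > 0) {
      hf <- setNames(
        if (context$unit_mode == "counts") {
          counts_to_molar(st$pools$free_holo, context)
        } else st$pools$free_holo,
        st$pools$species
      )
      out$normalized_rate <- vapply(out$species, function(sp) {
        g <- which(promoters$cognate_sigma == sp)
        if (!length(g)) return(NA_real_)
        normalized_rate(hf[[sp]], promoters[g[1], ])
      }, numeric(1))
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  res <- res[, c("control", setdiff(names(res), "control"))]
  structure(as_tibble(res),
            class = c("sigma_scan", class(as_tibble(res))),
            control = control, level = level)
}

#' Locate the onset of sigma factor competition
#'
#' The onset is defined as the smallest value of the control quantity at
#' which the observed holoenzyme drops to `1 - threshold` (by default 5%
#' below) of its value at the reference control value. The criterion is
#' applied to the free holoenzymes when non-specific DNA or the
#' transcription cycle is modeled, and to total holoenzymes in the
#' DNA-free model. A coarse scan brackets the crossing, which is then
#' refined by root bisection to a relative tolerance of 1e-6.
#'
#' @inheritParams competition_scan
#' @param observe Name of the species whose holoenzyme is monitored;
#'   defaults to the first species (the housekeeping sigma).
#' @param reference_value Control value defining the reference state
#'   (typically 0 competitor).
#' @param threshold Fractional reduction defining the onset (default
#'   0.05).
#' @param grid Optional search grid; by default 200 log-spaced points
#'   spanning up to twice the total subunit pool.
#' @return A one-row tibble with `onset` (NA if the reduction is never
#'   reached on the grid), `at_reference` (TRUE when the criterion is met
#'   at the first grid point already, the "housekeeping sigma already in
#'   excess" situation), and the reference observable.
#' @export
competition_onset <- function(species, core_total, control,
                              reference_value = 0, threshold = 0.05,
                              level = c("free", "ns", "cycle"),
                              promoters = NULL, ns = NULL, grid = NULL,
                              context = cell_context(), observe = NULL) {
  level <- match.arg(level)
  species <- as_species_table(species)
  observe <- observe %||% species$name[1]
  if (!observe %in% species$name) abort("`observe` must name a species.")
  if (level == "cycle") {
    promoters <- as_promoter_table(promoters, species$name)
  }
  obs <- function(x) {
    inp <- set_control(species, core_total, control, x)
    st <- solve_level(inp$species, inp$core_total, level, promoters, ns,
                      context)
    col <- if (level == "free") "total_holo" else "free_holo"
    st$pools[[col]][st$pools$species == observe]
  }
  ref <- obs(reference_value)
  target <- (1 - threshold) * ref
  if (ref <= 0) abort("reference observable is 0; onset undefined.")
  if (is.null(grid)) {
    hi <- 2 * (max(core_total, sum(species$total)) + sum(species$total))
    lo <- max(reference_value, hi * 1e-6)
    grid <- exp(seq(log(lo), log(hi), length.out = 200))
  }
  vals <- vapply(grid, obs, numeric(1))
  below <- which(vals <= target)
  if (!length(below)) {
    return(tibble(onset = NA_real_, at_reference = FALSE, reference = ref,
                  control = control, threshold = threshold))
  }
  k <- below[1]
  if (k == 1L) {
    return(tibble(onset = grid[1], at_reference = TRUE, reference = ref,
                  control = control, threshold = threshold))
  }
  root <- uniroot(function(x) obs(x) - target,
                  interval = c(grid[k - 1], grid[k]),
                  tol = grid[k] * 1e-8)
  tibble(onset = root$root, at_reference = FALSE, reference = ref,
         control = control, threshold = threshold)
}

#' Logarithmic response factor along a grid
#'
#' The response factor `R = d ln(rate) / d ln(x)` measures how strongly
#' an observable responds to a control parameter; `R > 1` marks
#' hypersensitivity (amplification beyond proportionality). Computed by
#' central differences in log-log space (one-sided at the endpoints), so
#' a log-spaced grid makes it a plain slope.
#'
#' @param rate Positive rates evaluated on `grid`, or a function of the
#'   control value returning them.
#' @param grid Strictly increasing, positive control values.
#' @return Numeric vector of `R` values, one per grid point.
#' @examples
#' g <- exp(seq(log(1), log(100), length.out = 50))
#' response_factor(g^2, g) # == 2 everywhere
#' @export
response_factor <- function(rate, grid) {
  if (is.function(rate)) rate <- vapply(grid, rate, numeric(1))
  if (length(rate) != length(grid)) abort("`rate` and `grid` lengths differ.")
  check_pos(grid, "grid")
  if (any(rate <= 0)) abort("`rate` must be positive everywhere on the grid.")
  lx <- log(grid); ly <- log(rate)
  n <- length(grid)
  if (n < 2) abort("need at least two grid points.")
  R <- numeric(n)
  R[1] <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  R[n] <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
  if (n > 2) {
    R[2:(n - 1)] <- (ly[3:n] - ly[1:(n - 2)]) / (lx[3:n] - lx[1:(n - 2)])
  }
  R
}

#' Maximum of the response factor over a control scan
#'
#' Evaluates the normalized transcription rate of one promoter class
#' along a control grid, computes the logarithmic response factor, and
#' refines the grid maximum by golden-section search on the local
#' log-slope. For strong sigma-core binding the maximum sensitivity of
#' alternative-sigma transcription to core availability sits near the
#' point where cores just saturate the housekeeping sigma pool.
#'
#' @inheritParams competition_scan
#' @param promoter A one-row promoter table whose cognate species'
#'   normalized rate is the observable.
#' @return A one-row tibble: `x_at_max`, `r_max`, and `hypersensitive`
#'   (`r_max > 1`).
#' @export
max_response <- function(species, core_total, control, grid,
                         promoter, level = c("free", "ns", "cycle"),
                         promoters = NULL, ns = NULL,
                         context = cell_context()) {
  level <- match.arg(level)
  species <- as_species_table(species)
  sp <- promoter$cognate_sigma[1]
  if (!sp %in% species$name) abort("promoter cognate sigma not in species.")
  if (level == "cycle") promoters <- as_promoter_table(promoters, species$name)
  rate_fun <- function(x) {
    inp <- set_control(species, core_total, control, x)
    st <- solve_level(inp$species, inp$core_total, level, promoters, ns,
                      context)
    hf <- st$pools$free_holo[st$pools$species == sp]
    if (context$unit_mode == "counts") hf <- counts_to_molar(hf, context)
    normalized_rate(hf, promoter)
  }
  R <- response_factor(rate_fun, grid)
  i <- which.max(R)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  delta <- 1e-4
  local_R <- function(x) {
    (log(rate_fun(x * exp(delta))) - log(rate_fun(x * exp(-delta)))) /
      (2 * delta)
  }
  opt <- optimize(local_R, interval = c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.35 * hi)
  tibble(x_at_max = opt$maximum, r_max = opt$objective,
         hypersensitive = opt$objective > 1)
}

#' Necessary condition for hypersensitivity to core availability
#'
#' For strong sigma-core binding, the response factor of
#' alternative-sigma transcription to the core RNAP number can only have
#' a maximum (and hence exhibit hypersensitivity) if the alternative
#' sigma pool is strictly smaller than the housekeeping pool. The exact
#' condition involves the dissociation constants but its right-hand side
#' approaches 1 for nanomolar-scale binding, leaving the strict
#' inequality on the totals; the equality case is conservatively
#' classified as not hypersensitive.
#'
#' @param sigma70_total,sigma_alt_total Available totals (same units).
#' @param kd70,kd_alt Dissociation constants, molar (accepted for
#'   interface completeness; the strong-binding form does not use them).
#' @return Logical: can a response-factor maximum exist?
#' @export
hypersensitivity_condition <- function(sigma70_total, sigma_alt_total,
                                       kd70 = 1e-9, kd_alt = 1e-8) {
  check_nonneg(sigma70_total, "sigma70_total")
  check_nonneg(sigma_alt_total, "sigma_alt_total")
  check_pos(kd70, "kd70")
  check_pos(kd_alt, "kd_alt")
  sigma_alt_total < sigma70_total
}

#' Stringent-response scenario preset
#'
#' Bookkeeping of RNA polymerase pools in an *E. coli* cell growing at
#' 2.5 doublings/h at the moment rRNA transcription shuts down: of 11400
#' total RNAPs, 1100 are immature, 2600 transcribe rRNA and 700 mRNA, and
#' 7000 are free or non-specifically bound. Stopping rRNA transcription
#' releases the 2600 rRNA-transcribing cores, raising the pool available
#' for mRNA transcription from 7700 to 10300 (= 11400 - 1100). The preset
#' carries 9000 available (non-anti-sigma-sequestered) housekeeping
#' sigmas, 5000 alternative sigmas, a 10 uM promoter Michaelis constant,
#' and strong nanomolar sigma-core binding with the housekeeping factor
#' binding more strongly.
#'
#' @param kd70,kd_alt Sigma-core dissociation constants (molar) for the
#'   housekeeping and alternative sigma. The nanomolar defaults (1 nM
#'   and 10 nM) follow the measured binding hierarchy; both are freely
#'   configurable.
#' @param km Promoter Michaelis constant, molar.
#' @return A list of class `stringent_scenario` with the pool bookkeeping,
#'   derived `available_before` / `available_after` core numbers, the
#'   species table and a [cell_context()].
#' @export
stringent_preset <- function(kd70 = 1e-9, kd_alt = 1e-8, km = 1e-5) {
  pools <- list(rnap_total = 11400, immature = 1100,
                rrn_transcribing = 2600, mrna_transcribing = 700,
                free_or_ns = 7000)
  stopifnot(with(pools, immature + rrn_transcribing + mrna_transcribing +
                   free_or_ns) == pools$rnap_total)
  species <- dplyr::bind_rows(
    sigma_species("sigma70", total = 9000, kd_core = kd70),
    sigma_species("sigmaAlt", total = 5000, kd_core = kd_alt)
  )
  structure(
    c(pools, list(
      sigma70_available = 9000, sigma_alt = 5000, km = km,
      growth_rate = "2.5 dbl/h",
      available_before = pools$free_or_ns + pools$mrna_transcribing,
      available_after = pools$rnap_total - pools$immature,
      species = species,
      promoter = promoter_class("PaltRNA", "sigmaAlt", km = km),
      context = cell_context()
    )),
    class = "stringent_scenario"
  )
}

#' @export
print.stringent_scenario <- function(x, ...) {
  cat("<stringent_scenario> growth", x$growth_rate, "\n")
  cat(sprintf(" RNAP total %d = %d immature + %d rrn + %d mRNA + %d free/NS\n",
              x$rnap_total, x$immature, x$rrn_transcribing,
              x$mrna_transcribing, x$free_or_ns))
  cat(sprintf(" available cores: %d before, %d after rrn shutdown\n",
              x$available_before, x$available_after))
  cat(sprintf(" sigma70 %d (Kd %.3g M), sigmaAlt %d (Kd %.3g M), K_M %.3g M\n",
              x$sigma70_available, x$species$kd_core[1], x$sigma_alt,
              x$species$kd_core[2], x$km))
  invisible(x)
}
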