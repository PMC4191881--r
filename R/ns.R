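# Non-specific DNA binding of cores and holoenzymes, under the
# excess-sites approximation: with ~1.7e7 genomic sites and at most ~1e4
# bound molecules, free sites ~ total sites, so every cytoplasmic pool is
# mirrored by a DNA-bound pool scaled by D / K_NS.

#' Probability that a molecule is cytoplasmically free
#'
#' Under the excess-sites approximation a molecule with non-specific
#' dissociation constant `kd_ns` facing a site concentration `D`
#' partitions between cytoplasm and DNA with free fraction
#' `p_free = 1 / (1 + D / kd_ns)`.
#'
#' @param ns_sites_conc Non-specific site concentration `D`, molar.
#' @param kd_ns Non-specific dissociation constant, molar (> 0).
#' @return The free fraction, in (0, 1].
#' @examples
#' ns_scaling_factor(1e-4, 1e-4) # half occupancy -> 0.5
#' @export
ns_scaling_factor <- function(ns_sites_conc, kd_ns) {
  check_nonneg(ns_sites_conc, "ns_sites_conc")
  check_pos(kd_ns, "kd_ns")
  1 / (1 + ns_sites_conc / kd_ns)
}

#' Solve the binding equilibrium with non-specific DNA binding
#'
#' As [solve_free_binding()], but free core and each free holoenzyme
#' additionally partition onto non-specific DNA sites (excess-sites
#' approximation). When core and all holoenzymes share the same
#' non-specific dissociation constant, total holoenzyme amounts are
#' exactly those of the DNA-free system and the free pools are rescaled by
#' [ns_scaling_factor()]; unequal constants break this rescaling (e.g. a
#' stickier core is sequestered away from sigma binding).
#'
#' @inheritParams solve_free_binding
#' @param ns An [ns_params()] object carrying the core non-specific Kd;
#'   per-species holoenzyme constants come from the species table's
#'   `kd_ns_holo` column. With `context$ns_sites == 0` this reduces to
#'   [solve_free_binding()].
#' @return A `holo_state`; `pools$ns_bound_holo` and `ns_bound_core` hold
#'   the DNA-bound amounts.
#' @export
solve_with_ns <- function(species, core_total, ns = ns_params(),
                          context = cell_context()) {
  species <- as_species_table(species)
  check_nonneg(core_total, "core_total")
  if (!inherits(ns, "ns_params")) abort("`ns` must be an `ns_params` object.")
  to_molar <- function(x) {
    if (context$unit_mode == "counts") counts_to_molar(x, context) else x
  }
  species$total_molar <- to_molar(species$total)
  species$anti_molar <- to_molar(species$anti_total)
  core_molar <- to_molar(core_total)
  D <- ns_sites_molar(context)
  eng <- partition_engine(
    totals = species$total_molar, kds = species$kd_core,
    anti_totals = species$anti_molar, kd_antis = species$kd_anti,
    r_holo = D / species$kd_ns_holo, r_core = D / ns$kd_ns_core,
    core_total = core_molar
  )
  build_state(species, eng, context, core_molar)
}
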