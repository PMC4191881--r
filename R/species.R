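#' Describe a sigma factor species
#'
#' Returns a one-row tibble describing one sigma species: its total copy
#' number, its affinity for core RNAP, and optional anti-sigma and
#' non-specific-DNA parameters. Bind rows together (e.g. with
#' [dplyr::bind_rows()]) to build the species table that the solvers take
#' as their first argument.
#'
#' @param name Species label, e.g. `"sigma70"`.
#' @param total Total copies per cell (>= 0).
#' @param kd_core Sigma-core dissociation constant in molar (> 0). The
#'   default 1 nM is the nominal strong-binding value used throughout the
#'   in-vivo scenarios.
#' @param kon_core Sigma-core association rate in /M/s; only needed when
#'   effective dissociation constants are computed (transcription cycle).
#'   Default 1e8 /M/s, a diffusion-limited protein-protein rate.
#' @param kd_ns_holo Holoenzyme non-specific DNA dissociation constant in
#'   molar; used only by the non-specific-binding and cycle solvers.
#'   Default 1e-4 M.
#' @param anti_total Copies of a cognate anti-sigma factor (0 = none).
#' @param kd_anti Sigma--anti-sigma dissociation constant in molar;
#'   required when `anti_total > 0`.
#' @return A one-row tibble with class-checked columns.
#' @examples
#' species <- dplyr::bind_rows(
#'   sigma_species("sigma70", total = 5700, kd_core = 1e-9),
#'   sigma_species("sigmaAlt", total = 8000, kd_core = 1e-9)
#' )
#' @export
sigma_species <- function(name, total, kd_core = 1e-9, kon_core = 1e8,
                          kd_ns_holo = 1e-4, anti_total = 0,
                          kd_anti = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  check_nonneg(total, "total")
  check_pos(kd_core, "kd_core")
  check_pos(kon_core, "kon_core")
  check_pos(kd_ns_holo, "kd_ns_holo")
  check_nonneg(anti_total, "anti_total")
  if (anti_total > 0) check_pos(kd_anti, "kd_anti")
  tibble(
    name = name, total = as.numeric(total), kd_core = kd_core,
    kon_core = kon_core, kd_ns_holo = kd_ns_holo,
    anti_total = as.numeric(anti_total), kd_anti = kd_anti
  )
}

# Fill defaults / validate a user-supplied species data frame.
as_species_table <- function(species) {
  if (!is.data.frame(species) || nrow(species) == 0) {
    abort("`species` must be a data frame with at least one row.")
  }
  if (!all(c("name", "total") %in% names(species))) {
    abort("`species` needs at least `name` and `total` columns.")
  }
  defaults <- list(kd_core = 1e-9, kon_core = 1e8, kd_ns_holo = 1e-4,
                   anti_total = 0, kd_anti = NA_real_)
  for (col in names(defaults)) {
    if (!col %in% names(species)) species[[col]] <- defaults[[col]]
    species[[col]][is.na(species[[col]]) & col != "kd_anti"] <- defaults[[col]]
  }
  if (anyDuplicated(species$name)) abort("species names must be unique.")
  check_nonneg(species$total, "total")
  check_pos(species$kd_core, "kd_core")
  check_nonneg(species$anti_total, "anti_total")
  bad_anti <- species$anti_total > 0 &
    (is.na(species$kd_anti) | species$kd_anti <= 0)
  if (any(bad_anti)) {
    abort(sprintf("species %s: `kd_anti` must be > 0 when `anti_total` > 0.",
                  paste(species$name[bad_anti], collapse = ", ")))
  }
  as_tibble(species)
}

#' Describe a promoter class
#'
#' A promoter class groups the promoters recognized by one holoenzyme
#' species: copy number, Michaelis parameters of initiation, operon and
#' sigma-retention lengths, the elongation speed, and how sigma and core
#' leave the transcription cycle. The defaults are the nominal values for
#' a class of sigma-cognate genes in a fast-growing cell: 200 promoters,
#' a 2000-nt operon transcribed at 55 nt/s, a maximal initiation rate of
#' 40/min and a sigma retention length of 300 nt.
#'
#' @param name Class label.
#' @param cognate_sigma Label of the sigma species whose holoenzyme
#'   transcribes this class.
#' @param count Promoter copies per cell.
#' @param km Michaelis constant of initiation in molar (holoenzyme
#'   concentration at half-maximal initiation).
#' @param kmax Maximal initiation rate per promoter, per second.
#' @param operon_length,retention_length Operon length and sigma retention
#'   length in nucleotides; `retention_length <= operon_length`.
#' @param elongation_speed Transcript elongation speed, nt/s.
#' @param release_mode `"separate_release"`: sigma leaves the elongating
#'   complex after the retention length and core at the terminator (the
#'   physiological sigma cycle, which inflates the effective sigma-core
#'   Kd); `"holoenzyme_release"`: sigma and core leave together, so the
#'   equilibrium Kd applies.
#' @param repressors Optional list of `list(species =, kd_rep =)` entries
#'   for non-transcribing holoenzymes that bind (and thereby repress) this
#'   promoter.
#' @return A one-row tibble; `repressors` is a list-column.
#' @export
promoter_class <- function(name, cognate_sigma, count = 200, km = 1e-9,
                           kmax = 40 / 60, operon_length = 2000,
                           retention_length = 300, elongation_speed = 55,
                           release_mode = c("separate_release",
                                            "holoenzyme_release"),
                           repressors = NULL) {
  release_mode <- match.arg(release_mode)
  stopifnot(is.character(name), is.character(cognate_sigma))
  check_nonneg(count, "count")
  check_pos(km, "km")
  check_nonneg(kmax, "kmax")
  check_pos(operon_length, "operon_length")
  check_pos(retention_length, "retention_length")
  check_pos(elongation_speed, "elongation_speed")
  if (retention_length > operon_length) {
    abort("`retention_length` must not exceed `operon_length`.")
  }
  tibble(
    name = name, cognate_sigma = cognate_sigma, count = as.numeric(count),
    km = km, kmax = kmax, operon_length = operon_length,
    retention_length = retention_length,
    elongation_speed = elongation_speed, release_mode = release_mode,
    repressors = list(repressors)
  )
}

as_promoter_table <- function(promoters, species_names) {
  if (is.null(promoters) || (is.data.frame(promoters) && nrow(promoters) == 0)) {
    return(promoter_class("none", "none")[0, ])
  }
  if (!is.data.frame(promoters)) abort("`promoters` must be a data frame.")
  needed <- c("name", "cognate_sigma", "count", "km", "kmax", "operon_length",
              "retention_length", "elongation_speed", "release_mode")
  missing <- setdiff(needed, names(promoters))
  if (length(missing)) {
    abort(paste0("`promoters` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"repressors" %in% names(promoters)) {
    promoters$repressors <- vector("list", nrow(promoters))
  }
  unknown <- setdiff(promoters$cognate_sigma, species_names)
  if (length(unknown)) {
    abort(sprintf("promoter cognate sigma(s) not in species table: %s",
                  paste(unknown, collapse = ", ")))
  }
  as_tibble(promoters)
}

#' Non-specific DNA binding parameters
#'
#' @param kd_ns_core Core RNAP non-specific dissociation constant, molar.
#'   Per-holoenzyme constants live in the species table (`kd_ns_holo`).
#' @return A list of class `ns_params`.
#' @export
ns_params <- function(kd_ns_core = 1e-4) {
  check_pos(kd_ns_core, "kd_ns_core")
  structure(list(kd_ns_core = kd_ns_core), class = "ns_params")
}
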