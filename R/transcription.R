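# Promoter occupancy and transcription rates. Initiation is described by a
# Michaelis-Menten model in the free holoenzyme concentration; repression
# by non-transcribing holoenzymes at shared/overlapping promoters uses the
# standard single-site competitive occupancy form.

#' Transcription rate of a promoter class
#'
#' Michaelis-Menten initiation: `rate = kmax * [P] * h / (km + h)`, an RNA
#' synthesis rate per volume (M/s when `holo_free` and the promoter
#' concentration are molar).
#'
#' @param holo_free Free cognate holoenzyme concentration, molar (>= 0).
#' @param promoter One row of a promoter table ([promoter_class()]).
#' @param context [cell_context()] used to convert the promoter copy
#'   number to a concentration.
#' @return Rate per volume, M/s.
#' @export
transcription_rate <- function(holo_free, promoter,
                               context = cell_context()) {
  check_nonneg(holo_free, "holo_free")
  p_conc <- counts_to_molar(promoter$count, context)
  promoter$kmax * p_conc * holo_free / (promoter$km + holo_free)
}

#' Normalized transcription rate per gene
#'
#' The Michaelis-Menten occupancy `h / (km + h)`, i.e. the rate divided by
#' its maximum `kmax * [P]`; dimensionless, in `[0, 1)`.
#'
#' @inheritParams transcription_rate
#' @export
normalized_rate <- function(holo_free, promoter) {
  check_nonneg(holo_free, "holo_free")
  holo_free / (promoter$km + holo_free)
}

#' Transcription rate with holoenzyme repression
#'
#' Some promoters bind more than one holoenzyme species although only the
#' cognate one initiates; the others act as competitive repressors. The
#' occupancy then follows the single-site competition form
#' `rate = kmax * [P] * (h/km) / (1 + h/km + sum_r r/K_rep)`,
#' which reduces to [transcription_rate()] when every repressor
#' concentration is zero and, unlike plain Michaelis-Menten competition
#' for core, suppresses even saturated promoters.
#'
#' @inheritParams transcription_rate
#' @param repressor_holo_free Named vector of free repressor holoenzyme
#'   concentrations (molar), names matching the promoter's `repressors`
#'   species labels.
#' @return Rate per volume, M/s.
#' @export
rate_with_repressor <- function(holo_free, repressor_holo_free, promoter,
                                context = cell_context()) {
  check_nonneg(holo_free, "holo_free")
  check_nonneg(repressor_holo_free, "repressor_holo_free")
  reps <- promoter$repressors[[1]]
  if (is.null(reps) || length(reps) == 0) {
    abort("promoter has no repressors; use `transcription_rate()`.")
  }
  rep_term <- 0
  for (r in reps) {
    if (!r$species %in% names(repressor_holo_free)) {
      abort(sprintf("repressor species '%s' missing from `repressor_holo_free`.",
                    r$species))
    }
    check_pos(r$kd_rep, "kd_rep")
    rep_term <- rep_term + repressor_holo_free[[r$species]] / r$kd_rep
  }
  p_conc <- counts_to_molar(promoter$count, context)
  x <- holo_free / promoter$km
  promoter$kmax * p_conc * x / (1 + x + rep_term)
}

#' Effective Michaelis-Menten parameters of a two-step initiation scheme
#'
#' Maps the scheme "holoenzyme binds the promoter (`kon_p`, `koff_p`),
#' bound complex initiates (`kinit`)" onto an effective Michaelis-Menten
#' description: `km = (koff_p + kinit) / kon_p`, `kmax = kinit`. When
#' initiation is much slower than promoter unbinding the Michaelis
#' constant approaches the equilibrium promoter dissociation constant
#' `koff_p / kon_p`.
#'
#' @param kon_p Promoter association rate, /M/s.
#' @param koff_p Promoter dissociation rate, /s.
#' @param kinit Initiation (escape) rate, /s.
#' @return A list with `km` (molar) and `kmax` (/s).
#' @export
mm_from_three_state <- function(kon_p, koff_p, kinit) {
  check_pos(kon_p, "kon_p")
  check_nonneg(koff_p, "koff_p")
  check_nonneg(kinit, "kinit")
  list(km = (koff_p + kinit) / kon_p, kmax = kinit)
}
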