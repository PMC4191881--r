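# Unit handling. The model is solved in molar throughout; copy numbers per
# cell are a reporting/input convenience tied to the cell volume.

AVOGADRO <- 6.02214076e23

# E. coli genome, base pairs; non-specific sites default to one site per bp
# times the number of genome equivalents in a fast-growing cell.
GENOME_BP <- 4.6e6
GENOME_EQUIVALENTS <- 3.8

#' Cell context: volume and non-specific-site bookkeeping
#'
#' Holds the conversion between molecule copy numbers per cell and molar
#' concentrations, and the number of non-specific DNA binding sites. The
#' default volume of 1.32 fL corresponds to an average rapidly growing
#' *E. coli* cell; the default site count is one site per base pair over
#' 3.8 genome equivalents.
#'
#' @param volume Cell volume in fL. Must be positive.
#' @param ns_sites Number of non-specific DNA binding sites per cell
#'   (dimensionless count, may be 0 for a DNA-free system).
#' @param unit_mode `"counts"` (default) or `"molar"`; controls the units in
#'   which solved states are reported. Internally everything is molar.
#' @return A list of class `cell_context`.
#' @examples
#' ctx <- cell_context()
#' molar_to_counts(counts_to_molar(11400, ctx), ctx) # round-trips exactly
#' @export
cell_context <- function(volume = 1.32,
                         ns_sites = GENOME_EQUIVALENTS * GENOME_BP,
                         unit_mode = c("counts", "molar")) {
  unit_mode <- match.arg(unit_mode)
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    abort("`volume` must be a single positive number (fL).")
  }
  if (!is.numeric(ns_sites) || length(ns_sites) != 1L || ns_sites < 0) {
    abort("`ns_sites` must be a single non-negative number.")
  }
  structure(
    list(volume = volume, ns_sites = ns_sites, unit_mode = unit_mode),
    class = "cell_context"
  )
}

#' @export
print.cell_context <- function(x, ...) {
  cat(sprintf(
    "<cell_context> volume %.3g fL, %.3g non-specific sites, reporting in %s\n",
    x$volume, x$ns_sites, x$unit_mode
  ))
  invisible(x)
}

#' Convert copy numbers per cell to molar concentration
#'
#' `n = C * N_A * V` with `V` the cell volume; these two helpers are exact
#' inverses of each other.
#'
#' @param n Copy number(s) per cell.
#' @param context A [cell_context()].
#' @return Concentration(s) in molar.
#' @export
counts_to_molar <- function(n, context = cell_context()) {
  n / (AVOGADRO * context$volume * 1e-15)
}

#' @rdname counts_to_molar
#' @param conc Concentration(s) in molar.
#' @export
molar_to_counts <- function(conc, context = cell_context()) {
  conc * AVOGADRO * context$volume * 1e-15
}

# Molar concentration of non-specific sites for a context.
ns_sites_molar <- function(context) {
  counts_to_molar(context$ns_sites, context)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and >= 0.", name))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and > 0.", name))
  }
  invisible(x)
}
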