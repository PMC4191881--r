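# broom-style accessors and print methods for solved states and fits.

#' Tidy a solved equilibrium or cycle state
#'
#' @param x A `holo_state` (or `cycle_state`).
#' @param long If `TRUE`, pivot to one row per species per pool.
#' @param ... Unused.
#' @return A tibble of per-species pools, in the units of the state's
#'   `cell_context` (`counts` by default).
#' @method tidy holo_state
#' @export
tidy.holo_state <- function(x, long = FALSE, ...) {
  out <- x$pools
  if (long) {
    out <- tidyr::pivot_longer(out, -c("species", "effective_kd"),
                               names_to = "pool", values_to = "amount")
  }
  out
}

#' One-row summary of a solved state
#'
#' @param x A `holo_state`.
#' @param ... Unused.
#' @return A one-row tibble: free/NS-bound core, iteration count,
#'   convergence flag and worst conservation residual.
#' @method glance holo_state
#' @export
glance.holo_state <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    free_core = x$free_core, ns_bound_core = x$ns_bound_core,
    core_total = x$core_total,
    iterations = d$iterations, converged = d$converged,
    max_residual = max(d$residual_sigma, d$residual_core)
  )
}

#' @export
print.holo_state <- function(x, ...) {
  u <- x$context$unit_mode
  cat(sprintf("<%s> %d species, core total %.4g (%s)\n",
              class(x)[1], nrow(x$pools), x$core_total, u))
  print(x$pools, n = nrow(x$pools))
  cat(sprintf("free core %.4g, NS-bound core %.4g; converged: %s (max residual %.2g)\n",
              x$free_core, x$ns_bound_core, x$diagnostics$converged,
              max(x$diagnostics$residual_sigma, x$diagnostics$residual_core)))
  invisible(x)
}

#' @export
print.cycle_state <- function(x, ...) {
  NextMethod()
  if (!is.null(x$promoters)) {
    cat("promoter classes:\n")
    print(x$promoters, n = nrow(x$promoters))
  }
  invisible(x)
}

#' Tidy a titration fit
#'
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @method tidy titration_fit
#' @export
tidy.titration_fit <- function(x, ...) x$estimates

#' One-row summary of a titration fit
#'
#' @param x A `titration_fit`.
#' @param ... Unused.
#' @method glance titration_fit
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, iterations = x$iterations,
         n = nrow(x$data),
         flags = paste(x$flags, collapse = ";"))
}

#' Observed and fitted values of a titration fit
#'
#' @param x A `titration_fit` fitted to single-curve data.
#' @param ... Unused.
#' @return The data with `.fitted` and `.resid` columns appended.
#' @method augment titration_fit
#' @export
augment.titration_fit <- function(x, ...) {
  out <- as_tibble(x$data)
  if (!is.null(x$predict_fn) && !inherits(x, "relative")) {
    fitted <- tryCatch(x$predict_fn(out$x), error = function(e) NULL)
    if (is.numeric(fitted) && length(fitted) == nrow(out)) {
      out$.fitted <- fitted
      out$.resid <- out$y - fitted
    }
  }
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> converged: %s, RSS %.4g, %d iterations\n",
              x$converged, x$rss, x$iterations))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  print(x$estimates)
  invisible(x)
}
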