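# JSON scenario configuration and batch dispatch. A config bundles the
# cell context, the core pool, the species and promoter tables, the model
# level and optional scan/onset/response directives, so a whole scenario
# is reproducible from one file (and drives the command-line interface).

#' Load and validate a scenario configuration
#'
#' Reads a JSON scenario file, applies defaults for omitted fields (cell
#' volume 1.32 fL, 200 promoters per class, 55 nt/s elongation, ...),
#' normalizes units and checks cross-references. All schema violations
#' are reported together in a single error.
#'
#' Totals (`species[].total`, `core.total`) are copy numbers per cell
#' unless `units.totals` is `"molar"`; dissociation constants and
#' Michaelis constants are always molar.
#'
#' @param path Path to a JSON file.
#' @return A list of class `scenario_config` with elements `context`,
#'   `core`, `species`, `promoters`, `ns`, `level`, the optional
#'   directives, and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  units <- raw$units$totals %||% "counts"
  if (!units %in% c("counts", "molar")) {
    note(sprintf("units.totals: unknown unit '%s' (counts|molar).", units))
  }
  ctx_in <- raw$context %||% list()
  context <- tryCatch(
    cell_context(
      volume = ctx_in$volume_fl %||% 1.32,
      ns_sites = ctx_in$ns_sites %||% (GENOME_EQUIVALENTS * GENOME_BP),
      unit_mode = if (identical(units, "molar")) "molar" else "counts"
    ),
    error = function(e) { note(paste("context:", conditionMessage(e))); NULL }
  )

  if (is.null(raw$core$total)) note("core.total is required.")
  if (is.null(raw$species) || NROW(raw$species) == 0) {
    note("species: at least one species is required.")
  }
  species <- NULL
  if (!is.null(raw$species) && NROW(raw$species) > 0) {
    sp <- as_tibble(as.data.frame(raw$species, stringsAsFactors = FALSE))
    species <- tryCatch(as_species_table(sp), error = function(e) {
      note(paste("species:", conditionMessage(e))); NULL
    })
  }

  promoters <- NULL
  if (!is.null(raw$promoters) && NROW(raw$promoters) > 0) {
    pr <- as.data.frame(raw$promoters, stringsAsFactors = FALSE)
    defaults <- list(count = 200, km = 1e-9, kmax = 40 / 60,
                     operon_length = 2000, retention_length = 300,
                     elongation_speed = 55,
                     release_mode = "separate_release")
    for (col in names(defaults)) {
      if (!col %in% names(pr)) pr[[col]] <- defaults[[col]]
      pr[[col]][is.na(pr[[col]])] <- defaults[[col]]
    }
    if (!is.null(species)) {
      promoters <- tryCatch(as_promoter_table(pr, species$name),
                            error = function(e) {
                              note(paste("promoters:", conditionMessage(e)))
                              NULL
                            })
      # repressor labels must resolve against the species table
      if (!is.null(promoters)) {
        for (i in seq_len(nrow(promoters))) {
          for (r in promoters$repressors[[i]] %||% list()) {
            if (!r$species %in% species$name) {
              note(sprintf("promoters[%d]: repressor species '%s' unknown.",
                           i, r$species))
            }
          }
        }
      }
    }
  }

  level <- raw$level %||% "free"
  if (!level %in% c("free", "ns", "cycle")) {
    note(sprintf("level: '%s' is not one of free|ns|cycle.", level))
  }
  if (identical(level, "cycle") && is.null(promoters)) {
    note("level 'cycle' requires a promoters table.")
  }
  ns <- NULL
  if (!is.null(raw$ns) || identical(level, "ns")) {
    ns <- tryCatch(ns_params(kd_ns_core = raw$ns$kd_ns_core %||% 1e-4),
                   error = function(e) {
                     note(paste("ns:", conditionMessage(e))); NULL
                   })
  }
  for (d in c("scan", "onset", "response")) {
    dir <- raw[[d]]
    if (!is.null(dir) && is.null(dir$control)) {
      note(sprintf("%s: `control` is required.", d))
    }
  }

  if (length(errors)) {
    abort(paste0("invalid scenario config:\n  - ",
                 paste(errors, collapse = "\n  - ")))
  }
  structure(
    list(context = context,
         core = list(total = raw$core$total,
                     kd_ns_core = raw$core$kd_ns_core %||% 1e-4),
         species = species, promoters = promoters, ns = ns, level = level,
         scan = raw$scan, onset = raw$onset, response = raw$response,
         seed = raw$seed %||% 1L, path = path),
    class = "scenario_config"
  )
}

directive_grid <- function(dir) {
  if (!is.null(dir$grid)) return(as.numeric(dir$grid))
  n <- dir$n %||% 200
  if (isTRUE(dir$log %||% TRUE) && (dir$from %||% 1) > 0) {
    exp(seq(log(dir$from), log(dir$to), length.out = n))
  } else {
    seq(dir$from, dir$to, length.out = n)
  }
}

#' Run a scenario and write its artifacts
#'
#' Dispatches a loaded configuration to the requested solver or analysis
#' and writes tidy CSV plus a JSON summary into `outdir`. Deterministic:
#' rerunning the same config reproduces the same files.
#'
#' @param config A `scenario_config` from [load_config()] (or a path).
#' @param command One of `"solve"`, `"scan"`, `"onset"`, `"response"`,
#'   `"cycle"`, `"stringent"`.
#' @param outdir Output directory, created if needed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed result and the files
#'   written.
#' @export
run_scenario <- function(config, command = c("solve", "scan", "onset",
                                             "response", "cycle",
                                             "stringent"),
                         outdir = ".", quiet = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config or a path to one.")
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character()
  out_csv <- function(df, name) {
    f <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  out_json <- function(x, name) {
    f <- file.path(outdir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, f)
  }

  result <- switch(command,
    solve = , cycle = {
      level <- if (command == "cycle") "cycle" else config$level
      st <- solve_level(config$species, config$core$total, level,
                        config$promoters, config$ns, config$context)
      out_csv(tidy(st, long = TRUE), "state_pools")
      out_json(c(as.list(glance(st)),
                 list(level = level, config = config$path)), "state_summary")
      if (inherits(st, "cycle_state") && !is.null(st$promoters)) {
        out_csv(st$promoters, "promoter_fluxes")
      }
      say("solved %s-level state: free core %.4g", level, st$free_core)
      st
    },
    scan = {
      dir <- config$scan %||% abort("config has no `scan` directive.")
      sc <- competition_scan(config$species, config$core$total,
                             control = dir$control,
                             grid = directive_grid(dir),
                             level = config$level,
                             promoters = config$promoters, ns = config$ns,
                             context = config$context)
      out_csv(sc, "scan")
      say("scan over %s: %d points", dir$control, length(unique(sc$control)))
      sc
    },
    onset = {
      dir <- config$onset %||% abort("config has no `onset` directive.")
      on <- competition_onset(config$species, config$core$total,
                              control = dir$control,
                              reference_value = dir$reference_value %||% 0,
                              threshold = dir$threshold %||% 0.05,
                              level = config$level,
                              promoters = config$promoters, ns = config$ns,
                              grid = if (!is.null(dir$from)) {
                                directive_grid(dir)
                              } else NULL,
                              context = config$context,
                              observe = dir$observe)
      out_json(as.list(on), "onset")
      say("competition onset at %s = %.6g", dir$control, on$onset)
      on
    },
    response = {
      dir <- config$response %||% abort("config has no `response` directive.")
      if (is.null(config$promoters)) abort("response requires promoters.")
      idx <- if (!is.null(dir$promoter)) {
        which(config$promoters$name == dir$promoter)
      } else 1L
      if (!length(idx)) abort(sprintf("unknown promoter '%s'.", dir$promoter))
      grid <- directive_grid(dir)
      mr <- max_response(config$species, config$core$total,
                         control = dir$control, grid = grid,
                         promoter = config$promoters[idx[1], ],
                         level = config$level,
                         promoters = config$promoters, ns = config$ns,
                         context = config$context)
      out_json(as.list(mr), "response")
      say("max response %.4g at %s = %.6g", mr$r_max, dir$control,
          mr$x_at_max)
      mr
    },
    stringent = {
      sp <- stringent_preset()
      before <- solve_free_binding(sp$species, sp$available_before,
                                   context = sp$context)
      after <- solve_free_binding(sp$species, sp$available_after,
                                  context = sp$context)
      report <- list(
        available_before = sp$available_before,
        available_after = sp$available_after,
        holo_before = setNames(as.list(before$pools$total_holo),
                               before$pools$species),
        holo_after = setNames(as.list(after$pools$total_holo),
                              after$pools$species)
      )
      out_json(report, "stringent")
      say("stringent preset: available cores %d -> %d",
          sp$available_before, sp$available_after)
      report
    }
  )
  invisible(list(result = result, files = files))
}
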