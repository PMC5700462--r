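#' Read a pipeline run configuration
#'
#' A run configuration is a YAML (or JSON) document with fields:
#' \describe{
#'   \item{mode}{`"simulate"` or `"load"`.}
#'   \item{alleles}{Named map. In simulate mode each entry may be empty (the
#'     name is looked up among the built-in [allele_models()]), or give
#'     `model:` (a path to a [read_kinetic_model()] file) and optional
#'     `n_exits`/`render`. In load mode each entry gives `trace:` (a trace
#'     TSV, idealized on the fly) or `path:` (an already-idealized state-path
#'     TSV).}
#'   \item{seed}{Integer; per-allele seeds are derived by offset.}
#'   \item{n_exits}{Default number of sojourns to simulate per allele.}
#'   \item{render}{Render traces and re-idealize them (simulate mode), rather
#'     than analysing the simulated path directly. Slower; exercises the full
#'     chain.}
#'   \item{thresholds}{Optional `k_max`, `min_dwell_samples`, `n_min`.}
#'   \item{melting}{Optional: `t_m`/`slope`/`noise_sd` to simulate, or
#'     `file:` to load a melting TSV.}
#' }
#'
#' @param path Path to the YAML/JSON configuration.
#' @return The validated configuration list (class `run_config`).
#' @seealso [run_pipeline()]
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) {
    abort("configuration must be a list.", class = "hairpinkinetics_parameter_error")
  }
  cfg$mode <- cfg$mode %||% "simulate"
  if (!cfg$mode %in% c("simulate", "load")) {
    abort('`mode` must be "simulate" or "load".',
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (is.null(cfg$alleles) || length(cfg$alleles) == 0 ||
    is.null(names(cfg$alleles))) {
    abort("`alleles` must be a named map.", class = "hairpinkinetics_parameter_error")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_exits <- cfg$n_exits %||% 2000
  cfg$render <- isTRUE(cfg$render)
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    k_max = th$k_max %||% 3,
    min_dwell_samples = th$min_dwell_samples %||% 2,
    n_min = th$n_min %||% 10
  )
  if (cfg$mode == "load") {
    for (nm in names(cfg$alleles)) {
      spec <- cfg$alleles[[nm]]
      f <- spec$trace %||% spec$path
      if (is.null(f) || !file.exists(f)) {
        abort(sprintf("allele '%s': trace/path file missing or nonexistent.", nm),
          class = "hairpinkinetics_parameter_error"
        )
      }
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

resolve_allele_model <- function(name, spec, builtin) {
  if (!is.null(spec$model)) {
    if (is.character(spec$model)) {
      return(read_kinetic_model(spec$model))
    }
    if (inherits(spec$model, "kinetic_model")) {
      return(spec$model)
    }
    abort(sprintf("allele '%s': `model` must be a file path or kinetic_model.", name),
      class = "hairpinkinetics_parameter_error"
    )
  }
  if (name %in% names(builtin)) {
    return(builtin[[name]])
  }
  abort(sprintf("allele '%s': no model given and not a built-in allele.", name),
    class = "hairpinkinetics_parameter_error"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain for every configured allele -- simulate (or
#' load) a recording, idealize it if needed, extract dwells, estimate the
#' transition-probability/lifetime matrix and occupancy -- then calls each
#' observed occupancy profile against the reference profiles, ranks alleles
#' by duplex stability, and optionally fits a melting curve. All intermediate
#' tables are written under `out_dir` as TSV/JSON, plus a combined
#' `report.json`. Deterministic for a fixed `seed`.
#'
#' @param config A `run_config` (see [read_run_config()]), a path to one, or a
#'   plain list with the same fields.
#' @param out_dir Output directory (created if missing). `NULL` skips writing.
#' @param references Reference occupancy profiles for [call_allele()].
#' @param strict Abort (after writing partial outputs) if any stage failed;
#'   when `FALSE`, failures are recorded in the returned `errors` field.
#' @return Invisibly, a `pipeline_report` list: `occupancy` (long tibble),
#'   `kinetics` (bound kinetic matrices), `calls`, `stability`, `melting`
#'   (or `NULL`), `errors`.
#' @examples
#' \donttest{
#' cfg <- list(
#'   mode = "simulate", seed = 7, n_exits = 500,
#'   alleles = list(`WT-C` = list(), `MT-T` = list())
#' )
#' rep <- run_pipeline(cfg, out_dir = tempfile("run"))
#' rep$stability
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         references = reference_occupancy(), strict = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  builtin <- if (config$mode == "simulate") allele_models() else list()
  th <- config$thresholds

  errors <- list()
  per_allele <- list()
  for (i in seq_along(config$alleles)) {
    nm <- names(config$alleles)[i]
    spec <- config$alleles[[nm]]
    res <- tryCatch(
      {
        seed_i <- config$seed + 13L * i
        if (config$mode == "simulate") {
          model <- resolve_allele_model(nm, spec, builtin)
          n_exits <- spec$n_exits %||% config$n_exits
          path <- simulate_state_path(model, n_exits, seed = seed_i)
          if (isTRUE(spec$render %||% config$render)) {
            trace <- render_trace(path, model, seed = seed_i + 1L)
            fit <- fit_amplitude_histogram(trace, k_max = th$k_max)
            path <- idealize_trace(trace, fit,
              min_dwell_samples = th$min_dwell_samples
            )
          }
        } else {
          if (!is.null(spec$path)) {
            path <- read_state_path_tsv(spec$path)
          } else {
            trace <- read_trace_tsv(spec$trace)
            fit <- fit_amplitude_histogram(trace, k_max = th$k_max)
            path <- idealize_trace(trace, fit,
              min_dwell_samples = th$min_dwell_samples
            )
          }
        }
        dwells <- extract_dwells(path)
        ksum <- kinetic_summary(dwells, n_min = th$n_min, seed = seed_i + 2L)
        occ <- occupancy(path)
        if (!is.null(out_dir)) {
          d <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", nm))
          dir.create(d, showWarnings = FALSE)
          write_state_path_tsv(path, file.path(d, "state_path.tsv"))
          write_dwells_tsv(dwells, file.path(d, "dwells.tsv"))
          readr::write_tsv(as_tibble(ksum), file.path(d, "kinetic_matrix.tsv"))
          readr::write_tsv(as_tibble(occ), file.path(d, "occupancy.tsv"))
        }
        list(path = path, dwells = dwells, kinetics = ksum, occupancy = occ)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
    } else {
      per_allele[[nm]] <- res
    }
  }

  occ_long <- purrr::map_dfr(per_allele,
    function(r) as_tibble(r$occupancy),
    .id = "allele"
  )
  kin_long <- purrr::map_dfr(per_allele,
    function(r) as_tibble(r$kinetics),
    .id = "allele"
  )
  calls <- purrr::map(per_allele, function(r) {
    tryCatch(call_allele(r$occupancy, references = references),
      error = function(e) NULL
    )
  })
  stability <- tryCatch(
    rank_stability(purrr::map(per_allele, "kinetics")),
    error = function(e) {
      errors[["stability"]] <<- conditionMessage(e)
      NULL
    }
  )

  melting <- NULL
  if (!is.null(config$melting)) {
    melting <- tryCatch(
      {
        mc <- config$melting
        curve <- if (!is.null(mc$file)) {
          read_melting_tsv(mc$file)
        } else {
          simulate_melting_curve(
            t_m = mc$t_m, slope = mc$slope %||% 2.5,
            noise_sd = mc$noise_sd %||% 0.02,
            seed = config$seed + 997L
          )
        }
        fit_melting_curve(curve)
      },
      error = function(e) {
        errors[["melting"]] <<- conditionMessage(e)
        NULL
      }
    )
  }

  report <- structure(
    list(
      occupancy = occ_long,
      kinetics = kin_long,
      calls = calls,
      stability = stability,
      melting = melting,
      errors = errors,
      config = unclass(config)
    ),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    readr::write_tsv(occ_long, file.path(out_dir, "occupancy_summary.tsv"))
    readr::write_tsv(kin_long, file.path(out_dir, "kinetics_summary.tsv"))
    json <- list(
      occupancy = occ_long,
      kinetics = kin_long,
      calls = purrr::map(calls, function(cl) {
        if (is.null(cl)) NULL else list(call = cl$call, tie = cl$tie, distances = cl$distances)
      }),
      stability = stability,
      melting = if (!is.null(melting)) tidy(melting) else NULL,
      errors = errors
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
  }

  if (strict && length(errors) > 0) {
    abort(
      paste0(
        "pipeline finished with errors (partial outputs retained): ",
        paste(names(errors), collapse = ", ")
      ),
      class = "hairpinkinetics_pipeline_error"
    )
  }
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", length(unique(x$occupancy$allele)), "allele(s)\n")
  if (nrow(x$occupancy)) {
    wide <- tidyr::pivot_wider(x$occupancy,
      names_from = "state", values_from = "percent"
    )
    print(mutate(wide, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1))))
  }
  if (!is.null(x$stability)) {
    cat("stability ranking (by low-state lifetime):\n")
    print(x$stability)
  }
  for (nm in names(x$calls)) {
    cl <- x$calls[[nm]]
    if (!is.null(cl)) cat(sprintf("  %s -> called %s\n", nm, cl$call))
  }
  if (!is.null(x$melting)) {
    cat(sprintf("melting fit: t_m = %.2f C\n", x$melting$t_m))
  }
  if (length(x$errors)) {
    cat("errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
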