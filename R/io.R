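#' Read and write the package's delimited text formats
#'
#' Traces are 2-column TSV (`time_ms`, `current_nA`); state paths are
#' 3-column TSV (`state`, `start_ms`, `duration_ms`); dwell tables are
#' 3-column TSV (`state`, `duration_ms`, `next_state`); melting curves are
#' 2-column TSV with headers `temp_C` and `abs_norm`.
#'
#' @param x The tibble to write.
#' @param path File path.
#' @return Readers return tibbles in the package's internal column naming;
#'   writers return `x` invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace_tsv <- function(x, path) {
  stopifnot(all(c("time_ms", "current_nA") %in% names(x)))
  readr::write_tsv(x[c("time_ms", "current_nA")], path)
  invisible(x)
}

#' @rdname trace_io
#' @export
read_trace_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      time_ms = readr::col_double(),
      current_nA = readr::col_double()
    )
  )
}

#' @rdname trace_io
#' @export
write_state_path_tsv <- function(x, path) {
  stopifnot(all(c("state", "start_ms", "duration_ms") %in% names(x)))
  readr::write_tsv(x[c("state", "start_ms", "duration_ms")], path)
  invisible(x)
}

#' @rdname trace_io
#' @export
read_state_path_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      state = readr::col_character(),
      start_ms = readr::col_double(),
      duration_ms = readr::col_double()
    )
  )
}

#' @rdname trace_io
#' @export
write_dwells_tsv <- function(x, path) {
  stopifnot(all(c("state", "duration_ms", "next_state") %in% names(x)))
  readr::write_tsv(x[c("state", "duration_ms", "next_state")], path)
  invisible(x)
}

#' @rdname trace_io
#' @export
read_dwells_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      state = readr::col_character(),
      duration_ms = readr::col_double(),
      next_state = readr::col_character()
    )
  )
}

#' @rdname trace_io
#' @export
write_melting_tsv <- function(x, path) {
  stopifnot(all(c("temp_c", "absorbance") %in% names(x)))
  readr::write_tsv(
    tibble(temp_C = x$temp_c, abs_norm = x$absorbance),
    path
  )
  invisible(x)
}

#' @rdname trace_io
#' @export
read_melting_tsv <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      temp_C = readr::col_double(),
      abs_norm = readr::col_double()
    )
  )
  tibble(temp_c = df$temp_C, absorbance = df$abs_norm)
}

#' Read or write a kinetic model as a YAML/JSON config
#'
#' The on-disk layout mirrors the [kinetic_model()] fields: `states`,
#' `levels_nA`, `P` and `tau_ms` as row-major nested lists, and the scalar
#' noise/sampling settings. Format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param model A [kinetic_model()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_kinetic_model()` returns a [kinetic_model()];
#'   `write_kinetic_model()` returns `model` invisibly.
#' @export
write_kinetic_model <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  payload <- list(
    states = model$states,
    levels_nA = unname(model$levels),
    P = apply(model$P, 1, as.list, simplify = FALSE),
    tau_ms = apply(model$tau, 1, as.list, simplify = FALSE),
    noise_sd = model$noise_sd,
    pink_amplitude = model$pink_amplitude,
    sample_rate = model$sample_rate,
    filter_cutoff = model$filter_cutoff
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    abort("unsupported model file extension (use .yaml/.yml/.json).",
      class = "hairpinkinetics_parameter_error"
    )
  }
  invisible(model)
}

#' @rdname write_kinetic_model
#' @export
read_kinetic_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  payload <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("unsupported model file extension (use .yaml/.yml/.json).",
      class = "hairpinkinetics_parameter_error"
    )
  }
  to_matrix <- function(rows, k) {
    m <- do.call(rbind, lapply(rows, function(r) {
      vapply(r, function(v) {
        if (is.null(v) || length(v) != 1 || (is.character(v) && !nzchar(v))) {
          return(NA_real_)
        }
        suppressWarnings(as.numeric(v)) # non-numeric placeholders read as NA
      }, numeric(1))
    }))
    stopifnot(nrow(m) == k, ncol(m) == k)
    m
  }
  k <- length(payload$states)
  kinetic_model(
    levels = as.numeric(payload$levels_nA),
    P = {
      P <- to_matrix(payload$P, k)
      P[is.na(P)] <- 0
      P
    },
    tau = to_matrix(payload$tau_ms, k),
    states = as.character(payload$states),
    noise_sd = payload$noise_sd %||% 0.5,
    pink_amplitude = payload$pink_amplitude %||% 0,
    sample_rate = payload$sample_rate %||% 28.8,
    filter_cutoff = payload$filter_cutoff %||% 5
  )
}
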