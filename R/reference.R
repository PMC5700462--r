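#' Published reference values for the four target alleles
#'
#' The package ships a literature-derived fixture
#' (`inst/extdata/allele_reference.json`) with the published summary
#' statistics for hairpin-DNA hybridization with the fully complementary
#' target (WT-C) and the three single-base mismatched targets (MT-A, MT-G,
#' MT-T): destination-resolved transition probabilities and mean lifetimes,
#' per-device state occupancies from five representative recordings, their
#' printed averages, representative device current levels, and the hairpin /
#' duplex melting temperatures. These values are published numbers, not
#' measurements made by this package; they serve as generative parameters for
#' simulation and as reference profiles for allele calling.
#'
#' @return `allele_reference()` returns the parsed fixture as a list.
#' @examples
#' names(allele_models())
#' reference_occupancy()
#' @export
allele_reference <- function() {
  path <- system.file("extdata", "allele_reference.json",
    package = "hairpinkinetics", mustWork = TRUE
  )
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname allele_reference
#' @return `allele_models()` returns a named list of [kinetic_model()]
#'   objects, one per allele, parameterized by the published transition
#'   probabilities, mean lifetimes and representative current levels.
#' @param ... Passed to [kinetic_model()] to override noise or sampling
#'   defaults (e.g. `noise_sd`, `sample_rate`).
#' @export
allele_models <- function(...) {
  ref <- allele_reference()
  lapply(ref$kinetics, function(entry) {
    P <- as.matrix(entry$P)
    tau <- as.matrix(entry$tau_ms)
    kinetic_model(
      levels = entry$levels_nA, P = P, tau = tau,
      states = ref$states, ...
    )
  })
}

#' @rdname allele_reference
#' @return `reference_occupancy()` returns a tibble of the published
#'   across-device average occupancy profiles, with columns `allele`, `state`,
#'   `mean_percent`, `sd_percent` and `n_devices`, suitable as the reference
#'   map of [call_allele()].
#' @export
reference_occupancy <- function() {
  ref <- allele_reference()
  purrr::map_dfr(names(ref$occupancy_avg), function(al) {
    tibble(
      allele = al,
      state = ref$states,
      mean_percent = ref$occupancy_avg[[al]]$mean,
      sd_percent = ref$occupancy_avg[[al]]$sd,
      n_devices = 5L
    )
  })
}

#' @rdname allele_reference
#' @return `device_occupancy()` returns the per-device occupancy percentages
#'   behind the published averages as a long tibble with columns `allele`,
#'   `device`, `state` and `percent`.
#' @export
device_occupancy <- function() {
  ref <- allele_reference()
  purrr::map_dfr(names(ref$occupancy_devices), function(al) {
    dev <- ref$occupancy_devices[[al]]
    purrr::map_dfr(ref$states, function(s) {
      tibble(
        allele = al,
        device = seq_along(dev[[s]]),
        state = s,
        percent = dev[[s]]
      )
    })
  }) %>%
    arrange(.data$allele, .data$device)
}
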