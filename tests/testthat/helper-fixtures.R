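# Expensive simulations shared across test files, computed once per session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

wtc_path_20k <- function() {
  fixture(
    "wtc20k",
    simulate_state_path(allele_models()[["WT-C"]], 20000, seed = 101)
  )
}

wtc_path_50k <- function() {
  fixture(
    "wtc50k",
    simulate_state_path(allele_models()[["WT-C"]], 50000, seed = 202)
  )
}

allele_summaries_5k <- function() {
  fixture("allele_ksum_5k", {
    models <- allele_models()
    lapply(seq_along(models), function(i) {
      path <- simulate_state_path(models[[i]], 5000, seed = 300 + i)
      kinetic_summary(extract_dwells(path), n_boot = 50, seed = 400 + i)
    }) |> setNames(names(models))
  })
}
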