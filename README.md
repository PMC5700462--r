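# hairpinkinetics

Simulation and analysis of single-molecule conductance recordings from
hairpin-DNA-decorated nanowire field-effect biosensors, for SNP allele
discrimination.

A surface-tethered hairpin probe interconverts between three conformations
when target DNA is present — probe–target **duplex** (low conductance),
folded **hairpin** (intermediate, the 0 nA baseline) and unfolded **single
strand** (high) — and the recording ΔI_D(t) is a noisy three-level
telegraph signal. A fully complementary target stabilizes the duplex; a
single mismatched base collapses duplex occupancy by an order of magnitude
and reshuffles lifetimes and unwinding probabilities. This package turns
those observations into a reproducible pipeline for anyone analysing (or
simulating) such recordings: single-molecule biophysicists working with
FET/nanopore-style telegraph signals and anyone who needs a tested
three-state dwell-time analysis.

## The model

States hop as a **semi-Markov process**: from state *i* the destination *j*
is drawn with exit probability `P[i,j]`, and the sojourn duration is
exponential with a destination-resolved mean `τ[i,j]` (ms). This reproduces
destination-dependent lifetimes that a plain CTMC cannot. Long-run occupancy
has the closed form

    occupancy_i = π_i · τ̄_i / Σ_k π_k · τ̄_k ,   τ̄_i = Σ_j P[i,j] τ[i,j]

with π the stationary distribution of the embedded exit chain. Analysis of a
recording proceeds: Gaussian-mixture amplitude-histogram fit with BIC model
selection (k = 1–3 levels) → HMM (Baum–Welch + Viterbi) idealization into
dwells → direction-resolved exponential lifetime fits `τ̂` and transition
probabilities `P̂` → time-weighted occupancies → nearest-reference allele
call on the occupancy profile. A two-state sigmoid module fits melting
curves (Tm) for the thermodynamic side of the story.

## Worked example

```r
library(hairpinkinetics)
library(dplyr)

m <- allele_models()[["WT-C"]]               # published parameters, complementary target
path <- simulate_state_path(m, n_exits = 20000, seed = 1)

occupancy(path)
#> # A tibble: 3 × 2
#>   state        percent
#>   <chr>          <dbl>
#> 1 low            87.5
#> 2 intermediate   11.4
#> 3 high            1.16

kinetic_summary(extract_dwells(path), seed = 2)
#> # A tibble: 6 × 7
#>   state        next_state   n_dwells p_hat tau_ms tau_conf_low tau_conf_high
#>   <chr>        <chr>           <int> <dbl>  <dbl>        <dbl>         <dbl>
#> 1 low          intermediate     6511 0.854 18.1         17.7          18.6
#> 2 low          high             1111 0.146 26.0         24.4          27.6
#> 3 intermediate low              7027 0.768  1.69         1.65          1.73
#> 4 intermediate high             2119 0.232  3.40         3.27          3.54
#> 5 high         low               595 0.184  0.845        0.777         0.912
#> 6 high         intermediate    2635 0.816  0.550        0.529         0.570
```

The duplex (low) state dominates (~87% of the time), its exits go to the
hairpin with probability ≈0.85, and the fitted mean lifetime of low→hairpin
sojourns is ≈18.1 ms — recovering the generative values (0.856, 18.45 ms)
within sampling error. Calling the occupancy profile against the bundled
reference profiles picks the complementary target:

```r
call_allele(occupancy(path))
#> <allele_call> WT-C (low state 87.5%)
#> # A tibble: 4 × 3
#>   allele distance ref_low_percent
#>   <chr>     <dbl>           <dbl>
#> 1 WT-C       7.01            78.5
#> 2 MT-G      50.8              8.3
#> 3 MT-A     121.               3.6
#> 4 MT-T     189.               1.6
```

And the melting side:

```r
fit <- fit_melting_curve(simulate_melting_curve(59.6, noise_sd = 0.02, seed = 3))
fit
#> <melting_fit> t_m = 59.40 C, slope = 2.42 C (14 points)
unfolded_fraction(fit, 45)
#> [1] 0.0026
```

A duplex melting near 59.6 °C is almost never unwound at the 45 °C working
temperature — which is why the duplex state dominates for the matched target.

Traces themselves are available too: `render_trace()` samples a dwell path
at 28.8 kSa/s with Gaussian + optional 1/f noise, `fit_amplitude_histogram()`
and `idealize_trace()` take a noisy trace back to dwells, and
`run_pipeline()` drives the whole chain from a YAML config (see
`exec/hairpinkin` for the command-line wrapper). Every result is a tibble or
has `tidy()`/`glance()` methods, and `plot_trace()`, `plot_occupancy()`,
`plot_dwell_histogram()` and the `autoplot()` methods give the standard
figures.

## Package layout

- `R/` — simulation (`simulate_state_path`, `render_trace`,
  `simulate_control_trace`, `simulate_melting_curve`), idealization,
  kinetics, genotyping, melting, I/O and pipeline modules
- `inst/extdata/allele_reference.json` — literature-derived reference
  parameters and occupancy profiles for the four alleles
- `vignettes/hairpin-kinetics.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical details, limitations
- `tests/testthat/` — unit, property and end-to-end acceptance tests
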