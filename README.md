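# hespattern

Stochastic delay modelling and spatiotemporal pattern analysis of HES5
expression in neural progenitors.

Neural progenitors in the embryonic spinal cord express the Notch
effector HES5 in ultradian oscillations (~3.3 h period) generated by
delayed auto-repression. In tissue, neighbouring cells form dynamic
*microclusters* — groups of 3–7 nuclei with correlated, locally
in-phase HES5 levels — arranged periodically (~40 µm ≈ 4 cells) along
the dorsoventral axis and switching between high and low states every
6–8 h. `hespattern` is for quantitative biologists who want to (a)
simulate how such patterns emerge from Notch–Delta lateral inhibition
between stochastic HES5 oscillators, and (b) quantify spatiotemporal
micro-patterns in kymographs and segmented-nucleus data.

## The model

Each cell on a hexagonal lattice follows a chemical-Langevin model of
Hes5 mRNA *m* and protein *p* with transcriptional delay:

```
dm_i = [ α_m · G(p_i(t − τ_H)) · J(p̄_i(t − τ_ND)) − μ_m m_i ] dt + √(α_m G J + μ_m m_i) dW_m
dp_i = [ α_p m_i − μ_p p_i ] dt + √(α_p m_i + μ_p p_i) dW_p
```

with `G(p) = 1 / (1 + (p/P_H)^h)` the auto-repression Hill function and
`J(p̄) = 1 / (1 + (p̄/P_0)^n)` the inter-cellular Hill function of the
mean delayed protein of the six neighbours. The repression threshold
`P_0` is the inverse of coupling strength: `P_0 = 400` freezes an
alternating high–low pattern, `P_0 = 15,000` synchronises the tissue
globally, `P_0 = 21,000` (weak coupling) yields intermittent local
in-phase microclusters, and `P_0 = Inf` decouples the cells.

The analysis side provides Hilbert-phase reconstruction and the
Kuramoto order parameter (KOP), bootstrap-autocorrelation and
Lomb–Scargle spatial periodicity, kymograph band persistence and phase
maps, microcluster detection in segmented-nucleus tables with
randomisation controls and radial-gradient removal, and a
differentiation-probability model driven by protein deficit below the
population mean. Synthetic-data generators emulate all imaging inputs
with recorded ground truth.

## Worked example

```r
library(hespattern)

scp <- single_cell_params()   # shipped defaults: 30/90 min half-lives, ~3.3 h period
lat <- hex_lattice(14, 26)    # 364 cells, dorsoventral extent 260 um
sim <- simulate_hes5(scp, coupling_params(repression_threshold_p0 = 21000),
                     lat, sim_config(t_end = 3000, burn_in = 600, seed = 42))
print(sim)
#> HES5 lattice simulation: 364 cells (14 x 26), 161 frames every 15 min
#>   coupling: P0 = 2.1e+04, seed 42
#>   mean protein 2.609e+04 molecules (CoV 0.08)

sim_kop(sim)
#> Kuramoto order parameter: mean 0.341 over 161 timepoints, N = 364 oscillators

temporal_period(sim)$mean_period_h
#> [1] 3.998604

model_kymograph(sim)
#> Kymograph: 26 D-V bins (10 um/bin, extent 260 um) x 161 frames (15 min/frame, 40.25 h)
#>   origin: row 1 = ventral-most
```

At weak coupling the tissue is partially synchronised (KOP ≈ 0.34,
inside the 0.15–0.4 range measured in live tissue) and the single-cell
period stretches slightly above the uncoupled ~3.3 h. Transient
in-phase microclusters can then be scored against an uncoupled null
with `inphase_microclusters(sim)`, and tissue-style inputs are analysed
with `spatial_autocorr()`, `lomb_scargle_period()`,
`band_persistence()` and `detect_microclusters()` — see the vignette
(`vignettes/hes5-micropatterns.Rmd`) for the full methods account.

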