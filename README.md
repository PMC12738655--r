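# alphacell

Single-cell dosimetry and DNA-damage simulation for targeted alpha therapy
(TαT). `alphacell` answers, for the four clinically prominent alpha emitters
**Ac-225, Ra-223, Pb-212 and At-211**: how much dose does one parent decay
deliver to the cell nucleus as a function of where the radionuclide sits in
the cell, and how much clustered DNA damage does that produce? It is aimed
at radiopharmaceutical and microdosimetry researchers who want a fast,
fully scriptable desk-scale model rather than a full Monte-Carlo
track-structure code.

## Model

* **Cell**: two concentric spheres of unit-density water — cell radius
  10 µm, nucleus radius 5 µm — in a 30 µm bounding water cube. Sources are
  distributed uniformly in one of four compartments: cell membrane layer,
  cytoplasm, nucleus wall layer, nucleus volume.
* **Decay**: full decay chains sampled to stability from a packaged,
  validated branching table (or a discrete alpha-line spectrum with one
  alpha per decay). Every alpha is paired with its daughter recoil,
  E = E<sub>α</sub>·m<sub>α</sub>/m<sub>d</sub>. Ac-225 and Ra-223 emit 4
  alphas per parent decay, Pb-212 and At-211 emit 1.
* **Transport**: straight-track continuous slowing-down (CSDA) using a
  packaged stopping-power table for liquid water, S(5.5 MeV) ≈ 83 keV/µm;
  range inversion gives the residual energy after each geometric segment.
  Short-ranged electrons and recoils deposit locally; gammas escape.
* **Scoring**: absorbed dose to the nucleus per parent decay (cGy), total
  and alpha-only (the alpha-only value is a cellular S-value up to unit
  conversion), nucleus-surface crossings per decay, and — via the
  density-clustering damage scorer (DBSCAN, ε = 3.2 nm ≈ 10 bp,
  5→37.5 eV damage-probability ramp, 16 % DNA volume sampling) — SSB, sDSB
  and cDSB counts per decay with mean ± SD over independent repeats.

## Worked example

One hundred At-211 radionuclides uniformly distributed in the nucleus,
twenty independent repeats (the default experiment size):

```r
library(alphacell)
cfg <- run_config("At-211", "nucleus_volume", n_sources = 100,
                  n_repeats = 20, seed = 1)
run_experiment(cfg)
#> At-211 | nucleus_volume | full_chain | 100 sources x 20 repeats (seed 1)
#>   dose_total  12.42 +/- 0.6211 cGy/decay
#>   dose_alpha  8.406 +/- 0.6436 cGy/decay
#>   hits_total  1 +/- 0 /decay
#>   hits_alpha  1 +/- 0 /decay
#>   alpha dose fraction: 67.7%
```

Each parent decay deposits on average 12.4 cGy in the 5 µm nucleus, of
which 8.4 cGy comes from the alpha itself (the rest from the daughter
recoil and short-range electrons emitted inside the nucleus); At-211's
single alpha crosses the nucleus surface essentially every decay. Moving
the same source to the cell membrane drops the alpha dose to about
1.0 cGy/decay — only ~6.7 % of isotropic directions even intersect the
nucleus (`nucleus_solid_angle_fraction(c(10, 0, 0))` = 0.06699) — which is
why nuclear targeting dominates efficacy. A 4 × 4 sweep over radionuclides
and compartments is one call: `run_grid(n_sources = 100, n_repeats = 20)`.

A thin command-line front end with `run`, `grid`, `damage` and `fixtures`
subcommands is installed at `inst/cli/alphacell.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/alphacell.R", package="alphacell"))')" \
  run --radionuclide At-211 --location cytoplasm --seed 1 --out at211_cyto.tsv
```

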