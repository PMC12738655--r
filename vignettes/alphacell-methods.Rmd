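---
title: "Methods: cellular dosimetry and clustered DNA damage for alpha emitters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellular dosimetry and clustered DNA damage for alpha emitters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphacell)
```

## The problem

Targeted alpha therapy delivers alpha-emitting radionuclides to tumour cells
via carrier molecules. Whether a given radionuclide and subcellular targeting
strategy is effective depends on how much energy its decay products deposit in
the cell nucleus — the radiosensitive target — per parent decay, and on how
that energy converts into clustered DNA lesions. `alphacell` simulates this at
the single-cell scale for the four clinically prominent alpha emitters
Ac-225, Ra-223, Pb-212 and At-211, and scores:

* absorbed dose to the nucleus per parent decay (cGy), total and alpha-only
  (the alpha-only quantity is a cellular S-value);
* the number of particles crossing the nucleus surface per decay ("hits");
* single-strand breaks (SSB), simple double-strand breaks (sDSB) and complex
  double-strand breaks (cDSB) per decay, via density-based clustering of
  ionization events.

## Cell model and source compartments

The cell is two homogeneous concentric spheres of unit-density water: cell
radius 10 um, nucleus radius 5 um, centred in a 30 um water cube whose
boundary terminates particles. Sources (100 per cell by default) are placed
uniformly in one of four compartments: a 0.01 um layer on the outer cell
wall, the cytoplasm volume, a 0.01 um layer on the nucleus wall, or the
nucleus volume. Volume compartments sample the radius by the inverse CDF of
the shell volume; emission directions are isotropic (Marsaglia sampling).

A genuinely open geometric choice: whether the nucleus-wall layer sits just
inside or just outside the nucleus surface. We place it immediately
*outside* ([5.00, 5.01] um), reasoning that a carrier docking at the nuclear
envelope has not internalised; `wall_inside = TRUE` switches the convention.
At these radii the dosimetric difference is a fraction of a percent of the
wall-source dose.

## Decay chains

The packaged decay table covers the four chains to (effective) stability with
branching ratios, alpha line energies and mean beta energies condensed from
standard evaluated nuclear data; minor alpha fine-structure lines are folded
into the dominant lines. Chain sampling walks the branch graph (validated to
be acyclic, with probabilities summing to one) and emits, per branch, its
listed particles plus a recoil nucleus for every alpha
(E = E_alpha * m_alpha / m_daughter, ~100-170 keV). All chain members decay
at the parent's position instantly: uptake, diffusion and decay-time effects
are deliberately out of scope. Every branch path of Ac-225 and Ra-223 emits
exactly 4 alphas; Pb-212 and At-211 emit exactly 1 — this 4:1 yield ratio is
the mechanism behind the radionuclide ordering of nucleus dose.

Long-lived intermediates (Bi-207, half-life ~32 y, in the At-211 chain) are
included by default; `stop_half_life` truncates there if the user prefers to
treat them as effectively stable. Their MeV-scale gammas and conversion
electrons mostly escape the 30 um box either way.

The alternative *discrete-alpha* source model emits one alpha per decay drawn
from the chain's pooled alpha lines, weighted by exact branch-graph
enumeration of per-decay emission frequencies — the classical "alpha-only"
source description used for cross-study comparison.

Beta spectra are not modelled line-by-line: a beta branch carries its mean
energy and a single electron energy is drawn from an exponential with that
mean. This surrogate is adequate because electrons only matter here through a
short-range local-deposit policy (below); neither full Fermi spectra nor
atomic relaxation cascades (Auger line-by-line) are simulated.

## Alpha transport

Alphas travel on straight lines and lose energy by the continuous
slowing-down approximation (CSDA): the packaged electronic stopping-power
table for liquid water (29 log-spaced nodes, 0.05-10 MeV; Bethe-formula
values with I = 75 eV and a 3% shell correction above 2 MeV, empirical
Bragg-peak-region values below; consistent with ICRU-49/ASTAR to a few
percent, e.g. ~83 keV/um at 5.5 MeV) is log-log interpolated onto a dense
grid, integrated once into a cumulative range, and inverted: the energy
after a path `l` is the energy whose range is `R(E0) - l`. Deposits are
scored per traversed region (nucleus, cytoplasm, outside-cell water) until
the alpha stops or leaves the box; energy below the lowest table node
(<50 keV, residual range under a micron) is credited to the current region.

Justification of the two simplifications: multiple-scattering deflection of
4-9 MeV alphas over <=30 um of water is a sub-degree effect, and energy
straggling is symmetric about the CSDA mean, so the dominant variance in
per-decay dose comes from decay and geometry sampling — which the repeat
statistics capture. Transport is therefore deterministic given (origin,
direction, energy), and per-track energy conservation holds to 1e-9
relative by construction.

Non-alpha decay products use a policy rather than transport: electrons whose
CSDA range (packaged ESTAR-consistent table) is below a 1 um cut deposit
locally in the containing region; longer-ranged electrons and all gammas are
dropped as escaping; recoil nuclei deposit locally (their range is far below
a micron), with a `"drop"` option that imitates transport codes whose
track-structure physics cannot ionise with heavy daughter ions. Under this
policy the nucleus receives non-alpha dose only from decays *inside* the
nucleus (recoils plus sub-5.5 keV electrons), which reproduces the observed
pattern: alpha dose fraction ~100% for external sources, ~60-70% for
nucleus-resident sources.

## Ionization events and the clustered-damage scorer

For damage scoring, each nucleus chord deposit is discretised into point
ionization events: a Poisson number with mean `edep / W`, where W = 37.5 eV
is the mean energy per event, positions uniform along the chord with an
isotropic Gaussian lateral spread sigma_r = 3 nm (a compact surrogate for
the sub-clustering-radius track penumbra; DSB yields depend on it, so it is
configurable and reported), and exponential per-event energies rescaled so
their sum equals the deposit exactly. W was chosen equal to the upper
damage-probability knot so that one parameter controls the accepted-break
density; both are configurable.

Damage per event is a piecewise-linear probability: 0 below 5 eV, rising
linearly to 1 at 37.5 eV. Independently, DNA is assumed to occupy 16% of the
nucleus volume, so events are thinned by the product
`damage_probability(E) * 0.16` in one Bernoulli draw (the two filters are
independent, so the order is immaterial). Whether the 16% sampling should
apply to all ionizations or only certain ones is not settled; we apply it to
all events and record the choice. Accepted breaks get strand 1 or 2 with
probability 1/2 — strand assignment is our design choice, in the lineage of
density-clustering damage scorers; `strandless = TRUE` gives the pure
proximity definition for sensitivity analysis.

Breaks are clustered with DBSCAN (radius eps = 3.2 nm, about ten base
pairs; strictly less-than, a measure-zero tie-break choice; `min_points = 2`
so every mutually-close pair is a cluster, singletons are noise). Clustering
runs within one parent decay's events only — lesions from different decays
never co-cluster. Classification: a cluster with breaks on both strands is a
DSB (exactly two breaks: simple; three or more: complex); single-strand
clusters are tandem SSBs, and noise points are SSBs. The sDSB/cDSB size
boundary is forced by the definitions (a simple DSB is both strands broken
at a single site); conservation (breaks = SSBs + sum of DSB cluster sizes)
holds by construction and is asserted in the tests.

## Experiment design, seeding and problem sizes

`run_experiment()` repeats each configuration 20 times with 100 sources per
repeat (the study conditions; both configurable) and reports mean +/- SD over
repeats. Dose per decay divides by *parent* decays, not chain-member decays.
Repeat `r` re-seeds R's generator with child seed
`(1009 * seed + r) mod (2^31 - 1)`, so single repeats can be reproduced in
isolation. Damage scoring is off by default because event generation (tens
of thousands of events per nucleus-crossing alpha) dominates runtime; dose
and hits runs at the full 100 x 20 scale take on the order of ten seconds,
and the test suite and acceptance script use that full scale for dose
quantities while exercising damage scoring at reduced source counts.

## What the synthetic fixtures do and do not show

`make_event_cloud()` builds event clouds with exact, constructed SSB/sDSB/
cDSB ground truth (compact clusters separated by several clustering radii,
explicit strand labels, all energies at the acceptance plateau);
`make_toy_nuclide()` builds tiny chains with exactly enumerable alpha
yields; `make_line_track_events()` exposes the event sampler's Poisson and
conservation properties in isolation. These validate the *contracts* of each
stage — clustering topology, thinning rates, yield bookkeeping — not the
physics of real track structure: fixtures say nothing about whether W,
sigma_r or the straight-track approximation reproduce Geant4-DNA event
statistics, and measured SSB/DSB yields per decay should be read as
scorer-relative, not absolute biology.

## Known limitations

* Condensed-history and track-structure electron transport are not emulated;
  published nucleus doses computed with track-structure physics in the
  nucleus are systematically higher than condensed-history values and are
  outside what a CSDA model can or should be calibrated to.
* The local/drop electron policy zeroes small cross-compartment electron
  contributions (a few percent of nucleus dose for external sources).
* No chemistry, no repair kinetics, no realistic DNA geometry, no
  multi-cell cross-dose, no decay-time or uptake modelling.
* Hits counting is unique-particle (a track crossing the nucleus surface
  counts once, not once per boundary crossing); with the local-deposit
  policy only alphas are transported, so total and alpha hits coincide.
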