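---
title: "Scoring protein hydropathy by water evaporation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein hydropathy by water evaporation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parchr)
```

## The idea

Classical hydropathy scales assign one number per amino-acid *type*. On a
folded protein that is too coarse: a lysine buried in a crevice and a
lysine waving into solvent do not interact with water the same way. The
PARCH scale (Protocol for Assigning a Residue's Character on a
Hydropathy scale) instead scores each residue *site* by how tenaciously
it holds its hydration water while the solvent is heated. The protein is
wrapped in a thin explicit water shell, position-restrained, and the
water is annealed from 300 K to 800 K; residues that interact weakly
with water are stripped early, strong binders keep water to high
temperature. The score combines chemistry (the residue's identity and
neighbors) with nanoscale topography (how much water can reach it at
all), on a 0–10 scale: 0 means the residue rapidly loses water or never
had access to it, 10 means retention on par with the best-retaining free
amino acid.

`parchr` implements everything around the MD engine — system
preparation and engine configuration, per-residue water counting, the
scoring statistic, structure annotation, and cross-water-model
comparison — plus a synthetic evaporation generator so the entire
pipeline can be exercised and validated without running MD.

## The statistic

For residue $i$, let $w_i(t)$ be the number of water molecules whose
oxygen lies within $d_\mathrm{water}$ of any atom of the residue at
sample time $t$ (times $t_0 < t_1 < \dots < t_{T-1}$ on the annealing
schedule's grid).

1. **Monotone envelope.** Transient re-adsorption is discarded by the
   running minimum
   $$\eta_i(t_0) = w_i(t_0), \qquad
     \eta_i(t_k) = \min\{\eta_i(t_{k-1}),\, w_i(t_k)\},$$
   so $\eta_i$ encodes irreversible water loss
   (`monotone_envelope()`).

2. **Autocorrelation.** Retention is measured by the non-centered,
   lag-count-normalized autocorrelation of the envelope under water
   model $M$:
   $$C^M_i(\tau) \;=\;
     \frac{\dfrac{1}{T-\tau}\sum_{t} \eta_i(t)\,\eta_i(t+\tau)}
          {\dfrac{1}{T}\sum_{t} \eta_i(t)^2},
     \qquad \tau = 0,\dots,\tau_{\max}$$
   with $\tau_{\max} = T-1$ by default (`autocorrelation()`). A
   constant series gives $C \equiv 1$; an all-zero series (a residue
   with no access to water) is defined as $C \equiv 0$ and flagged
   degenerate.

3. **Time average.** $\bar{C}^M_i$ is the arithmetic mean of
   $C^M_i(\tau)$ over the computed lags
   (`time_averaged_autocorrelation()`).

4. **Standardization and scaling.** With $\bar{C}^M_\mathrm{ref}$ the
   value of the reference residue — the free zwitterionic amino acid
   with the highest $\bar{C}$, which is lysine in calibration against
   all four supported water models —
   $$\mathrm{PV}^M_i = 10\,\bar{C}^M_i / \bar{C}^M_\mathrm{ref},$$
   clipped to $[0, 10]$ (`parch_value()`, `select_reference()`).

Each of the three formulas lives in exactly one function, so an
alternative estimator (mean-subtracted autocorrelation, a shorter lag
window) is a one-line swap.

### Numerical notes on the estimator

- The lag-count normalization makes $C(0) = 1$ identically, but
  individual lags can exceed 1: because the numerator averages over
  $T-\tau$ terms while the denominator averages over $T$, the pointwise
  bound is $T/(T-\tau)$, and e.g. the envelope $(5, 5, 4)$ gives
  $C(1) \approx 1.023$. We keep the estimator as defined — it is the
  one that reproduces the hand-checkable case $\eta = (2,1) \Rightarrow
  C(1) = 0.8$ — and enforce the published 0–10 contract at the scaling
  step: ratios above 1 are clipped to 10 and the unclipped value is
  retained for diagnostics (`clipped` column, `"unclipped"`
  attribute).
- Lagged products are computed by FFT ($O(T\log T)$); the test suite
  checks them against direct summation to $10^{-10}$.
- The statistic is scale-invariant: multiplying a series by any
  constant leaves $C$, $\bar{C}$ and PV unchanged. Hydropathy is read
  from the *shape* of the decay, not from how much water a residue
  starts with — the initial count carries topography into whether water
  is present at all, not into the score's magnitude.
- Degenerate (never-hydrated) residues score 0 without error, and
  PV $= 0$ exactly when $\bar{C} = 0$.
- Reference ties break by lexicographic three-letter code, making the
  selection deterministic.

### Replicates

Annealing is stochastic, so runs are replicated (five by default).
Averaging happens on the PARCH values: within each replicate, values
are normalized by the reference's retention *in that same replicate*,
then averaged per residue (`parch_score()`, `aggregate_replicates()`).
This keeps the reference at exactly 10 in every replicate — and
therefore exactly 10 after averaging — and yields a per-residue
standard deviation. The alternative (averaging $\bar{C}$ across
replicates before scaling once) is exposed via `aggregate = "cbar"`.

## System preparation

`carve_shell()`, `place_counterions()`, `finalize_box()` and
`emit_annealing_config()` build the annealing system and emit the
engine configuration; the package never runs MD itself.

| parameter | default | meaning |
|---|---|---|
| `d_shell` | 0.415 nm | water-shell thickness; the second hydration shell, located at the second minimum of the backbone C$\alpha$–water-oxygen RDF (`compute_rdf()` reports the first two minima) |
| `d_water` | 0.315 nm | residue–water contact cutoff used for counting, identical across water models |
| `d_ion` | 3 nm | counterion distance from the nearest protein atom |
| `d_b` | 3 nm | margin from the ions to the box boundary |
| box edge | $l = 2(d_\mathrm{max} + d_\mathrm{ion} + d_b)$ | cubic, centered on the protein centroid; $d_\mathrm{max}$ is the maximum distance from the centroid to any atom (`max_radius()`) |
| ramp | 300 → 800 K at 1 K/10 ps | encoded as one linear annealing segment (0 ps, 300 K) → (5000 ps, 800 K), mathematically identical to per-kelvin stepping at that rate |
| sampling | 10 ps | one count per kelvin of heating |
| time step | 2 fs | 0.5 fs selectable; the distribution of scores is insensitive to the choice, at roughly 4× the cost |
| restraints | $10^4$ kJ mol$^{-1}$ nm$^{-2}$, heavy atoms + counterions | stiff enough to keep the structure fixed through the ramp; $10^3$, $5\times10^3$, $2\times10^4$ selectable |
| replicates | 5 | independent annealing runs |

Design choices where the protocol is underdetermined, all configurable
and recorded in the emitted manifest:

- **Shell membership** is oxygen-to-any-protein-atom (hydrogens
  included): the oxygen is the position center of all four water
  models, so one convention serves them all.
- **Clash cutoff** 0.24 nm for solvation (a typical exclusion
  distance).
- **Geometric center**, not center of mass, defines the origin for
  $d_\mathrm{max}$ — it needs no mass table and differs negligibly for
  proteins.
- **Hydrated counterions** are an ion plus an octahedral-like cluster
  of six model waters at 0.28 nm ("hydrated" is otherwise
  unspecified); ions are Na⁺ or Cl⁻ as needed to bring the total
  charge to zero, placed by seeded rejection sampling along random
  directions from the centroid, solved to $d_\mathrm{ion}$ from the
  nearest atom, with ≥ 1 nm mutual separation.
- **$d_\mathrm{ion}$ is measured to the nearest protein atom**, the
  operational reading of "distance from the protein surface".

## Water models

`water_models()` registers the four rigid models the scale is
calibrated against — TIP3P (the CHARMM-modified variant used with
CHARMM36m proteins), TIP4P, TIP4P-Ew and TIP5P — at their published
parameter precision: partial charges, $d_\mathrm{OH} = 0.09572$ nm and
$\theta_\mathrm{HOH} = 104.52°$ shared by all four, virtual-site
geometry ($d_\mathrm{OV}$, and $\theta_\mathrm{VOV} = 109.47°$ for
TIP5P's lone pairs), and oxygen Lennard-Jones parameters. All four are
electrically neutral to $10^{-10}$ e, which the tests assert.

Counting ignores virtual sites for every model: they are massless
charge carriers, and a single convention keeps counts comparable across
models. This is itself one plausible source of cross-model PARCH
differences and is stated in the documentation wherever counts are
produced.

## Counting and the RDF

`count_waters_frame()` counts waters whose oxygen is within
$d_\mathrm{water}$ — *inclusive* boundary, locked by a test with an
exact-boundary pair — of any atom of the residue. A water touching two
residues counts toward both, and waters from ion hydration clusters are
counted like any other. Open-boundary frames use a cell-list neighbor
grid verified against all-pairs brute force on random frames (exact
integer equality); periodic frames use an exact minimum-image search.
Non-amino-acid residues are never scored. `compute_rdf()` is the
standard ideal-gas-normalized pair distribution, used to locate the
shell boundary that motivates `d_shell`; its histogram is tested
against brute-force pair enumeration.

Trajectory input covers DCD and multi-model PDB (plus in-memory frame
lists built with `make_trajectory()`); counts travel as tidy tables or
as a wide TSV interchange format.

## The synthetic evaporation generator

`generate_series()` emulates exactly the statistical structure the
scorer relies on, with three interpretable knobs per residue:

- `w0` — initial water count (topography proxy);
- `affinity` $a$ — chemistry proxy: at sampled temperature $T$ each
  currently bound water survives independently with probability
  $\exp\!\big(-(T - T_\mathrm{start})/(a\,T_\mathrm{scale})\big)$,
  $T_\mathrm{scale} = 100$ K, so decay happens roughly where
  $T - T_\mathrm{start} \sim 100\,a$;
- `p_readsorb` — probability that one previously lost water re-binds
  for a single frame, producing the non-monotone blips the envelope
  must remove (default 0.05).

The default cohort (`default_cohort_specs()`) spans affinities over two
orders of magnitude (0.1–10) across the 20 amino-acid codes, assigned
along a hydrophilic-to-hydrophobic ranking with lysine the strongest
retainer, so reference selection on synthetic data mirrors the
calibration set; initial counts vary smoothly between 10 and 50.

What the generator does *not* emulate: real hydration-shell structure,
cooperative evaporation, neighbor-residue coupling, restraint softening
at high temperature, or any force-field physics. Green tests therefore
demonstrate that the *scorer* is correct and discriminating under the
protocol's assumptions (monotone-after-envelope decay whose speed
encodes affinity), not that the pipeline reproduces MD-derived values
for real proteins — that requires the actual annealing simulations.

Under the study conditions (default schedule, five replicates, fixed
seeds) the Spearman correlation between true affinity and recovered
PARCH value on the two-decade cohort exceeds 0.9, PARCH values are
independent of `w0` scaling across 10–1000, and the reference residue
scores exactly 10.

## Cross-model comparison

`residue_differences()` reports per-site signed differences
$\Delta\mathrm{PV}^M_i = \mathrm{PV}^M_i - \mathrm{PV}^\mathrm{base}_i$
against a baseline model (TIP3P by convention) with per-amino-acid
medians; signed differences, not statistical variances, are what a
"±0.17 median offset" can meaningfully summarize.
`compare_distributions()` tests two PARCH distributions with a
two-sided Mann–Whitney U by default — PARCH values are bounded and
non-normal, and the comparison is between violin-style distributions —
with Welch's *t* as an option, and maps p-values to the star convention
`ns` ($p > 0.05$), `*` ($p \le 0.05$), `**` ($p \le 0.01$), `***`
($p \le 0.001$), boundaries inclusive. No multiple-testing correction
is applied by default (stars are raw-threshold by convention);
Bonferroni is a flag. Residue classes default to charged
{LYS, ARG, ASP, GLU, HIS}, aromatic {PHE, TRP, TYR}, polar
{SER, THR, ASN, GLN, CYS}, nonpolar {the rest}; histidine sits with the
charged class by default and the whole mapping is overridable.

## Problem sizes in the test suite

The suite validates on sizes a laptop handles in seconds: 20-residue
cohorts with five replicates on the full 501-sample grid for pipeline
and recovery tests; 1000 random series for the scale-bound and envelope
oracle checks; 100 random frames of up to 500 waters for counting
oracles; tripeptide fixtures for structure I/O. These sizes give the
oracle comparisons exact or $10^{-10}$-level agreement and leave the
stochastic checks (volume scaling, ideal-gas RDF) comfortable margins.

## Worked example

```{r example}
sched <- annealing_schedule() # 300 -> 800 K, 1 K/10 ps, 5 replicates
cohort <- generate_cohort(schedule = sched, seed = 42)
profile <- parch_score(cohort$counts, model = "tip3p")
glance(profile)
head(dplyr::arrange(tidy(profile), dplyr::desc(pv)))
```

The reference residue (lysine in the default cohort) scores exactly 10;
hydrophilic-ranked residues follow in order, and the most weakly
retaining residues approach the bottom of the scale.

## Known limitations

- The package emits engine configuration but cannot validate it against
  a live MD engine; the mdp round-trip test checks self-consistency
  only.
- XTC/TRR trajectories are not read; convert to DCD or multi-model PDB
  upstream.
- Published per-protein values (transmembrane-domain scores, specific
  loop residues) depend on cluster-scale MD of solvated proteins and
  are out of scope for desk-scale validation.
- mmCIF, structure repair, protonation assignment and hydrogen-bond
  analysis are out of scope.
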