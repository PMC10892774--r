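---
title: "Residue-wise alanine scanning with GB/SA energetics and interaction entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-wise alanine scanning with GB/SA energetics and interaction entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alascan)
```

## The model

`alascan` post-processes a conformational ensemble of a bound
protein–peptide complex (for instance a class I MHC molecule with a 9-mer
antigen) to answer two questions: *which interface residues carry the
binding*, and *how does the binding free energy change when the peptide is
mutated*.

The central quantity is the per-residue mutational difference. For a
residue $x$ truncated to alanine,

$$\Delta\Delta G_{\mathrm{bind}}^{x\to a} \;=\; \Delta G_{\mathrm{bind}}^{a}
  - \Delta G_{\mathrm{bind}}^{x},$$

which is **positive when the wild-type side chain is favorable**. It is
decomposed into van der Waals, electrostatic, polar and nonpolar solvation,
and entropic components; the internal (bonded) term cancels exactly because
both end states are evaluated on the *same* trajectory (single-trajectory
approximation) and is therefore never computed. The binding free energy of
one partner's scan is the negated sum over its scanned residues,

$$\Delta G_{\mathrm{bind}} = -\sum_x \Delta\Delta G_{\mathrm{bind}}^{x\to a},$$

evaluated receptor-side (MHC–AS), ligand-side (Peptide–AS), or as the
arithmetic mean of the two (the averaged scheme). A reduced scheme keeps
only the van der Waals and entropy terms,
$\Delta\Delta G \approx \Delta\Delta E_{\mathrm{vdW}} - T\Delta\Delta S$,
for systems dominated by hydrophobic packing where point-charge
electrostatics and implicit solvation carry the largest model error.

### Energy terms

* **van der Waals** — 12-6 Lennard-Jones with Lorentz–Berthelot combination,
  $\varepsilon_{ij}\left[(r_{\min,ij}/r)^{12} - 2 (r_{\min,ij}/r)^6\right]$.
  Gas-phase binding terms are pairwise additive, so the complex − receptor −
  ligand difference reduces exactly to the inter-partition pair sum; no
  distance cutoff is applied (end-state systems are small, determinism wins
  over speed).
* **Electrostatics** — Coulomb sum $332.0637\,q_iq_j/(\varepsilon r)$ with
  the interior dielectric set by the **class of the mutated residue**:
  1 (nonpolar), 3 (polar), 10 (charged). The class table is explicit and
  overridable (`classify_residue()`); histidine tautomers map to polar,
  doubly protonated HIP to charged.
* **Polar solvation** — generalized Born in the Still pairwise form with
  OBC-style effective radii: Hawkins–Cramer–Truhlar pairwise descreening
  integrals with per-atom screening factors, a 0.09 Å intrinsic-radius
  offset, and the tanh rescaling with $(\alpha,\beta,\gamma) =
  (1.0, 0.8, 4.85)$. The prefactor of the pairwise sum is the conventional
  rounded value 166.03 kcal·Å/(mol·e²); self terms use $f_{GB} = R_i$, so a
  single ion reproduces the Born formula. Salt screening is zero. The class
  dielectric of the scanned residue is used for the interior dielectric of
  both the Coulomb and GB terms of that scan, which keeps the two
  electrostatic pieces mutually consistent.
* **Nonpolar solvation** — $\gamma\,\mathrm{SASA} + \beta$ with defaults
  $\gamma = 0.00542$ kcal/(mol·Å²), $\beta = 0.92$ kcal/mol, probe 1.4 Å.
  SASA is Shrake–Rupley on a deterministic Fibonacci point set (960 points
  per atom by default), with `lj_rmin_half` as the atomic radius. Per-residue
  solvation contributions are **full end-state differences** (the mutant and
  wild-type three-state sums), not a pairwise decomposition: the difference
  definition above is applied literally.
* **Entropy** — the interaction-entropy estimator
  $-T\Delta S = kT\,\ln\langle e^{\beta(E_{\mathrm{int}} -
  \langle E_{\mathrm{int}}\rangle)}\rangle$ with
  $k_B = 0.0019872$ kcal/(mol·K), default $T = 300$ K, evaluated on a
  log-sum-exp path so large fluctuations cannot overflow. By Jensen's
  inequality the estimator is non-negative and is zero only for a constant
  series.

### Per-residue entropy and sign conventions

The residue's interaction-energy series is formed **per frame** as
$E_{\mathrm{int}}^{\mathrm{wt}}(t) - E_{\mathrm{int}}^{\mathrm{mut}}(t)$
(gas-phase electrostatics at the class dielectric plus van der Waals between
the two partners), which isolates the scanned side chain's interaction with
the partner. Its interaction entropy is the entropic penalty attributable to
that side chain, so in the positive-equals-favorable convention the reported
component is $-\mathrm{IE}(\text{differenced series}) \le 0$ — entropy
always *reduces* a residue's favorable contribution, and an
alanine-to-alanine identity scan gives exactly zero. The alternative
resolution, the difference of the two entropies
$\mathrm{IE}(\mathrm{mut}) - \mathrm{IE}(\mathrm{wt})$ computed from the raw
series, is available behind `ie_mode = "series_difference"`. The noise
filter is applied to the differenced series.

All frames feed the entropy series, while the enthalpy components use an
equally spaced subsample (default at most 100 frames) — fluctuation
statistics need the full sampling, means do not.

### The 3σ noise cutoff

Before the exponential average, frames deviating from the series mean by
more than three standard deviations are dropped in a **single,
non-iterated pass** (`sigma_filter()`); the pass reports exactly which
frames were removed. A single pass is deterministic and sufficient: the
exponential average is so outlier-dominated that one spurious frame at
$10\sigma$ inflates the estimate by an order of magnitude, while removal
restores the clean value to within a couple of percent (both properties are
asserted in the test suite).

## The scanning procedure

1. **Interface selection** — receptor residues with any heavy atom within
   5 Å (default) of any ligand heavy atom in a single reference frame
   (default the first; an any-frame mode exists but is off by default, for
   determinism). The ligand side defaults to *all* its residues, the
   convention for short peptides scanned in full. Hydrogens are excluded
   from the distance test because their placement varies across input
   sources.
2. **Truncation** — side-chain atoms beyond CB are removed; three methyl
   hydrogens are appended on CB at 1.09 Å with exact tetrahedral geometry
   (109.47° to the CA–CB axis, 120° apart in azimuth), the first sharing
   the azimuthal plane of the deleted CB→CG bond so the methyl inherits the
   old side chain's orientation. When no CG-like atom exists the N→CA
   direction seeds the azimuth; a fully degenerate seed falls back to a
   fixed coordinate axis. The construction is exact and deterministic —
   re-truncating gives bitwise identical geometry — and is re-derived in
   every frame from that frame's CA/CB/CG positions. Appended hydrogens are
   checked against all retained atoms at a 0.8 Å floor; violations are
   logged, never silently accepted. The residue's charges are replaced by
   the parameter table's alanine template; the net-charge change is not
   neutralized (only interaction differences are consumed downstream).
   Glycine (nothing to truncate) and proline (backbone ring) are skipped
   with a recorded reason and a zero contribution.
3. **Assembly** — `alanine_scan()` returns a tidy contribution table (one
   row per candidate residue); `binding_prediction()` /
   `aggregate_trajectories()` turn one table per trajectory into per-scheme
   means and standard deviations; `correlation_report()` and
   `bootstrap_correlation()` score the predictions against experimental
   affinities, converted from ID50 via $\Delta G_{\exp} = RT\ln
   \mathrm{ID}_{50}$. Hotspots are residues whose mean total contribution
   exceeds 2 kcal/mol. `mmgbsa_enthalpy()` provides the conventional
   whole-interface end-state enthalpy as the non-scanning baseline.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| interface cutoff | 5 | Å | heavy-atom distance for receptor-side selection |
| enthalpy frames | 100 | – | equally spaced subsample for component means |
| temperature | 300 | K | $kT$ in the entropy estimator and ID50 conversion |
| class dielectrics | 1 / 3 / 10 | – | interior dielectric by mutated-residue class |
| solvent dielectric | 78.5 | – | GB exterior |
| $\gamma$, $\beta$ | 0.00542, 0.92 | kcal/(mol·Å²), kcal/mol | nonpolar solvation |
| probe radius | 1.4 | Å | SASA solvent probe |
| SASA points | 960 | – | sphere discretization (≈1% area accuracy) |
| $\sigma$-filter $k$ | 3 | – | entropy noise cutoff |
| hotspot threshold | 2 | kcal/mol | reporting cutoff |
| bootstrap | 10⁴ rounds, percentile 95% CI, pair resampling | – | correlation uncertainty |

Every default is echoed into the provenance header of each output file, so
a run is reproducible from its config and inputs alone.

## What the synthetic generator emulates — and what it does not

`toy_complex_spec()` / `build_toy_complex()` create small two-chain
complexes from idealized residue templates, with *designed* contacts: the
contact tip atoms are placed exactly at their Lennard-Jones pair minimum
with a prescribed well depth, so each contact contributes exactly
$-\varepsilon$ at the reference geometry and the family's designed binding
free energy is the analytic sum of contact minima. Contact depths are
carried by the per-variant parameter table (keyed on residue and atom
name, which is why contact residue types must be unique in a complex), so
every fixture serializes losslessly through the package's own formats and
the whole pipeline can be exercised end-to-end from disk.
`perturbation_ensemble()` adds independent isotropic Gaussian displacements
around the reference frame, and `designed_variant_family()` weakens
contacts by prescribed effect sizes (spanning 4.5 kcal/mol by default,
producing single- and double-contact variants).

These fixtures reproduce the *statistical* structure the post-processor
depends on — fluctuating interaction energies, known contact energetics, a
designed affinity ranking — but not real data: there is no bonded
connectivity between ligand residues (immaterial here, since no bonded term
is ever evaluated), no correlated or anharmonic dynamics, no conformational
change on mutation, and no force-field realism in the synthetic charges.
Passing tests therefore demonstrate that the estimator and its plumbing are
correct and self-consistent, not that any particular force field or
sampling protocol is adequate for a given real system.

## Numerical choices

* Exponential averages always go through log-sum-exp; the naive path is
  asserted equal where it does not overflow.
* The estimator is floored at zero: the empirical Jensen bound guarantees
  non-negativity mathematically, and the floor removes sub-epsilon
  negative round-off.
* Effective Born radii are clamped at 0.1 Å with a warning if the tanh
  rescaling ever produces a non-positive value; distances below 0.1 Å in
  any pair kernel are a hard error (a clash at that range means broken
  input, not physics).
* SASA uses a fixed Fibonacci point set: deterministic, exact for an
  isolated sphere, about 0.3% orientation dependence under rigid rotation
  (translation is exact). Tests assert rotation invariance at 1%.
* Degenerate bootstrap resamples (zero variance) are redrawn and counted;
  Spearman uses average ranks for ties; single-trajectory standard
  deviations are reported as 0 with an explicit flag rather than NA.
* Output tables are written at fixed 4-decimal precision so reruns diff
  cleanly; the only non-reproducible output line is the timestamp.

## Problem sizes used in the checks

The test-suite benchmarks run at desk scale by design: toy complexes of
50–120 atoms, ensembles of 1–25 frames, 10-variant families with 15–20
replicate repetitions, Gaussian series up to $10^5$ frames, bootstrap
calibration with 60-point experiments, 1000 rounds and 500 repetitions.
These sizes were chosen so each property is measured where it is sharp
(e.g. the Gaussian closed form needs $10^5$ samples; percentile bootstrap
coverage is only near-nominal for experiments of dozens of points, which is
why the calibration uses 60).

## Known limitations

* The GB flavor is fixed (OBC-style radii + Still energy, zero salt); no
  Poisson–Boltzmann option.
* Per-residue solvation uses full end-state differences; a pairwise GB
  decomposition would attribute solvation differently and is not provided.
* Only alanine truncation is performed in place; other mutations require
  their own input ensembles.
* The entropy estimator converges slowly for very stiff interactions
  ($\sigma \gtrsim 2$ kcal/mol needs $\gg 10^4$ frames; the relative error
  of the exponential average grows as $e^{(\beta\sigma)^2/2}/\sqrt{N}$).
* The vdW+entropy scheme's entropy series still contains the electrostatic
  part of the interaction energy (that is how the estimator is defined);
  only the enthalpic electrostatic and solvation *sums* are dropped. The
  strictly charge-independent quantity is the pure van der Waals mask
  (`components = "vdw"` in `sum_binding_energy()`), which is the one
  asserted bitwise charge-invariant in the tests.
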