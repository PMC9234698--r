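---
title: "Validating protein structure models against NMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein structure models against NMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmodelcheck)
```

`nmrmodelcheck` asks a simple question of any protein structure model —
an NMR ensemble, a crystal structure, or a predicted model: *how well does
it fit the experimental solution NMR data?* It implements three
model-versus-data metrics in common use for this purpose, together with
seeded synthetic-data generators so that every metric can be exercised,
calibrated, and tested at desk scale without any external data.

This vignette is the package's account of the science: the models behind
each metric, the tunable parameters and their defaults, the numerical
choices made where the conventions leave room, what the synthetic data do
and do not emulate, and the known limitations.

## RPF-DP: scoring models against NOESY peak lists

A NOESY cross peak reports that two protons are close in space (roughly
within 5 Å). A structure model predicts exactly which proton pairs should
be that close. RPF-DP scoring turns this into a recall/precision analysis
between two graphs over *proton groups*:

* **G**, the model network: nodes are proton groups, and an edge joins two
  groups whose *summation distance* — `(Σ d⁻⁶)^(-1/6)` over all member
  atom pairs — is at most `d_noe_max` (default 5 Å). The r⁻⁶ form mirrors
  how NOE intensities of degenerate protons add.
* **G_ANOE**, the ambiguous NOE network: each peak is mapped to *all*
  proton-group pairs whose chemical shifts match both proton dimensions
  within the match tolerance (and the attached heavy-atom shift for 3D
  peaks). Degeneracy makes this assignment one-to-many on purpose.

Proton groups absorb the ambiguity that NOESY cannot resolve: methyls are
single 3-member groups, the two-fold symmetric Tyr/Phe ring protons are
merged, and prochiral methylene pairs and Leu/Val isopropyl methyls are
merged unless a stereospecific assignment is supplied.

A peak is a **true positive** if at least one of its candidate pairs is an
edge of G, and a **false negative** only if none is. **Recall** is the
matched fraction of assignable peaks. **Precision** is the fraction of G's
edges supported by at least one peak, with each edge weighted by
`(d_min/d)⁶` so that long distances near the cutoff — whose NOEs are weak
and often unobserved — barely count; a `"uniform"` mode disables the
weighting so tests need not depend on it. **F** is the harmonic mean.

The **DP score** rescales F between two data-dependent anchors:

* `F_free`, the F-measure a structureless chain would achieve, estimated
  by scoring sampled freely-rotating virtual-bond chains through exactly
  the same path as any model and averaging;
* `F_max`, the best F the data permit, limited by the completeness of the
  peak list: protons 2–4 covalent bonds apart are *always* within 5 Å, so
  the fraction `c` of such pairs actually present in the peak list bounds
  recall, and `F_max = 2c/(1+c)` (the F-measure at recall `c`, precision
  1).

`DP = (F − F_free)/(F_max − F_free)`, capped at 1 but deliberately not
floored: a model that fits the data worse than a random coil earns a
negative DP. For an ensemble we report both `DP_avg` (mean of
per-conformer DPs) and `<DP>` (DP of the network built from
ensemble-averaged distances, averaging r⁻⁶ per atom pair across conformers
before the group summation — the averaging NOE intensities actually
perform). `<DP>` is typically 10–15% above `DP_avg`, and much more for
diverse ensembles whose pooled contacts explain peaks no single conformer
explains.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `d_noe_max` | 5 Å | maximum NOE-detectable distance; can also be calibrated from the data (`calibrate_d_noe_max()`, smallest F-maximizing cutoff among 4.5/5/5.5/6 Å) |
| `tolerance_h` | 0.05 ppm | ¹H shift-match tolerance |
| `tolerance_heavy` | 0.5 ppm | ¹³C/¹⁵N tolerance for 3D peaks |
| `n_free_samples` | 100 | chains sampled for `F_free` |

The tolerances are conventional working values for well-referenced data;
both are configurable and echoed into every report. The `F_free` sample
count of 100 keeps the Monte Carlo standard error of the baseline small
relative to DP differences of interest (~0.01 in F units on a 20-residue
chain); the seed is explicit everywhere, so baselines are bit-reproducible.

### Numerical and design choices

* **Diagonal peaks** (both proton shifts within one ¹H tolerance and a
  single group matching both dimensions) are discarded: they carry no
  distance information.
* **Unassignable peaks** (no candidate pair at all) are excluded from
  recall but counted and reported, so data-referencing problems surface
  without corrupting the score.
* **Precision weighting** uses `w(d) = d⁻⁶` normalized by the largest edge
  weight. The convention in the field is stated only as "weighted by
  interproton distance"; exact parity with other implementations of the
  weighting is therefore not guaranteed, which is why the `"uniform"` mode
  exists and why DP's anchors are computed through the same weighting.
* **Iteration order** is deterministic (groups sorted by residue index and
  group name), so weighted scores are bit-reproducible.
* **`F_max`'s pair enumeration** approximates 2–4-bond proton connectivity
  by heavy-atom attachment rank within each residue (N = 0, CA = 1,
  CB = 2, ...; pairs with rank difference ≤ 2 are expected). This covers
  geminal, vicinal, and amide-to-β pairs without a full bond graph; for
  synthetic data completeness is 1 and the bound is exact.

## RDC Q factors: fitting the alignment tensor

A residual dipolar coupling measured on a partially aligned sample encodes
the orientation of an N–H bond vector relative to the molecular alignment
tensor (Saupe matrix) — a traceless symmetric 3×3 tensor with five
independent elements. Given a model, the unit N–H vectors form the
standard five-column direction-cosine design matrix, and the tensor is the
linear least-squares solution, computed by SVD (minimum norm; a condition
number above 10⁸ is treated as degenerate geometry, e.g. parallel bond
vectors). The tensor is fitted directly in coupling units (Hz), so no
table of gyromagnetic constants is needed; the axial component
`Da = λzz/2` and rhombicity `Rh = (2/3)(λxx − λyy)/λzz` follow from the
eigenvalues ordered `|λzz| ≥ |λyy| ≥ |λxx|`, which makes `Rh ∈ [0, 2/3]`
automatically.

Two quality factors compare observed and back-calculated couplings:

* `Q1 = sqrt( Σ(D_exp − D_calc)² / Σ D_exp² )`
* `Q2 = sqrt( Σ(D_exp − D_calc)² / (N · Da²(4 + 3Rh²)/5) )`

Both are **rms ratios**: the square root is applied, following the
original definitions and the magnitude of Q values reported in practice
(~0.1–0.6). The Q2 denominator is exactly the isotropic second moment
⟨D²⟩ implied by the fitted tensor, which makes Q2 preferable when the
bond vectors sample orientations unevenly — and gives a sharp internal
check: for well-sampled isotropic orientations, Q1/Q2 → 1.

For ensembles, a tensor is fitted independently to each conformer (the
members are alternative models, not a simultaneous average) and Q1/Q2 are
summarized as mean ± standard deviation; the medoid conformer's fit is
reported alongside. Amide protons are placed with ideal planar geometry
(N–H = 1.02 Å on the direction opposed to the bisector of N–CA and
N–C(i−1)) when a model lacks hydrogens — only the N–H direction matters
for these couplings. The fit is unweighted; reported uncertainties are
carried through but unused. N–H vectors are taken from the coordinates
as-is, without renormalizing bond lengths.

## Structure comparison: Kabsch, GDT_TS, medoid

All comparisons are computed over a user-supplied residue selection — the
consensus *well-defined* (converged across the NMR ensemble) and
*reliably predicted* (e.g. pLDDT > 80) residues. The package ships the
ranges used for its reference targets (`well_defined_ranges()`) and offers
`residue_convergence()` as a rough helper, but deliberately does not
reimplement the dedicated range-finding algorithms: ranges are input.

`kabsch_superpose()` computes the optimal proper rotation by SVD with the
determinant sign correction. `gdt_ts()` performs a *single* least-squares
superposition on the selection Cα atoms and then counts residues deviating
by less than 1, 2, 4, and 8 Å; `GDT_TS = (P1+P2+P4+P8)/4`, reported 0–100.
This single-fit convention matches the stated procedure for ensemble
comparisons but can differ slightly from the multi-superposition searches
used by prediction-assessment servers, which maximize each threshold count
independently; our values are therefore conservative (never higher).
Thresholds are strict: a deviation exactly at a cutoff does not count.
Residues lacking a Cα in either structure are dropped from the selection
and the count used is reported.

The **medoid** conformer — minimal mean Cα RMSD to all other members,
ties to the lowest index — represents each ensemble in cross-structure
comparisons. `similarity_matrix()` assembles the publication-style matrix:
GDT_TS above the diagonal, Cα RMSD below, and the within-ensemble spread
(mean Cα RMSD of members to the medoid) on the diagonal.

## What the synthetic data emulate — and what they do not

`make_toy_structure()` builds poly-alanine chains with ideal covalent
geometry (helix φ = −57°, ψ = −47°; extended; or random torsions),
carrying exactly the protons the metrics need (amide H, Hα, β-methyl), and
perturbs conformers with Gaussian coordinate noise to emulate ensemble
spread. `simulate_noesy()` fabricates chemical shifts (unique, spaced
beyond twice the tolerance, in randomized order) and degrades the ideal
peak list with missing peaks, spurious peaks drawn uniformly over the
occupied shift range (so a controllable fraction lands near real
resonances, injecting ambiguity), and shift jitter. `simulate_rdc()`
contracts a configured tensor with the model's N–H vectors and adds
Gaussian noise. `sample_freely_rotating_chain()` draws Cα virtual-bond
chains (3.8 Å bonds, fixed 120° virtual angle, uniform torsions) with a
generic proton set at fixed local-frame offsets.

Defaults (20 residues, 20 conformers, 0.5 Å coordinate noise, 0.01 ppm
jitter, 10% noise and missing peaks, Da = 10 Hz, Rh = 0.3, 1 Hz RDC noise)
were chosen once to resemble a small, rigid, well-behaved NMR target with
good data. Every generator is a pure function of its configuration: the
seed fixes all draws.

What passing tests on these data **do** show: the scoring machinery is
self-consistent (perfect data from a model score R = P = F = 1 and
DP = 1 for that model), correctly normalized (a random-coil model scores
DP ≈ 0; tensors are recovered to machine precision from noiseless RDCs),
and exact where arithmetic is checkable by hand. What they **do not**
show: behavior on real spectra — fabricated shifts have no chemical
realism, peak intensities ignore relaxation and spin diffusion, the toy
chains have no side-chain diversity, and conformational exchange (the
regime where `<DP>` and `DP_avg` diverge most informatively on real
proteins) is only caricatured by Gaussian coordinate noise.

## Degenerate inputs and edge cases

* Empty peak list → recall is undefined → error. A model network with no
  edges → precision defined as 1, with a warning.
* Fewer than 5 usable RDC records, or rank-deficient bond-vector geometry
  → error.
* `F_free ≥ F_max` (pathological data) → DP is undefined → error rather
  than a silent clamp.
* Proline and chain-initial residues receive no amide proton; residues
  with missing backbone atoms are skipped with a warning.
* Alternate locations other than 'A'/blank are dropped on reading;
  a single chain (the first, unless specified) is scored.

## Known limitations

* The precision weighting function and the completeness bound are this
  package's documented instantiations of conventions that are stated only
  loosely in the literature; scores are internally consistent but not
  guaranteed to match other RPF implementations digit-for-digit.
* GDT_TS uses one global superposition, not the per-threshold search of
  assessment servers.
* Only one-bond ¹⁵N-¹H RDCs are supported; the coil baseline is a coarse
  virtual-bond model, adequate for an F-measure baseline but not a
  physical ensemble.
* Scores are computed for the problem sizes the generators default to
  (tens of residues, tens of conformers) in well under a minute; all
  simulation sizes used by the tests and the acceptance script are stated
  in their configurations.
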