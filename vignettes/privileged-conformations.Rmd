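---
title: "Privileged-conformation occupancy analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privileged-conformation occupancy analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privconf)
```

# The problem

Strigolactone (SL) receptors of the D14/HTL/KAI2 family are
α/β-hydrolases whose Ser–His–Asp catalytic triad both perceives and
cleaves the hormone's butenolide D-ring.  For ShHTL7, the *Striga
hermonthica* receptor with numbering S95–H246–D217, ligand hydrolysis and
the resulting covalent modification of the catalytic histidine track the
biological potency of synthetic agonists, and hydrolysis in turn depends
on how often the bound complex visits a reaction-competent, *near-attack*
geometry.  `privconf` formalizes that geometry as the **privileged
conformation (PC)** and provides the estimator of its ensemble occupancy
together with the adjacent computational workflow: ensemble I/O, a
synthetic-trajectory generator, a fingerprint screening cascade, covalent
adduct/fragment-ion mass calculations, and the standard assay statistics.

# The occupancy statistic

## Model

Given an ordered ensemble of frames sharing one topology, a PC criterion
is a set of (distance, closed window) pairs.  Frame $t$ is a privileged
conformation iff **every** member distance lies inside its window:

$$\mathrm{PC}(t) \;=\; \prod_{m} \mathbf{1}\!\left[\,l_m \le d_m(t) \le
h_m\,\right], \qquad
P_{\mathrm{PC}} \;=\; \frac{100}{n}\sum_{t=1}^{n} \mathrm{PC}(t)\ (\%).$$

Two criteria are built in:

* **ser-attack** — nucleophilic attack of Ser95 OG on the D-ring carbonyl
  carbon (5′C): $D_{5'\mathrm{C{-}OG}} \in [1.5, 3.8]$ Å and
  $D_{\mathrm{NE2{-}HG}} \in [1.6, 3.5]$ Å.
* **his-attack** — direct attack of His246 NE2 on the 2′C stereocenter:
  $D_{2'\mathrm{C{-}NE2}} \in [1.5, 3.8]$ Å and the same
  $D_{\mathrm{NE2{-}HG}}$ window.

The 1.5–3.8 Å range is the generic reactive-approach distance for
enzyme–substrate pairs; 1.6–3.5 Å is the range of Ser(HG)–His(NE2)
hydrogen bonds observed across deposited α/β-hydrolase receptor crystal
structures, which `triadSurvey()` re-measures on any set of single-frame
structures (falling back to the heavy-atom OG–NE2 distance, flagged, when
a structure has no hydrogens).  The His–Asp hydrogen bonds
($D_{\mathrm{OD1{-}HD1}}$, $D_{\mathrm{OD2{-}HD1}}$) are *diagnostics*:
they are expected to stay near 2 Å whenever the triad is intact, so they
are summarized by `hbondSummary()` but deliberately kept out of the
classification.  The defining criterion uses exactly the two distances
above; folding the H-bond lengths into the AND-classification would make
$P_{\mathrm{PC}}$ measure triad integrity rather than ligand approach.

## Assumptions

* Frames are samples from one stationary process; the estimator is a
  plain frame fraction with no reweighting.  If the source trajectory
  includes an equilibration transient, discard it with the `burnIn`
  argument of `computePPC()` (default 0 — all frames are used).
* Windows are **closed** intervals: a distance exactly on a bound counts
  as inside.  "Within $a$–$b$ Å" is read inclusively; because the
  criterion thresholds are round numbers and distances are continuous,
  the choice is immaterial for real data but is fixed for
  reproducibility.
* Hydrogens are never reconstructed.  The criterion distances are
  H-explicit (HG, HD1); an ensemble without hydrogens must either come
  from an H-explicit source or use heavy-atom surrogates explicitly.
* Residue numbers are kept verbatim from the input (PDB convention);
  nothing is renumbered.

## Uncertainty

Trajectory frames are autocorrelated, so a binomial interval on the frame
count would be too narrow.  `bootstrapCI()` uses a **moving-block
bootstrap**: overlapping blocks of `blockLength` frames (default 50) are
resampled with replacement until the original length is reached
(trimming the last partial block), the occupancy is recomputed in each of
`nBoot` replicates (default 1000), and the 2.5/97.5 percentiles are
reported.  The seed is mandatory — there is no hidden RNG state — and the
same seed always returns the same interval.  With `blockLength = 1` the
procedure reduces to the i.i.d. bootstrap and closely brackets the
binomial percentile interval.  Point estimates are conventionally
reported to 1 decimal place in percent.

# The synthetic-ensemble generator

MD trajectories of receptor–ligand complexes are not redistributable at
package scale, so the generator provides ensembles in which the true
occupancy is *known by construction*.

* **State process.**  A two-state Markov chain (PC-competent vs
  displaced) with stationary PC probability $\pi_{\mathrm{PC}}$ and
  persistence $\rho \in [0,1)$: at every step the current state is kept
  with probability $\rho$, otherwise redrawn from the stationary law.
  The lag-1 autocorrelation of the state indicator is exactly $\rho$ and
  the effective sample size is $n_{\mathrm{eff}} = n(1-\rho)/(1+\rho)$.
  The default $\rho = 0.5$ gives visibly sticky states without making
  estimates at moderate $n$ useless; $\rho = 0$ yields i.i.d. frames.
  Two states are the minimal structure for the bound-warhead vs
  shifted-away-from-the-catalytic-center narrative; richer kinetics can
  be emulated by composing ensembles.
* **Distances.**  Per state and per label, distances are drawn from
  truncated Gaussians.  Defaults (Å): PC state
  $D_{5'\mathrm{C{-}OG}} \sim \mathcal{TN}(2.8, 0.3, [1.6, 3.7])$,
  $D_{\mathrm{NE2{-}HG}} \sim \mathcal{TN}(2.2, 0.3, [1.7, 3.4])$;
  displaced state $D_{5'\mathrm{C{-}OG}} \sim
  \mathcal{TN}(6.0, 0.8, [4.0, 9.0])$ with the H-bond-like
  $D_{\mathrm{NE2{-}HG}}$ unchanged; both H-bond diagnostics
  $\sim \mathcal{TN}(2.0, 0.15, [1.6, 2.6])$ in both states.  These are
  fixture conventions for a plausible bound-vs-displaced geometry, not
  measured values.  The PC-state truncation bounds sit strictly inside
  the criterion windows and the displaced-state $D_{5'\mathrm{C{-}OG}}$
  bounds strictly outside, with ≥ 0.1 Å margin — larger than the
  0.0005 Å PDB rounding error — so classifying a generated ensemble
  (even after a PDB round trip) reproduces the ground-truth state
  sequence exactly.  The generator refuses parameter sets that break
  this encoding.
* **Embedding.**  Each frame is embedded by sequential placement: Ser OG
  anchors the origin and every further atom is placed at its sampled (or
  fixed pseudo-bond: OG–HG 0.96 Å, NE2–HD1 1.00 Å, 5′C–2′C 1.54 Å)
  distance from exactly one already-placed parent along a seeded random
  direction.  One constraint per atom guarantees feasibility without a
  distance-geometry solver; sampled distances are therefore realized to
  machine precision, while non-sampled distances (e.g.
  $D_{2'\mathrm{C{-}NE2}}$) are emergent.
* **Determinism.**  All sampling derives from the spec seed through a
  single RNG stream that is restored afterwards; identical specs give
  byte-identical PDB output, and `sampleStates()` returns exactly the
  sequence `generateEnsemble()` uses.

What the generator does *not* emulate: force-field energetics, sterics,
solvent, multi-state kinetics, or actual ShHTL7 geometry beyond atom
naming.  Passing tests on synthetic ensembles therefore validate the
*estimator* (classification, counting, uncertainty, I/O), not any claim
about real receptor dynamics.

# The screening cascade

The cascade screens a binary-fingerprint library against multiple query
stimulants and funnels the hits:

1. **Ranking.**  Tanimoto similarity $|a \wedge b| / |a \vee b|$ (defined
   as 1 for two empty fingerprints, so identical records always score 1);
   each record's aggregate score is its **maximum** over the queries.
   Max-aggregation preserves per-query top-$n$ semantics — a compound
   close to any one stimulant remains visible — whereas mean-aggregation
   would bury single-query hits; the per-query top lists are retained in
   the result.  Ties are broken by ascending id everywhere, making the
   cascade fully deterministic.
2. **Pooling.**  Default: the library-wide top 100 by aggregate score.
   An alternative mode pools the union of each query's top 100; both are
   exposed via `cascadeConfig(poolMode=)` since either reading of
   "top 100" is defensible.  The top 130 of the aggregate ranking is
   kept as a triage list for manual structure-based selection, which is
   intentionally *not* automated.
3. **Clustering.**  Taylor–Butina sphere exclusion at a Tanimoto
   *distance* threshold (default 0.35): neighbour lists at distance ≤
   threshold; iteratively the unassigned record with the most unassigned
   neighbours (ties by id) becomes a center and claims its unassigned
   neighbours.  Butina is the standard order-deterministic fingerprint
   clustering; its cluster count never increases as the threshold is
   raised.
4. **Center selection.**  Centers of the `nCenters` (default 10) largest
   clusters; ties by higher aggregate score, then id.

Fingerprint *generation* is out of scope — the cascade consumes
precomputed bit vectors (TSV: `id<TAB>bits-or-hex`), because the
commercial fingerprint types used in screening studies are proprietary;
the reproducible part is the cascade logic itself.

# Covalent-adduct masses and fragment ions

Adducts are modelled as pure elemental-formula mass additions on a
residue — no atom-level chemistry.  Embedded IUPAC tables give
monoisotopic and average masses; **nominal** mass is the integer-rounded
monoisotopic value, the convention behind "+94 Da"-style statements about
intact-protein shifts.  Note the two documented adducts straddle that
convention: C6H6O is 94.0419 Da (nominal 94), while the butenolide-derived
C5H5O2 is 97.0290 Da (nominal 97) even though the associated
intact-protein shift is commonly quoted as +94/95 Da; the package reports
both numbers and does not attempt to reconcile them.

Peptide masses are residue sums plus water plus modifications; fragment
series are singly charged b/y ions,

$$b_i = \sum_{k \le i} m_k + m_{\mathrm{H^+}}, \qquad
  y_j = \sum_{k > n-j} m_k + m_{\mathrm{H_2O}} + m_{\mathrm{H^+}},$$

with the modification mass carried by every fragment containing the
modified position, and the complementarity identity
$b_i + y_{n-i} = M + 2m_{\mathrm{H^+}}$ holding to $10^{-4}$ Da by
construction.  Only charge 1+ is produced (label convention of annotated
MS2 spectra); multi-charge states and isotope envelopes are out of scope.
`matchPeaks()` assigns each theoretical ion to its nearest observed peak
within a ppm tolerance and flags the rest; tryptic digestion is not
simulated — the peptide of interest (e.g. residues 231–262 with the
adduct on His246 = position 16) is supplied directly.

# Assay statistics

* **Germination rate**: $GR\% = 100\,N_{gs}/N_{ts}$ per well, with
  $0 \le N_{gs} \le N_{ts}$ enforced.
* **Initial rates**: OLS slope of background-corrected fluorescence over
  the initial window, default 0–8 min, where the fluorogenic-substrate
  signal is still linear; ≥ 3 in-window points required.
  Relative inhibition $100(1 - v/v_0)$ is clipped to $[0, 100]$ with the
  clipping flagged rather than silently accepted, since values outside
  the range indicate apparent activation or background over-correction.
* **Dose–response**: 4-parameter logistic in $\log_{10}$ concentration,
  fitted by Levenberg–Marquardt.  The initialization is fixed so fits are
  reproducible: top/bottom from the response extremes, midpoint at the
  concentration whose response is nearest the half-range, Hill slope of
  magnitude 1 signed by the observed Spearman trend of response vs
  concentration (reference web calculators used for such fits do not
  document their algorithm, so the package fixes its own).  Both free and
  constrained (top = 100, bottom = 0) variants are exposed because the
  constraint convention varies between labs.  Degenerate inputs
  (constant response, non-convergence) return `converged = FALSE` with a
  message — never a silent fallback value.
* **First-order decay**: OLS on $\ln(\text{remaining})$ vs time,
  $t_{1/2} = \ln 2 / k$ — the standard analysis of percent-remaining HPLC
  peak-area series; linearization keeps it closed-form and
  deterministic.  A non-decaying series reports $k \le 0$ with
  $t_{1/2} = \infty$ and a flag (slopes within $10^{-12}$ of zero are
  treated as non-decay to absorb floating-point noise on constant
  series).
* **Percent hydrolysis**: $100(1 - A_{\text{sample}}/A_{\text{blank}})$
  against the no-enzyme blank.
* Replicates are summarized per condition as mean ± SD
  (`replicateSummary()`), the usual triplicate reporting convention.

# Numerical choices and degenerate inputs

* PDB coordinates are written at 3 decimals (format precision
  $5\times10^{-4}$ Å); round-trip tests use a $10^{-3}$ Å tolerance.
  XYZ is written at 6 decimals.
* Multi-model PDB reading requires identical (chain, resSeq, name) atom
  records in every model and names the offending model on mismatch;
  selection requires a unique match and distinguishes "no atom matches"
  from "ambiguous selection".
* `pairDistance()` refuses identical indices and out-of-range indices;
  distances are invariant under rigid-body transforms to $10^{-9}$ Å in
  the test suite.
* Bootstrap, generator and cascade are deterministic given their seeds;
  seeds are always explicit arguments, and the global RNG state of the
  caller is preserved.
* Empty masks, empty label lists, empty peptide sequences, non-positive
  controls/blanks and infeasible truncations are all hard errors with
  specific messages; row-level failures in `triadSurvey()` are recorded
  per structure without aborting the survey.

# Problem sizes

The test suite and the acceptance script run at sizes chosen to make
sampling error negligible relative to the tested tolerances while keeping
a full run inside a few minutes on one CPU: occupancy recovery at
$n = 10{,}000$ frames (three binomial SEs at $\pi = 0.013$ is then
±0.34 points), the stationarity check at $n = 100{,}000$ chain steps,
fixtures at $n = 2{,}000$ frames, clustering oracles at ≤ 20 fingerprints
with exhaustive references, fragment-ion identities over 1,000 random
peptides, and 200 Monte-Carlo replicates for decay-estimator bias.

# Known limitations

* $P_{\mathrm{PC}}$ is a frame-count proxy for reaction propensity; no
  free energies, reaction-path weighting, or kinetic models are
  estimated, and the absolute occupancies reported for real receptor
  trajectories depend on simulation details (force field, length,
  equilibration) outside this package's control.
* The ensemble reader handles text formats only (multi-model PDB, XYZ);
  binary trajectory formats require prior conversion, and periodic
  boundary conditions are not unwrapped.
* The his-attack occupancy of the generator's ensembles is emergent, not
  controlled: the generator pins only the sampled (serine-attack and
  H-bond) distances.
* Fingerprints are consumed, not computed; no 3D similarity, docking or
  property filtering.
* Intact-protein mass deconvolution is out of scope; only peptide-level
  b/y evidence is computed.
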