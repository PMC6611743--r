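---
title: "Ranking candidate structures with hydrogen-deuterium exchange MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate structures with hydrogen-deuterium exchange MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxrank)
```

## The measurement and the model

Non-target identification from LC-MS/MS usually ends with a list of candidate
structures that all share the precursor's molecular formula. A second
acquisition with deuterated mobile phase (D2O/MeOD) adds orthogonal
information: hydrogens bound to oxygen, nitrogen, or sulfur — hydroxyl,
carboxyl, amino, thiol — exchange for deuterium on the chromatographic
timescale, while C–H hydrogens do not. Every exchange shifts the mass by

m(D) − m(H) = 2.014102 − 1.007825 = 1.006277 Da,

and in deuterium-flooded electrospray the precursor ionizes as `[M+D]+` (or
deprotonates as `[M−D]−`), so the number of experimentally exchanged
hydrogens X is read directly off the neutral-mass difference between the
normal and the deuterated precursor: `determine_X()` rounds
(m_D − m_H)/1.006277 to the nearest integer and reports the residual in ppm.
Residuals beyond 10 ppm (default) flag a likely wrong isotope-peak pick; the
pair is flagged, never discarded.

Candidates with the right formula but the wrong *placement* of exchangeable
hydrogens predict the wrong deuterated fragment masses, and that is what the
ranking exploits.

## In silico deuteration

For a candidate with eH exchangeable hydrogens (counted topologically:
hydrogens on O, N, S; tautomerism and steric hindrance are deliberately
ignored and left to scoring):

* eH = X — one variant, all exchangeable hydrogens exchanged;
* eH < X — one variant, all exchanged plus vH = X − eH "variable" deuteriums
  whose position is unknown (aliphatic/aromatic exchange, tracked as a count
  only);
* eH > X — `choose(eH, X)` variants, one per X-subset of the exchangeable
  hydrogen slots.

Disagreement between eH and X is never grounds for elimination — hindered or
tautomeric sites make both over- and under-exchange possible for the correct
structure — it only lowers a score. Combinatorics are capped (eH ≤ 20 and at
most 5000 variants by default); beyond the cap a single positionally
ambiguous variant is used and a warning is emitted.

## Fragmentation

`generate_fragments()` performs MetFrag-style combinatorial bond
disconnection on the heavy-atom skeleton: a cleavage event removes one
acyclic bond or a disconnecting pair of ring bonds, recursively to
`max_depth` events (default 2 — the usual compromise between coverage of
rearrangement-free fragments and combinatorial cost). Deuterium is a per-atom
label, so one fragment set serves all deuteration variants of a candidate.
Each fragment accumulates the dissociation energies of the bonds cleaved to
make it; duplicated atom subsets keep the minimal sum, making the output
independent of cleavage order (this is verified against an exhaustive
connected-subset oracle in the tests). The built-in BDE table is a compact
set of homolytic bond energies by element pair and order (aromatic bonds
1.5 × the single-bond value, unknown pairs 348); its exact values only scale
a penalty that is max-normalized downstream.

Observed fragment ions rarely sit exactly at the subgraph mass: hydrogen
rearrangements and, in HDX experiments, gas-phase H/D scrambling move up to
about two hydrogens. Hypothesized m/z values therefore include every
±H/±D combination with |ΔH| + |ΔD| ≤ 2 (configurable), where mixed signs
(+H/−D) express a deuterium swapped back for a hydrogen. Normal spectra are
ionized with the proton, deuterated spectra with the deuteron. Each
deuterated hypothesis tracks the total deuterium count of the ion —
exchange-derived deuteriums (bounded by X) plus dynamic ±D shifts plus the
ionizing deuteron. That ion-level count, not the exchange-derived count
alone, is what the raw m/z difference between paired peaks measures: it is
the only accounting that simultaneously explains a fully exchanged precursor
pair, a fragment pair after an ND3-type neutral loss, and a terminal
fragment that has lost all deuterium and sits at identical m/z in both
spectra.

## The four scores and the consensus

A peak is matched when a hypothesis lies within
max(rel_ppm · m/z, abs_da) — defaults 5 ppm/0.001 Da, with 10 ppm/0.01 Da
the recommended setting for QTOF-accuracy data. Per candidate:

* **S_MetFrag** — spectral match of the normal spectrum: over matched peaks,
  `I_rel^0.6 · (m/z)^3 · exp(−BDE/E0)` (E0 = 500). The exponents are declared
  defaults; every ranking property is invariant to their exact values within
  reason, and all are configurable.
* **S_MetFragHD** — the same rule applied to the deuterated spectrum with the
  deuterated hypotheses.
* **S_PairHD** — the number of fragments explaining a peak in *both* spectra
  whose two peak masses differ by exactly the fragment ion's deuterium count
  times 1.006277 Da (within ε, default the matching tolerance). Any
  in-tolerance explanation of a peak may pair (not only the single
  lowest-BDE assignment, which a dense hypothesis space lets hijack peaks);
  fragments pair greedily in BDE order and consume their peaks, so the count
  never exceeds the peak count of either spectrum. Pairs are counted, not
  intensity-weighted — the count is the evidence that the same substructure
  was observed twice.
* **S_OSN** — 1/(|X − eH| + 1): structure-level agreement between predicted
  and observed exchange.

S_MetFragHD and S_PairHD take their maximum over the candidate's deuteration
variants. Each raw score is divided by its maximum over the candidate list
(an all-zero column stays zero), and the consensus is the weighted sum with
default weights (0.109, 0.004, 0.497, 0.390). Candidates are ranked by
descending consensus with average ranks for ties; duplicates are collapsed
beforehand on the InChIKey connectivity block. Peaks at or above the
precursor m/z are excluded from scoring by default (`exclude_precursor`),
since precursor-derived signal carries no fragmentation information.

## Weight fitting

`sample_simplex()` draws weight vectors uniformly from the simplex
(normalized i.i.d. exponentials — exact Dirichlet(1,1,1,1)).
`optimize_weights()` evaluates a fixed number of draws (default 1000) and
keeps the one maximizing the training top-1 count, ties broken by top-3 and
then by first occurrence under the seed — a deterministic policy the
randomized search needs for reproducibility. `cross_validate()` wraps this
in seeded k-fold CV (k = n gives leave-one-out), fits on each fold's
complement restricted to any subset of the four terms (excluded terms get
weight zero), and pools held-out top-1/3/5/10 counts over folds; pooling
(rather than averaging per-fold rates) is what the report labels.

## The synthetic spectrum-pair generator

`generate_fixture_pair()` emulates the clean, complete-exchange regime: the
true structure is fragmented, up to 12 low-BDE fragments become peaks with
log-normal intensities (meanlog log 1000, sdlog 1) and 1 ppm Gaussian mass
error, the deuterated spectrum shifts each fragment by its retained
exchangeable-hydrogen count, and 5 uniform decoy peaks per spectrum model
unexplained signal. All draws are seeded; identical seeds give identical
fixtures. `candidate_family()` supplies formula-matched decoys: all di- and
tri-substituted benzenes over a fixed substituent vocabulary that hit a
target formula, deduplicated by InChIKey — isomer sets of 21+ members whose
eH values differ, which is exactly the discrimination problem the method
addresses.

What the generator does *not* emulate: partial or slow exchange,
back-exchange, retention-time shifts between the two runs, isotope-pattern
interference, rearrangement fragments, and electron-impact-style chemistry.
Passing tests on fixtures therefore demonstrate the scoring machinery and
its implementation, not performance on real spectra; the benchmark's value
is the *comparison* between scoring configurations under identical
conditions, in which the full consensus consistently places the true
structure at least as well as the fragmenter score alone.

Benchmark sizes used by the tests (50 spectrum pairs, ≥ 20 decoys each,
fragmentation depth 2) keep a full run in the low minutes on one core;
fragment sets are cached per structure across pairs.

## Numerical choices and degenerate inputs

* Masses: H 1.007825, D 2.014102, electron 0.00054858; proton 1.007276,
  deuteron 2.013553; 13C 13.003355 Da. The 13C/D separation is 0.00292 Da —
  `find_pairs()` flags feature pairs whose tolerance (or stated resolving
  power) cannot exclude the isotopologue explanation.
* An unexchanged compound in the deuterated run can still appear at its
  protonated m/z; `find_pairs()` falls back to the `[M+H]+` reading when the
  `[M+D]+` reading gives no non-negative exchange count.
* Peak lists without intensities get equal intensities; relative-intensity
  weighting then degenerates gracefully.
* Matching ties (equal BDE) break on smaller mass deviation; score ties in
  ranking get average ranks.
* `exchange_completeness_probability(p, n) = p^n`: at 99 % deuterium purity
  and 40 labile hydrogens, complete exchange has probability 0.66 — large
  glycosides will show mixed isotopologue envelopes.

## Known limitations

Only `[M+H]+`/`[M+D]+` and `[M−H]−`/`[M−D]−` are supported. Exchange
detection is topological; amide and amine N–H are treated identically. No
kinetic model of partial exchange, no back-exchange correction, no
mechanistic fragmentation rules — scrambling is absorbed by the ±H/±D
hypothesis range exactly as the scoring intends. Retention-time alignment
between the two runs is exposed only as a window parameter
(`rt_window`, default 0.4 min); strongly shifted late-eluting compounds need
a wider window chosen by the analyst.
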