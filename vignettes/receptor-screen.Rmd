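---
title: "Methods: from spike trains to an in-silico substitution screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike trains to an in-silico substitution screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

This vignette documents the models behind each stage of the pipeline,
the parameters that matter, the numerical choices made where the
procedure is under-determined, and what the synthetic-data generators do
and do not emulate.

## Spike quantification

A single-sensillum recording trial is reduced to a net response in
spikes/s: the spike count in the 0.5-s window opening 0.2 s after
stimulus onset (the latency of odor transport to the sensillum), minus
the count in the 0.5-s window immediately before onset, doubled to
express the difference per second. Both windows are closed on the left
and open on the right, so a spike falling exactly on a boundary is
assigned to the earlier window; the convention matters only for
zero-measure events but keeps the operation deterministic. Responses
may be negative (suppression below spontaneous rate) and are never
clipped, because the downstream spike ratio
$R_\mathrm{BITC} / (R_\mathrm{BITC} + R_{\gamma\mathrm{hex}})$ is
defined with a summed denominator precisely because control-subtracted
attractant responses can come out negative; when the denominator is
$\le 0$ the ratio is reported as missing rather than raised as an
error.

Control subtraction operates per sensillum: the mean net response of
that sensillum's solvent trials is subtracted from each of its odorant
responses. A sensillum without a solvent trial is a hard error naming
the sensillum, since silent failure would bias the panel.

Sensilla are grouped into functional classes by agglomerative
hierarchical clustering (Ward linkage, Euclidean distance on the
response vectors) cut at `n_classes` (default 3, the number of palp
basiconic types). No clustering algorithm is canonical for this task;
Ward on Euclidean distance was chosen because it is deterministic,
needs no starting values, and matches the "functional classes" framing
of response-profile typing. Rows are sorted by sensillum id before
clustering so the partition is invariant to input order, and distances
scale linearly under uniform response scaling, so the partition is also
scale-invariant. Class labels are arbitrary (a partition, not a
naming); tests compare partitions, not labels.

## EC50 estimation policy

Dose–response series are fitted in log10-concentration space for
conditioning,

$$y = d + \frac{a - d}{1 + 10^{\,h (\log_{10}\mathrm{EC50} - \log_{10} x)}},$$

reported on the linear vol/vol scale. The two-parameter branch fixes
$a = 100$, $d = 0$ and requires responses on the percent-of-maximum
scale; `normalize_series()` floors negatives at zero and scales the
largest response of the chemical–species pair to 100. Flooring happens
only inside normalization — the four-parameter branch sees raw
responses. Normalization to the largest *observed* response distorts a
curve whose top concentration has not reached its plateau; that is the
reason the policy routes non-saturating chemicals (the SBITC situation)
to the four-parameter fit with a free plateau, and why the exact
noise-free inversion property is stated for series already on the
percent scale.

Fitting uses Levenberg–Marquardt least squares (`minpack.lm::nlsLM`)
with starting values EC50 at the concentration whose response is
nearest half-max, $a = \max y$, $d = \min y$, and a restart grid over
$h \in \{0.5, 1, 2\}$; the best converged restart by residual sum of
squares wins. "Failed to fit" is operationalized as: optimizer
non-convergence, non-positive Hill slope, or a fitted EC50 outside
$[\min x,\ 100 \times \max x]$. The lower bound is the lowest tested
concentration because an EC50 below it means the entire transition was
unobserved — the degenerate "calculated value of 0" case; an earlier,
looser bound of $\min x / 100$ admitted spurious four-parameter fits
whose whole transition sat below the tested range. The upper slack of
100× is kept because a non-saturating top still brackets the midpoint
usefully. When both branches fail, the minimum observed response within
the chemical–species group is recorded (`method =
"min_value_fallback"`); note this value is a response (spikes/s or %),
not a concentration, which is why it is stored as `fallback_value` and
the result is flagged unconverged.

The noisy-recovery simulation in the tests and acceptance script uses
a true EC50 of 1e-4 vol/vol with Hill slope 1, plateau 100 spikes/s,
Gaussian noise of 5 spikes/s, and seven half-decade concentrations from
1e-5 to 1e-2 — an EC50 placed inside the tested range with a plateau
and noise magnitude typical of strong palp responses.

## Behavioral indices

*Immobility.* Mobile counts on the 10-minute grid up to 60 min are
converted to per-fly event times: immobility is treated as absorbing,
the event time is the first grid point at which a fly is scored
immobile, and flies still mobile at 60 min are right-censored there.
The interval-censored nature of grid observation is collapsed to the
grid times, which is what a Mantel–Cox comparison of the curves
operates on anyway.

*Positional choice.* Two percentages per time point: participation,
$100 (n_\mathrm{odor} + n_\mathrm{control}) / n_\mathrm{released}$, and
preference, $100\, n_\mathrm{odor} / (n_\mathrm{odor} +
n_\mathrm{control})$. Preference is undefined when no fly chose and is
propagated as missing (excluded from signed-rank samples) rather than
imputed. An assay is discarded only when participation is strictly
below 40% at *every* time point; exactly 40% anywhere keeps it.

*Consumption.* The vial feeding score is the weighted category mean
$(0 n_0 + 0.25 n_{0.25} + 0.5 n_{0.5} + 1 n_1 + 2 n_2)/N \in [0, 2]$,
normalized by the mean score of control vials of the same genotype
assayed the same day, so the null value is 1. A missing same-day
control is a hard error; normalizing across days would absorb day
effects into the treatment estimate.

## Nonparametric tests

The four tests the pipeline reports are implemented in the package
rather than wrapped, so their exact small-sample paths are under direct
control and testable against enumeration oracles:

* signed-rank: zero differences dropped (Wilcoxon convention — the
  assay protocols do not say how they treated them), exact null via the
  enumerated distribution of the positive-rank sum for $n \le 25$
  without ties, otherwise a tie-corrected normal approximation with
  continuity correction;
* Mann–Whitney U: exact for $n + m \le 20$ without ties, same
  approximation scheme otherwise;
* Kruskal–Wallis with tie correction, Dunn's pairwise $z$ with
  Bonferroni adjustment by default (the adjustment used in the original
  figure legends is unstated; Bonferroni is the conservative default
  and the `correction` argument accepts any `p.adjust` method);
* log-rank (Mantel–Cox): observed-minus-expected events summed over
  distinct event times with the hypergeometric variance, $\chi^2_1$
  reference.

Two-sided alternatives are the default everywhere; one-sided versions
are available per argument, mirroring the occasional one-tailed usage
in the assay designs. Exact p-values use the symmetric
$2 \min(P_\le, P_\ge)$ convention capped at 1, which coincides with the
standard library's convention for these symmetric nulls (verified in
the tests).

## Expression summaries

RPM is computed against the sum over all genes present in the count
table. Whether the original denominator was all mapped reads or all
counted genes is ambiguous; all-counted-genes was chosen because it is
reproducible from the table alone, and the choice only rescales all
genes of a sample jointly. The low-expression filter retains a gene
when its median $\log_2(\mathrm{RPM}+1)$ over replicates is $\ge 1$
(exclusion is strict `< 1`) in at least one sample group; requiring all
groups is available via `all_groups = TRUE`. At-least-one is the
default because per-species expression panels display each species
separately, and a gene expressed in only one species is still
informative.

## Structure screen

Superposition is the closed-form Kabsch solution: SVD of the
cross-covariance of centered coordinate pairs, with the sign of the
smallest singular vector flipped if needed to enforce a proper rotation
(det = +1). Collinear point sets (second singular value numerically
zero, below 1e-8 of the largest) are rejected as degenerate. The
brute-force oracle used in tests searches a 10×10×10 Euler-angle grid
polished by Nelder–Mead, and agrees to well below 1e-6 Å.

The frame policy is the load-bearing design decision: the global
transform is fitted once over *all* residues passing the confidence
mask (pLDDT strictly greater than 70 in both models — low-confidence
termini are excluded, as predictors are unreliable there), and regional
RMSDs are then measured under that single transform without per-region
refitting. Refitting per region would absorb exactly the local
divergence the screen is trying to measure.

The screen itself is greedy forward selection over the candidate set
returned by `diff_positions()` (all residue differences between the
aligned paralog sequences). Each round predicts the structure of the
background sequence carrying the accepted substitutions plus one
additional candidate, and fixes the candidate giving the lowest S5–S6
RMSD; ties are broken by lowest residue position. The stop threshold
defaults to $\max(0.15\ \mathrm{Å},\ \mathrm{median\ RMSD\ of\ the\
non\text{-}target\ regions})$ — "comparable to the other regions" made
operational — and the screen also stops when no candidate reduces the
RMSD or candidates are exhausted. Accepted steps are therefore strictly
decreasing in regional RMSD. Greedy selection was chosen over
exhaustive subset search because the procedure it models is itself
sequential (mutate, re-predict, re-align, repeat); its known failure
mode is interacting sites, discussed under limitations.

The direction convention is donor residues substituted into the
background sequence (Or42a3-like background receiving Or42a4-like
residues), with the predicted chimera aligned against the donor's
structure model.

The backend contract keeps prediction pluggable: a predictor is a pure
function from sequence to `structure_model`, deterministic for a fixed
input; `run_screen()` caches predictions by sequence within a run. The
package ships only the deterministic mock backend; wiring a real
folding engine means wrapping its invocation in a function honoring the
contract.

## Synthetic-data generators

The generators define the conditions under which the pipeline is
validated:

* spike trains are homogeneous Poisson processes with a rate step in
  the response window `[onset+0.2, onset+0.7]` s — no adaptation,
  bursting, or amplitude structure, so tests exercise counting and
  subtraction, not spike sorting (out of scope);
* dose–response series are exact two-parameter logistics plus Gaussian
  noise truncated at $-a$;
* the structure pair is an idealized seven-helix Cα bundle (2.3 Å
  radius, 1.5 Å rise, 100°/residue, axes on an 11 Å circle with
  alternating orientation) of 400 residues — the length of a typical
  insect odorant receptor — with 40-residue helices, interpolated
  loops, and 10-residue low-confidence termini (pLDDT 50 vs 90
  elsewhere). The target copy displaces S5–S6 coordinates by Gaussian
  fields of width 3 residues centered on each causal position,
  truncated to the S5–S6 union so the pair is bitwise identical
  elsewhere; decoy substitutions change sequence but not coordinates,
  modeling paralog differences that are structurally silent. The
  default amplitude 4.7 Å comes from a closed form: one bump of width
  $w = 3$ contributes $\sum_i \exp(-(i-p)^2/w^2) \approx w\sqrt{\pi}
  \approx 5.32$ to the squared deviation, so two bumps over the
  80-residue S5–S6 helix block give regional RMSD $\approx A
  \sqrt{2 \times 5.32 / 80} \approx 0.36 A$, and $A = 4.7$ Å targets
  the ~1.7 Å divergence scale of interest (the global superposition
  absorbs a small part of it, which the acceptance script quantifies);
* behavior tables use exponential immobilization times discretized
  upward to the 10-min grid (immobility as an absorbing state),
  binomial participation/choice at each 5-min time point, and
  multinomial feeding categories.

All generators take a required seed, route randomness through one
locally scoped generator, and restore global RNG state, so identical
spec plus seed is byte-identical output. What passing tests on these
inputs does *not* show: robustness to spike-sorting errors, receptor
adaptation, non-logistic dose–response shapes, non-exponential
immobilization hazards, or real predictor noise (a folding engine is
not deterministic across versions and its displacement response to a
point mutation is not additive).

## Known limitations

* Greedy forward selection can stall when causal sites interact: with
  two overlapping displacement fields in partial cancellation, no
  single substitution reduces the regional RMSD and the screen stops
  short (observed in simulation when both planted sites fall within a
  few residues of each other). The screen validation therefore plants
  one causal site per helix, matching the configuration of a two-hit,
  two-helix screen; for small candidate sets an exhaustive pair search
  is a straightforward extension.
* The fallback EC50 value is a response, not a concentration;
  downstream consumers must branch on `method`.
* Regional RMSD depends on the global superposition frame; values are
  comparable between runs of this package but not directly to tools
  that refit locally or weight outliers differently.
* PDB support is the Cα/B-factor dialect of structure predictors; full
  atomic models and mmCIF are out of scope.
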