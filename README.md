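# orscreen

Analysis pipeline for studying how insect odorant receptor (Or) paralogs
diverge in function — from electrophysiology to behavior to structure.
It was built for the kind of study where duplicated receptor genes (e.g.
the *Or42a* triplication in the mustard-specialist fly *Scaptomyza
flava*) are characterized by single-sensillum recordings (SSR),
dose–response curves, behavioral assays, maxillary-palp expression data,
and an AlphaFold-style in-silico mutagenesis screen that asks *which of
the residue differences between two paralogs explain a localized
structural difference in the ligand-binding helices*.

Everything downstream of raw data collection is covered:

* **Spike quantification** — the net odor-evoked response of a recording
  is `2 × (spikes in [onset+0.2 s, onset+0.7 s) − spikes in the 0.5 s
  before onset)` spikes/s, control-subtracted per sensillum against the
  mean solvent response (`net_response()`, `control_subtract()`).
  Sensilla are classified into functional types by Ward-linkage
  hierarchical clustering of their response profiles
  (`classify_sensilla()`), and ligand preference is summarized by the
  spike ratio `R_BITC / (R_BITC + R_γhex)` (`spike_ratio()`).
* **EC50 estimation** — `estimate_ec50()` implements a three-step
  policy: a two-parameter logistic `y = 100 / (1 + (EC50/x)^h)` on
  responses normalized to the largest response of the chemical–species
  pair; a four-parameter logistic `y = d + (a−d)/(1 + (EC50/x)^h)` with
  free plateau and floor when the two-parameter fit fails or the top
  concentration does not saturate (forced for such chemicals via
  `force_four_param`); and, when both fits degenerate, the minimum
  observed response is recorded as a fallback value.
* **Behavioral indices** — percent mobile flies over time with log-rank
  (Mantel–Cox) comparison of immobilization curves; positional-choice
  percentages (`% made choice`, `% odor side`) with the
  below-40%-participation exclusion rule; 5-point feeding scores
  normalized to same-day controls.
* **Nonparametric statistics** — self-contained Wilcoxon signed-rank,
  Mann–Whitney U (both exact for small samples), Kruskal–Wallis with
  Dunn's post hoc, and the two-arm log-rank test, validated in the test
  suite against full-enumeration oracles and the standard library
  implementations.
* **Expression summaries** — reads-per-million normalization, the
  `median log2(RPM+1) < 1` low-expression filter, and FISH cell-count
  ratios (receptor-positive / Orco-positive neurons) with species
  comparison.
* **Structure screen** — `run_screen()` superposes predicted paralog
  structures by Kabsch least squares over the pLDDT > 70 confidence
  mask, measures per-helix RMSD under the single global transform, and
  greedily accepts the donor-residue substitution that most reduces the
  S5–S6 regional RMSD per round until it is comparable to the other
  regions. The structure-prediction backend is pluggable; a
  deterministic mock backend (`mock_predictor()`) with planted ground
  truth supports fully offline testing.
* **Synthetic data** — seeded generators for every input family
  (Poisson spike trains, logistic dose–response series, idealized
  seven-helix Cα bundles with planted causal substitutions and silent
  decoys, and binomial/exponential/multinomial behavior tables).

## Worked example

Simulate a paralog pair with two causal substitutions (one in each
binding-pocket helix) hidden among 30 structurally silent decoys, then
screen for them:

```r
library(orscreen)

spec <- struct_sim_spec(causal_positions = c(250, 310), n_decoys = 30, seed = 7)
pair <- gen_structure_pair(spec)

round(region_rmsd(pair$background, pair$target, spec$regions)$rmsd, 2)
#>   S1   S2   S3   S4   S5   S6   S7
#> 0.17 0.07 0.09 0.19 1.61 1.62 0.25

run_screen(pair$background$sequence, pair$target$sequence,
           pair$target, mock_predictor(pair), spec$regions)
#> In-silico substitution screen over S5-S6
#>   stop threshold: 0.173 A, converged: TRUE
#>   regional RMSD: 1.616 -> 0.000 A in 2 step(s)
#>   accepted: S250M + P310A
```

The divergence is localized (S5/S6 at ~1.6 Å vs ≤0.25 Å elsewhere), and
the screen recovers exactly the two planted sites out of 32 candidates.
An EC50 fit from a noisy series:

```r
x <- 10^seq(-5, -2, 0.5)
set.seed(1)
estimate_ec50(dose_response_series(x, 100/(1 + (2e-4/x)^1.1) + rnorm(7, 0, 4),
                                   chemical = "AITC", species = "S. flava"))
#> EC50 fit: AITC / S. flava
#>   method: two_param_normalized  converged: TRUE
#>   EC50: 0.000192 vol/vol  hill: 1.2  range: [0, 100]
```

The estimate (1.92e-4 vol/vol against a true 2e-4) comes from the
primary two-parameter branch of the fitting policy.

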