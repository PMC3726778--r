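# saxsens

Ensemble optimization of small-angle X-ray scattering (SAXS) data for
elongated multidomain proteins with flexible interdomain hinges — the
plakin domains of cytoskeletal linker proteins (envoplakin, periplakin,
desmoplakin), built from tandem spectrin-repeat arms, are the motivating
case.

## Who this is for

Structural biologists asking whether a two-arm protein is a rigid rod or
articulates about a linker in solution. A single static model fitted to a
SAXS profile cannot answer that; comparing a random conformer *pool*
against the GA-selected *sub-ensemble* that best fits the data can.

## The method

For a coarse-grained bead model (one bead per residue at the C-alpha
position, weights *w*), the theoretical scattering is the Debye formula

    I(q) = sum_i sum_j w_i w_j sin(q r_ij) / (q r_ij),    I(0) = (sum w)^2

A model curve is scored against data (q, I, sigma) by the reduced
chi-square with an analytically profiled scale mu:

    chi^2 = (1 / (K - 1)) * sum_k ((mu * I_mod(q_k) - I_exp(q_k)) / sigma_k)^2

The pipeline generates a pool of N random conformers (rigid arms, freshly
sampled flexible linkers; canonically N = 10,000), caches each member's
Debye curve, and runs a genetic algorithm over index multisets of size
M = 50 whose fitness is the chi-square of the ensemble-average curve.
Flexibility is read out of pool-versus-selected distributions of Rg, Dmax
and end-to-end distance, and of hinge-angle shape classes: U (< 60 deg,
folded back), L (60-120 deg), I (> 120 deg, extended).

Three architectures are compared on one data curve: a fully rigid
*linear extended* rod, a *linear* rod with flexible C-terminal tail, and a
*hinged* model (flexible hinge + tail). For genuinely hinged chains the
ranking chi2(hinged) < chi2(linear) < chi2(linear extended) holds.

## Worked example

Fabricate a desmoplakin-like ground truth — a 75/25 mixture of folded-back
(U, 20 deg) and extended (I, 170 deg) conformers about a 37-residue hinge —
then run the three-model comparison:

```r
library(saxsens)
spec  <- scenario_spec("bimodal_UI", noise_fraction = 0.01, seed = 21)
truth <- precompute_curves(simulate_true_ensemble(spec, 200), spec$q_grid)
data  <- synthesize_saxs(truth, spec)
report <- run_three_model_comparison(
  data, spec,
  compare_config(pool_size = 500, ensemble_size = 50,
                 ga = ga_config(n_repeats = 3), seed = 42))
print(report)
```

prints (about two minutes on one CPU):

```
<comparison_report> bimodal_UI
  data Guinier Rg: 56.4 A
  chi2 linear_extended  226.922
  chi2 linear           109.362
  chi2 hinged           0.937
  ranking (best first): hinged < linear < linear_extended
<distribution_summary> Rg RMS pool 64.6 A, selected 59.9 A; 2 selected-Rg peak(s), peak mass ratio 2.3
```

Reading it: only the hinged model reaches chi-square ~ 1 (a fit within the
noise); both rigid-rod architectures fail by two orders of magnitude. The
selected ensemble's Rg histogram is bimodal — the two hinge orientations of
the truth — with the compact peak carrying ~2x the mass of the extended
one, and the RMS-averaged selected Rg (59.9 A) is pulled below the pool's
(64.6 A) by the dominant compact population.

Every stage is also exposed as a CLI (`inst/cli/saxsens`):

```sh
saxsens simulate --scenario bimodal_UI --seed 21 --out demo
saxsens compare  --data demo/data.dat --scenario bimodal_UI \
                 --n-pool 500 --seed 42 --out demo_report
```

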