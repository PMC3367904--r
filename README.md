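# serialorder

Tools for decomposing **implicit serial-order knowledge** in serial reaction
time (SRT) tasks.  When responses to a covert repeating sequence speed up,
that learning can rest on two distinct memory structures: **item-item
(chaining) associations**, where each element cues its successor, and
**serial position-item associations**, where an ordinal position code cues
the element occupying it.  The package is aimed at cognitive psychologists
studying sequence learning who need (a) a fully specified derived-list SRT
design, (b) a generative RT model to validate analysis pipelines against,
and (c) the complete analysis chain, from trial exclusions to the race model
inequality test.

## What it implements

* **Design generator** — a three-session visual-search SRT experiment on a
  32-location grid (6 × 6 minus corners): per session 15 training blocks
  (each 24 four-trial mini-blocks: 8 + 8 fixed-sequence, 4 + 4 random-set)
  and transfer blocks at positions 6/12/18 containing 8 ordinal-only,
  8 order-only and 8 random-transfer mini-blocks.  Ordinal-only trials show
  a trained item at its learned serial position among never-trained
  locations; order-only trials preserve exactly one learned transition at a
  wrong serial position; control trials carry no usable association.
  Adjacency constraints, run caps, response-side balancing and
  location-role counterbalancing over an 8-participant cycle are enforced,
  and `classify_transfer_trials()` re-derives every analysis tag from first
  principles.
* **Generative RT model** — shifted-lognormal search baseline minus two
  exponential learning curves (position-item: fast, asymptote 88 ms;
  item-item: slow, asymptote 120 ms), expressed through an independent
  **race** (noisy per-cue retrievals, fastest wins) or **coactivation**
  (additive facilitation plus an over-additive bonus).
* **Preprocessing** — exclusion of errors and post-error trials, cell
  medians, and the seven condition difference scores
  (`median(reference) − median(test)`).
* **Race model inequality test** — per-participant CDF percentile points
  (plotting positions `(i − 0.5)/n`, ten levels 5%...95%), the summed bound
  `F_order + F_ordinal`, and paired one-tailed t-tests with a
  restricted-range (5-20%, Bonferroni factor 2) violation decision:

  `F_fixed(t) ≤ F_order(t) + F_ordinal(t)` — violation ⇒ coactivation.

* **Explicit-knowledge scorer** — ordered-hit guessing null (exact by
  enumeration/inclusion-exclusion, or Monte Carlo), hypergeometric
  upper-tail scores for unordered reports, averaged two-report probability
  and the 5% exclusion rule.
* **Statistics** — two-way repeated-measures ANOVA (uncorrected df, each
  effect against its own subject-interaction error term), session
  regressions with standardized slopes, paired t-tests, Pearson/Spearman
  correlations, within-subject error bars `sqrt(MS_interaction / n)`.

## Worked example

```r
library(serialorder)

spec    <- design_spec(seed = 1)
designs <- lapply(1:6, function(p) make_experiment(spec, participant = p))
cohort  <- simulate_cohort(designs = designs, params = sim_params(), seed = 1)
scores  <- analyze_cohort(cohort)$session_scores

aggregate(value_ms ~ contrast + session, scores, mean)   # excerpt:
#>          contrast session mean_ms
#>   fixed_vs_random       1    81.8
#>   fixed_vs_random       3    90.5
#>      order_vs_new       1     5.5
#>      order_vs_new       3    57.8
#>    ordinal_vs_new       1    57.8
#>    ordinal_vs_new       3    58.8
```

The simulated cohort shows the signature pattern the design is built to
detect: the ordinal-only advantage (position-item knowledge, ~58 ms) is
already present in session 1 and stays flat, while the order-only advantage
(item-item knowledge) grows from ~6 ms to ~58 ms, and the fixed-sequence
advantage exceeds either single source throughout.

```r
rts <- simulate_condition_rts(sim_params(seed = 1))  # 21 participants, race
rmi_test(rmi_percentiles(rts))
#> Race model inequality test (21 participants)
#> Restricted range: 0.05, 0.15   alpha = 0.05
#>    level mean_fixed mean_sum      t df      p restricted p_adj
#> 1   0.05      539.2    511.3  3.678 20 0.9993       TRUE     1
#> 2   0.15      621.8    576.0  7.745 20 1.0000       TRUE     1
#> ...
#> => no violation: independent race not rejected
```

Under the race architecture the fixed-sequence percentile points stay above
the summed single-source bound, so no violation is declared; switching to
`sim_params(architecture = "coactivation")` produces reliably detected
violations at the fast percentiles.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script exercises the installed package end-to-end from the given seed:
it generates and verifies a counterbalanced set of designs, simulates a
cohort and computes all difference scores, runs the race model inequality
test on a full-size (21-participant) condition-level cohort, scores
simulated verbal reports against the exact guessing null, and writes the
JSON report to `--out`.
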