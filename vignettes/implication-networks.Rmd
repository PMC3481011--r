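---
title: "Implication coexpression networks for smoking-associated signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implication coexpression networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
prediction-logic model behind the implication networks, the downstream
differential/validation/selection pipeline, the synthetic study design the
tests run on, and the numerical and design decisions taken where the
method leaves room. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The implication-rule model

Expression is dichotomized per gene against the gene's mean in the
training cohort: state 1 ("up") is strict exceedance of that mean, state 0
("down") is everything else, ties included. The training means are frozen
and reused to dichotomize any test cohort — the test data never
re-estimate the threshold.

For an ordered pair of dichotomous variables $(A, B)$ six implication
rules are scored: the four directional forms $A \Rightarrow B$,
$A \Rightarrow \neg B$, $\neg A \Rightarrow B$,
$\neg A \Rightarrow \neg B$ and the two equivalences $A \Leftrightarrow B$
and $A \Leftrightarrow \neg B$. Each rule designates *error cells* of the
2×2 contingency table — the cells its prediction forbids
($A \Rightarrow B$ forbids $(1,0)$; $A \Leftrightarrow B$ forbids
disagreement; and so on). With $N$ samples, observed error rate
$V = \sum_{\text{error cells}} n_{ij} / N$ and chance error rate
$K = \sum_{\text{error cells}} (r_i/N)(c_j/N)$ from the margins, the rule
is scored by

* **precision** ("del") $\nabla = 1 - V/K$ — the proportionate reduction
  in error relative to independence; $\nabla = 1$ iff the error cells are
  empty, $\nabla = 0$ at exact independence;
* **scope** $U$ — the premise coverage: the antecedent's marginal
  frequency for directional rules, structurally 1 for equivalences;
* a one-sided **precision z-test**, treating the error count as
  $\mathrm{Binomial}(N, \hat K)$ under the independence null:
  $z = (NK - NV)/\sqrt{NK(1-K)}$, upper-tail p;
* a one-sided **scope z-test** against a configurable minimum coverage
  `min_scope` (default 0, making the test structural: it passes whenever
  the premise covers at least one sample).

These estimators are the standard prediction-logic forms; the source
method's software did not publish its exact formulas, so this
parameterization is a documented reconstruction, and the test suite guards
it with an independent Monte-Carlo oracle (section 4).

**Rule selection.** A pair receives an edge when at least one rule has
$p_{\text{precision}} < \alpha$, $p_{\text{scope}} < \alpha$ and
$\nabla > 0$; among qualifying rules the one with maximal $\nabla$ is
stored, ties resolved in favour of equivalence rules and then by the fixed
rule order. The arbitration is a package choice: the method stores a
single typed relation per pair but does not state its tie rule.

**Null behaviour worth knowing.** At balanced margins the equivalence-rule
z-statistic reduces to $(\#\text{agree} - \#\text{disagree})/\sqrt{N}$ and
is exactly standard normal under independence, so each equivalence
direction fires at the nominal one-sided rate; the directional rules are
conservative (their plug-in null variance overstates the sampling
variance). The per-pair any-edge rate at $\alpha = 0.05$ is therefore
dominated by the two equivalences, around twice the nominal level, which
is what the differential-validation chain (section 2) must overcome.

## 2. Pipeline: screens, differential components, validation, selection

1. **Survival screen.** Univariate Cox per gene (continuous expression,
   Wald test), raw $P < \alpha$, no multiplicity correction; an optional
   Benjamini–Hochberg flag exists but is off by default, matching the raw
   screening convention. Constant genes are flagged non-testable.
2. **Smoking screen.** Welch (unequal-variance) two-sided t-test on the
   survival screen's survivors; the equal-variance choice was unstated in
   the source method, and Welch is the safer default. Zero-variance,
   equal-mean genes report $p = 1$.
3. **Candidates** are the intersection of the two screens plus the hub
   genes, which are included regardless of screen outcome.
4. **Per-group networks** over the candidates, built separately for
   smokers and non-smokers on training data.
5. **Differential components**: pairs with an edge in one group and no
   edge of any type in the other. Pairs carrying differently-typed edges
   in both groups are reported as `type_changed` but excluded from
   selection — the conservative reading of "present in one group, missing
   in the other"; the alternative (counting type changes) remains visible
   in the output.
6. **Validation** in the test cohort, dichotomized with the frozen
   training means: an edge survives when its training rule type is
   significant in the corresponding test-cohort group *and* the pair is
   still group-specific there (no test edge in the other group). The
   source text is ambiguous about whether the identical rule type was
   required; requiring the same type is the stricter, frozen-model
   reading. Validation can only remove edges, never add.
7. **Signature selection**: a gene is selected when it has validated
   group-specific edges to *all* hub genes; hubs themselves are excluded.
   Selection operates on the differential components, not the full group
   networks, following the method's flow from differential components to
   signature.

## 3. Network evaluation

Edges are labeled against an annotation collection: gene sets (any
GMT-serializable source — positional, curated, motif, computational,
GO-style) plus optional interaction pairs. An edge is **TP** if the genes
share a set or interact, **FP** if both genes are annotated but share
nothing, **ND** (non-discriminatory) if either gene is unannotated; ND
edges are excluded from network precision $TP/(TP+FP)$ and q-value
$FP/(TP+FP)$.

**Permutation FDR.** The test cohort's smoking labels are permuted; the
validated differential edge set is recomputed against the unchanged
training networks; surviving edges are labeled and their q-value recorded;
the FDR is the mean q over permutations. Permutations yielding no labeled
edge contribute nothing and are counted separately (the method did not
state their treatment). Two regimes matter:

* over the screened candidate genes alone, permuted-label validation is
  almost always empty — the planted/real signal is significant in *both*
  permuted groups and hence never group-specific — so the FDR estimate is
  near zero;
* over a universe that includes background genes, the training
  differential set contains chance pairs, whose re-validation under
  permuted labels yields surviving edges that are effectively random
  annotated pairs; their mean q estimates the chance FP rate, which for
  the synthetic decoy annotations is $1 - \rho$ with $\rho$ the decoy
  sharing rate. The acceptance checks evaluate the FDR in this regime,
  where it has a closed-form expectation.

**Stability.** The training cohort is subsampled without replacement
within each smoking group (preserving the group ratio — important under
heavy smoker/non-smoker imbalance), the whole
dichotomize/network/differential/validation chain is re-run (training
means re-estimated on the subset), and the fraction of the full-data
validated edges retrieved is recorded; the mean over iterations is the
stability. The subset fraction is unspecified in the source method;
the default is 0.8. With fraction 1 the subsample is a permutation of the
full data and stability is exactly 1 (networks are sample-order
invariant).

## 4. Numerical choices

* **Testability guard.** The precision z-test is applied only when the
  expected error count satisfies $NK \ge 5$ (the classical validity rule
  for a normal approximation to a binomial tail). Without the guard,
  directional rules whose expected error cell is nearly empty — as happens
  when one gene's states are strongly unbalanced — fire spuriously with
  $\nabla = 1$ on two or three samples, and no Monte-Carlo null can match
  the z p-value there. Guarded rules are reported non-testable rather
  than significant.
* **Monte-Carlo oracle.** The z-test's null is
  $\mathrm{Binomial}(N, \hat K)$, i.e. independence *with the observed
  marginal frequencies*. The matching simulation oracle redraws both state
  vectors iid from those frequencies and uses the mid-p convention
  (half-weight on ties), which matches a no-continuity-correction normal
  tail to first order. A one-vector label permutation would instead give a
  hypergeometric null whose variance can be several-fold smaller — a
  different test than the one specified by the z formula. Oracle tables in
  the tests are drawn with margins in $[0.3, 0.7]$, the regime
  mean-dichotomized expression actually produces.
* **Ties at the dichotomization mean** go down ("upregulation" read as
  strict exceedance). Degenerate (constant) state vectors produce no edges
  rather than errors.
* **3-year ROC cutoff.** The outcome is death within 36 months; patients
  censored before 36 months carry no 3-year outcome and are excluded from
  the ROC. The cutoff maximizes the Youden index over observed scores
  (`score >= threshold` = high risk), ties resolved toward the lower
  threshold. Both the outcome definition and the optimality criterion are
  reconstructions of "best prediction on the 3-year ROC curve" and are
  exposed as arguments.
* **k-NN diagnosis** uses $k = 1$, Euclidean distance, and per-gene
  standardization by frozen training mean/sd (the standardization is a
  package addition, toggleable).
* **Odds ratios** use the Woolf logit interval with the Haldane–Anscombe
  +0.5 correction when a cell is empty (flagged).
* **Risk-group association** uses Pearson's χ² without continuity
  correction, with an expected-count warning below 5.

## 5. The synthetic study design

The generator (`cohort_config()`, `generate_expression_cohort()`)
emulates the structure the analysis assumes, with every default chosen
once, a priori:

* **Cohorts** default to 150 smokers / 150 non-smokers — balanced for
  power; `emulate_paper = TRUE` switches to the motivating study's 149/20
  imbalance. Train and test cohorts generated from one configuration share
  gene-level structure (baselines, planted rules) and differ in samples,
  which is what frozen-mean dichotomization of a test cohort requires.
* **Hubs and drivers.** Within each smoking group the six hub genes follow
  a shared latent driver state. This is not incidental: a single signature
  gene can only be coexpressed with all six hubs simultaneously if the
  hubs are mutually coherent. Hub–hub edges appear in both group networks
  and are therefore never differential.
* **Planted signature genes** follow their assigned rule against the
  driver in their own group (default rules alternate the two equivalence
  forms; all six types are supported and exercised via
  `plant_rule_states()`), with a violation probability of 0.02 per
  sample, and are *silent* in the other group: baseline expression with a
  reduced noise sd (0.15 vs 0.5 log2 units — a silenced gene varies
  less). Silence matters statistically: the silent group's dichotomized
  states are nearly degenerate, which suppresses the ~10% per-pair chance
  edge rate that would otherwise destroy all-hub adjacency in the
  off-group network for a large fraction of runs.
* **Expression** is baseline + `effect_size_delta` × state + Gaussian
  noise, baselines uniform on 5–9 log2 units, delta 1.5 (a 2.8-fold
  change, typical for strong smoking-induced genes).
* **Survival** is exponential with hazard
  $h_0 \exp(\beta \cdot \text{risk})$, risk being the *oriented* mean
  state of the group-active planted genes (a gene planted in opposition
  to the driver contributes $1 - s$, so oppositely-planted genes do not
  cancel). Defaults: $h_0 = 0.02$/month, $\beta = \log 4.5$ (full pathway
  activation comparable to a two-stage hazard contrast in NSCLC), 60-month
  horizon, 10% dropout. Dropout-flagged samples are recorded censored at a
  uniform fraction of their follow-up; this guarantees the degenerate
  contract (censoring rate 1 means everything is censored) at the cost of
  mild informativeness, negligible at the default rate.
* **Diagnosis cohorts** shift the signature genes by delta in cancer
  samples, all other genes unshifted.
* **Truth annotations** contain one planted pathway (hubs + signature
  genes) so every planted pair is TP, plus decoy sets whose per-set
  membership probability is calibrated so two annotated background genes
  share a set with a chosen probability $\rho$; a configurable fraction of
  genes can be left unannotated to exercise ND labels.

What the generator deliberately does **not** emulate: probe-level
measurement, batch and multi-institution effects, correlated background
structure, non-exponential survival, and informative missingness. Passing
tests therefore certify the machinery — recovery of planted structure
under the stated noise model — not performance on real microarray data,
where background co-regulation would inflate the candidate networks and
the screens' raw-p conventions would pass many more genes.

## 6. Problem sizes used by the checks

The test suite and acceptance script run at the defaults above: 213 genes
× 300 samples per cohort, 20 independent seeds for signature recovery, 200
label permutations for the FDR, 20 subsampling iterations for stability,
100 seeds for the survival-recovery checks, 10,000 Monte-Carlo draws per
oracle table. Structural unit tests use reduced cohorts (40 background
genes, 120 per group) with a proportionally strengthened survival effect,
since marginal screen power at small $n$ is not what those tests are
about.

## 7. Known limitations

* The prediction-logic z-forms are a reconstruction; a different original
  parameterization (e.g. a variance estimate for $\nabla$ itself) would
  shift borderline edges.
* With `min_scope = 0` the scope test never bins an edge; the original
  software's actual threshold is unpublished.
* The equivalence rules' exact calibration means the per-pair chance edge
  rate is ~$2\alpha$, so single-cohort networks are noisy by construction;
  the method's strength is the differential + cross-cohort validation
  chain, not per-edge inference.
* Multivariate Cox output assumes the covariate coding described in
  `multivariate_cox()` (binary gender/age>60, 3-level stage and
  differentiation with first-level reference); other codings are the
  caller's responsibility.
* `run_full_pipeline()` is sequential; the permutation FDR dominates the
  runtime and scales linearly in permutations × gene-pairs.
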