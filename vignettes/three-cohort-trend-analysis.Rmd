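---
title: "Methods: three-cohort trend analysis for aging and Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-cohort trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tritrend` analyses a three-cohort brain RNA-seq design — Young, Old and
Old-with-AD (OAD) — to separate expression changes attributable to normal
aging from changes attributable to disease. This vignette documents the
statistical model of each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the problem was genuinely open. No empirical claim is
made here beyond what the test suite and `scripts/acceptance.R` compute.

## Differential expression

Each of the three comparisons (YoungVsOld, OldVsOAD, YoungVsOAD) is a
two-cohort negative-binomial Wald test, written from first principles rather
than wrapped from an existing engine, so that its behaviour is fully pinned
by this package's tests:

* **Normalization.** Median-of-ratios size factors: for sample $j$,
  $s_j = \mathrm{median}_g\, k_{gj} / (\prod_{j'} k_{gj'})^{1/m}$ over genes
  with strictly positive counts in every sample. Strict mode: if no such gene
  exists the function errors instead of inventing a pseudo-reference, because
  a silent fallback changes the estimand.
* **Dispersion.** Per-gene method of moments on normalized counts, pooled
  across the two cohorts with degree-of-freedom weights, using
  $\widehat\alpha = (v - m\,\overline{1/s})/m^2$ (from
  $\mathrm{Var}(K/s) = \mu/s + \alpha\mu^2$), clamped to $[10^{-8}, 10]$.
  There is deliberately no shrinkage, no outlier refitting and no independent
  filtering: the goal is a transparent test whose operating characteristics
  are measured on synthetic data, not numerical equivalence with any
  particular production tool.
* **GLM and test.** $\mu_{gj} = s_j \exp(\beta_0 + \beta_1 x_j)$ with
  $x_j = 1$ for the test cohort; IRLS with weights $\mu/(1+\alpha\mu)$, at
  most 100 iterations, absolute deviance tolerance $10^{-8}$ (an absolute
  criterion leaves the estimate within $\sim 10^{-8}$ of the optimum, which
  the Poisson-limit oracle test requires); linear predictors are clamped to
  $\pm 30$ so cohorts with all-zero counts converge gracefully to a huge but
  finite fold change with a correspondingly huge standard error. The Wald
  statistic is $\beta_1/\mathrm{SE}$ with
  $\mathrm{SE}^2 = (\sum_{ref} w)^{-1} + (\sum_{test} w)^{-1}$, two-sided
  normal p-value, and $\log_2$FC $= \beta_1/\ln 2$ oriented
  test-over-reference with the younger/healthier cohort as reference.
* **Multiplicity.** Benjamini–Hochberg is implemented by its definition
  ($q_{(i)} = \min_{j\ge i} p_{(j)} m / j$, clipped at 1) and verified
  against a definitional oracle. Genes with zero counts across the
  comparison, or non-converged fits, are flagged untested and excluded from
  the BH family.
* **DEG filter.** Strictly $q < \alpha$ (default 0.05; a gene at exactly
  0.05 is excluded) *and* protein-coding per the annotation; unannotated
  genes are treated as non-coding with a warning rather than guessed.

## Trend crossing

The three DEG sets are crossed into the seven Venn regions, and every gene's
membership triple plus fold-change signs is mapped to exactly one archetype.
The mapping is total: patterns never reported in the motivating study
(discordant pairwise classes, triple-intersection genes) are representable
labels rather than errors, so observations like "no gene is significant in
all three comparisons" remain testable properties instead of hard-coded
assumptions. Magnitudes are ignored: classification is by trend only. The
headline archetype is `reversal` — significant with opposite signs in
YoungVsOld and OldVsOAD, absent from YoungVsOAD.

## Over-representation

Enrichment of a region's genes in a gene-set collection uses the one-sided
hypergeometric upper tail $P(X \ge k)$ (Fisher's one-sided exact test), the
standard choice when only membership lists are available. The background is
a parameter; the pipeline uses the protein-coding genes actually *tested* in
both comparisons that define the region, because that is the family from
which the query was drawn — a whole-genome background would overstate
significance. Sets with fewer than `min_set = 3` in-background members are
skipped (the smallest reported pathways in this design have three genes);
BH runs across the tested sets of the collection.

## Network hubs

Edges are kept when *any* requested evidence channel scores at least
`max(min_score, 1)`; the defaults are the curated channels `experiments` and
`database` with `min_score = 1` (any positive curated evidence), since the
motivating analysis names channels but no score cutoff. Networks are the
undirected simple subgraphs induced on a comparison's DEG list, with
unconnected DEGs dropped. Betweenness is exact and unweighted (shortest
paths carry no scores because no weighting scheme is defined for them),
endpoints excluded, unordered pairs counted once, normalized by
$(n-1)(n-2)/2$; pairs in different components contribute zero. Hubs are
nodes with betweenness z-score strictly above 1.96, standardized with the
*population* standard deviation over the network's nodes — the "upper 2.5%
of a normal" reading; the population/sample distinction is immaterial at
network scale and is pinned for determinism. A zero standard deviation
selects nothing (logged) rather than erroring. Shared hubs are the
intersection of selections across networks, sorted lexicographically.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions:

* cohorts of 8 Young / 10 Old / 12 OAD samples, one female per cohort;
* 3000 genes with log-normal baseline means (location $\log 200$, scale 1,
  truncated below at 1 — a plausible bulk-RNA-seq depth profile);
* negative-binomial counts with dispersion $\alpha = 0.05$
  (variance $\mu + \alpha\mu^2$), which gives realistic power at these
  sample sizes for effects of $|\log_2\mathrm{FC}| \gtrsim 0.8$;
* per-sample size factors uniform on $[0.7, 1.4]$ multiplied into the means,
  so normalization is genuinely exercised;
* planted archetypes in deterministic blocks of
  $\lfloor \text{fraction} \times n \rfloor$ genes:
  5% reversal ($\log_2$FC $-1.5$ aging, $+1.2$ disease — the magnitude range
  of the published sphingolipid genes), 5% aging-concordant ($-0.85$) and 5%
  AD-concordant ($+0.8$), remainder null. Cohort means follow
  $\mu_{Old} = \mu_{Young} 2^{\mathrm{lfc}_{aging}}$,
  $\mu_{OAD} = \mu_{Young} 2^{\mathrm{lfc}_{aging}+\mathrm{lfc}_{ad}}$.

Gene-set collections contain one planted set (all genes of a designated
archetype) plus uniform random decoys (default 50 sets of 10–50 genes).
Interactomes partition the members into communities (default 3) with
Erdős–Rényi edges inside each community and none between them; every bridge
gene connects to all other nodes, so all inter-community shortest paths run
through bridges and every bridge's exact betweenness strictly dominates
every non-bridge — which makes hub recovery checkable against construction
rather than against another heuristic. Bridge z-scores exceed 1.96 whenever
bridges are a small minority (roughly fewer than one node in five).

All randomness flows from one integer seed fanned out into per-artifact
substreams, so identical inputs give bit-identical files and adding one
artifact never perturbs another.

**What the simulator does not emulate:** sex effects (sex is recorded, never
modelled — the real design had 3 females among 30 samples and did not model
sex either), batch effects, gene–gene count correlation, length/GC biases,
read-level noise, and the topology of a real interactome (scale-free degree
distributions, overlapping pathways). Passing recovery tests therefore shows
the *inference chain* is correct under its stated model, not that the model
captures every property of real brain RNA-seq.

## Pipeline

`run_pipeline()` executes the stages in order from one YAML configuration
(either file paths or a `simulate:` block, never both), writes every stage
artifact as plain text under `outdir`, and closes with a YAML summary (Venn
counts, archetype counts, enrichment toplines per region, network sizes and
hub counts, shared hubs) that is recomputable from the artifacts on disk.
Networks are built for the YoungVsOAD and OldVsOAD comparisons — the two
disease-bearing contrasts whose shared central genes are the analysis's
final readout. Stage failures abort with the stage name; the CLI
(`inst/cli/tritrend.R`, verbs `run` and `simulate`) maps configuration
errors to exit code 2 and stage failures to 3. Reruns with the same
configuration and seed are byte-identical.

## Verification sizes and numerical choices

The oracle tests compare exact betweenness against an independent
brute-force enumeration of all shortest paths on: every labeled graph on up
to 5 nodes (728 connected graphs at $n=5$), 40 seeded random connected
graphs at $n = 6{-}7$, and 50 seeded random graphs up to $n = 8$ including
disconnected ones — sizes chosen so the whole catalogue runs in seconds
while covering every structural feature the Brandes-style computation must
honour (multiple shortest paths, bridges, isolated pairs). BH and the
hypergeometric tail are compared to definitional/combinatorial oracles on
100 random p-vectors ($m \le 20$) and every configuration with $N \le 12$.
Error control and recovery are measured at the design scale (8/10/12,
3000 genes): the null false-call rate at $q<0.05$ stays below 1% per
comparison across 10 seeds, and reversal recall/precision against planted
truth are required to reach 0.7/0.8 — recall is limited by reversal genes
whose residual YoungVsOAD shift ($-1.5+1.2 = -0.3$) occasionally reaches
significance, moving them to the `triple` label.

## Known limitations

* The DE engine targets transparency, not equivalence with shrinkage-based
  engines; at $n \le 12$ per cohort its unshrunk fold changes are noisier
  than moderated ones, and genes with one all-zero cohort get boundary
  estimates with very large standard errors rather than moderated values.
* Dispersion is estimated per gene without information sharing; at these
  sample sizes that costs some power relative to empirical-Bayes approaches
  (the recovery criteria above are met regardless).
* The enrichment background must be supplied thoughtfully; defaults are
  sensible for this pipeline but no background is "correct" in general.
* Betweenness is exact, so very large interactomes (≫10⁵ edges) will be
  slow; the intended scale (DEG-induced subnetworks, ~10³ nodes) is fast.
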