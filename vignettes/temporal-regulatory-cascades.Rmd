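---
title: "Temporal regulatory cascades: model, parameters and design notes"
author: "trcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal regulatory cascades: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcascade)
```

## The problem

Differentiation time courses are driven by regulatory waves: small sets of
transcription factors (and regulatory RNAs) that switch on at one stage,
activate the next wave, and fall silent. Given

* a time-series expression matrix (genes x samples, each sample annotated
  with a time point and replicate), and
* a background regulatory network — a precomputed directed
  regulator → target graph derived from binding-site predictions,
  independent of any expression dataset,

`trcascade` identifies the regulators *specific to each time point* and
arranges them into a **temporal regulatory cascade (TRC)**: a stage-ordered
graph whose columns hold the stage-specific regulators and whose edges are
the background-network interactions within a column and from each column to
the next.

## The model

**Template peak patterns.** For a design with $T$ time points, the template
library holds $T$ one-hot profiles: template $s$ has expression 100 (percent
of peak) at time point $s$ and 0 elsewhere. A gene's replicate-averaged
profile $x = (x_1, \dots, x_T)$ is scored against every template by Pearson
correlation. Because Pearson correlation is invariant to positive affine
transforms, correlating against a one-hot template has a closed form:

$$ r_s \;=\; \frac{x_s - \bar{x}}{\sigma_{\mathrm{pop}}(x)\,\sqrt{T-1}}, $$

with $\sigma_{\mathrm{pop}}$ the population (divide-by-$T$) standard
deviation. Summing over stages gives a conservation law for every
non-constant profile:

$$ \sum_{s=1}^{T} r_s^2 \;=\; \frac{T}{T-1}. $$

Both identities are verified against `stats::cor` to near machine precision
in the test suite; the 100-vs-1 encoding of the template is cosmetic.
Constant (zero-variance) profiles have no defined correlation; they are
silently excluded and counted in the run log.

The conservation law has a practical consequence: at small $T$ a profile can
exceed a correlation floor for two stages at once (e.g. $T = 2$ forces
$r_1 = -r_2 = \pm 1$). Since cascade columns are meant to be *unique* to a
time point, each gene is assigned only to its argmax stage, ties broken
toward the earlier stage.

**Filtering parameters.** Three knobs control the cascade
(`trc_params()`):

| parameter | meaning | default | units |
|---|---|---|---|
| `min_e` | expression floor: a gene must exceed it *strictly* in at least one raw replicate/time point | 4 | expression units of the matrix |
| `min_c` | minimum correlation of a gene to its best template | 0.6 | dimensionless, $[-1,1]$ |
| `max_s` | cap on regulators per stage column | 10 | count |

`min_e` is tested on the raw, *uncollapsed* matrix — a single replicate
above the floor rescues a gene — and removes genes that are lowly expressed
even at their peak, whose peak shape is therefore mostly noise. Defaults
suit normalized RNA-seq expression on the order of 1–100; for raw counts
`min_e` should be rescaled (e.g. 30 for a deeply sequenced course). `min_c`
at 0.6 demands a clearly dominant peak; `max_s` bounds the cascade at
`max_s` × $T$ nodes so it remains visually inspectable. Only genes in the
**regulator universe** — the source nodes of the background network — are
eligible; everything else, however sharply it peaks, is left to the
enrichment universe.

**Cascade assembly.** Time points with at least one surviving gene form
columns in time order. All background edges between members of one column
become *within* edges; all edges from a column to the **next retained
column** become *cross* edges — an empty stage is skipped entirely, so the
cascade stays connected across a silent time point. Node indegree and
outdegree are computed on the cascade graph only. Interaction patterns are
labelled per edge (`classify_interactions()`): a one-way within-stage edge
supports causality; a reciprocal pair cannot be oriented by correlation
alone; a cross edge is a time-lagged prediction. Per node, the same-stage
and next-stage out-fan counts rank potential master regulators.

**Building the network from binding predictions.** When no ready-made edge
list exists, `build_network()` consumes a scored binding-prediction table
(PWM id, target gene, match score; one row per predicted site) plus a
PWM → regulator-gene map. Per PWM, sites are ranked by score and the best
fraction retained: `min(n, max(1, ceiling(f * n)))` rows for a PWM with `n`
sites at fraction `f` (default 0.05). The ceiling-with-floor-1 rule
guarantees every scanned PWM contributes at least one site; ties at the
cutoff break by (score desc, target symbol asc, input order) so rebuilds
are identical. A PWM mapped to several regulator genes fans out to all of
them — motif models are frequently shared within TF families — and
duplicate edges collapse.

**Per-stage enrichment.** Each column is tested for annotation-term
over-representation with the one-sided Fisher's exact test (hypergeometric
upper tail), Bonferroni-corrected over the number of terms actually tested
— terms with at least one overlapping gene; terms the column never touches
cannot be enriched and would only inflate the correction. Significant terms
are ranked by fold enrichment $(k/n)/(K/N)$. The universe is every dataset
gene that passes `min_e` and carries at least one annotation: conditioning
on detectability, the standard choice for expression-derived sets. The
annotation map is taken flat; no ontology-graph propagation is applied.

## Null models

Three dataset randomizations (`shuffle_profile_assignment()`,
`permute_matrix()`, `random_dataset()`) plus one ablation
(`unrestricted_cascade()`) probe whether stage-specific enrichment is a
property of the data or an artifact of the pipeline:

* **profile reassignment** permutes gene labels over profile rows (all
  genes, or regulators only) — peaks persist but land on random genes;
* **matrix permutation** shuffles every cell — the value multiset is
  conserved exactly, all profile structure is destroyed;
* **random values** redraws the matrix i.i.d. (default uniform on
  $[0, \max]$) on the template's design;
* the **unrestricted** run lets all genes, not just network sources,
  compete for columns.

All generators take an explicit seed, record it, and conserve the relevant
multisets exactly; the expectation — borne out on the synthetic benchmark —
is that planted stage terms are significant in the real data and not after
randomization.

## The synthetic benchmark

`generate_planted()` draws a fixture with known truth: per stage,
`n_planted_per_stage` regulators carry a one-hot-plus-noise profile
(baseline 5, peak 100, additive Gaussian noise truncated at zero);
background genes carry flat profiles around log-normal baselines
(`meanlog = log(20)`, `sdlog = 1`), so the expression floor has realistic
bite; the network contains the planted within- and next-stage edges plus
random decoys, with every planted gene guaranteed an outgoing edge (source
status); annotations give each stage a dedicated term plus random terms.
With `noise_sd = 0` each planted profile is an exact affine image of its
template (correlation exactly 1) and backgrounds are constant (excluded),
so the pipeline provably recovers the truth with 100% precision and recall;
rising noise degrades recall gracefully, which the tests check as a
monotone trend over seeds.

The default scale — 5 time points on an irregular day grid, 2 replicates,
6 planted regulators per stage, 1200 background genes of which 300 are
decoy regulators, 150 random annotation terms, stage terms holding the 6
planted regulators plus 12 non-regulatory members — was chosen to keep
three structural ratios in the regime of a genome-scale experiment, scaled
down for speed:

1. *seats vs pool*: the cascade offers at most `max_s` × $T$ = 50 seats to
   a pool of 330 regulators (~15%); a pool barely larger than the seat
   count would seat nearly every regulator under any randomization, and
   chance co-seating of term members would mimic enrichment;
2. *term composition*: ontology terms are dominated by non-regulatory
   members, so a stage term can reach a cascade column only through its
   planted regulators — terms made purely of regulators would be trivially
   reachable by shuffled columns;
3. *annotation density*: most expressed genes carry annotations, keeping
   the per-column tested-term count (the Bonferroni $m$) realistic; under
   sparse annotation a column collapses to one or two annotated genes and
   a single gene can "enrich" its term at $m = 1$.

These are structural properties of the data the method targets, not tuning
knobs; the fixture does **not** model library-size effects, count
dispersion, correlated replicate noise, multi-peak or ramping profiles, or
annotation hierarchy — so passing tests demonstrate correctness of the
machinery and of the null logic at realistic proportions, not performance
on any particular real dataset.

## Numerical and degenerate-input choices

* Pearson correlation on replicate-mean profiles is the template-matching
  convention; whether per-replicate profiles should be correlated instead
  is undetermined by the method's definition — averaging first is this
  package's choice and is applied consistently.
* `min_e` is a strict inequality on raw values; `min_c` is a non-strict
  bound applied to the argmax-stage correlation (a gene first picks its
  stage, then must clear the floor there).
* Ranking ties at the `max_s` cutoff break by (correlation desc, symbol
  asc); all outputs are therefore byte-reproducible run to run.
* Gene symbols are matched after trimming and upper-casing (HGNC
  convention); original spellings are preserved for display.
* A single time point is a design error (correlation undefined); a
  zero-variance profile is an exclusion, not an error; an empty stage is a
  skipped column, not a break in the cascade.
* Expression values must be finite and non-negative; duplicate gene rows
  (after case normalization) are rejected rather than silently merged.

## Scope limits

The package consumes the background network; it does not scan genomes for
binding sites, compute match scores, or apply conservation filtering. The
template library is fixed to single peaks — regulators active across
several time points are invisible to it by construction. Enrichment
supports flat annotation maps only, with Bonferroni (no FDR variants). The
problem sizes used in the shipped tests (up to ~1,230 genes, 5 stages, 100
random structural fixtures, 20-seed null panels) were chosen so the whole
suite documents the method at interactive speed.
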