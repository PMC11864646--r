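---
title: "Methods: the CMA activation score, KFERQ-like motif scanning and median-ratio quantification"
author: "cmatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CMA activation score, KFERQ-like motif scanning and median-ratio quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmatools)
```

Chaperone-mediated autophagy (CMA) degrades cytosolic proteins carrying a
KFERQ-like pentapeptide, delivered by the HSC70 chaperone to the lysosomal
receptor LAMP2A, the pathway's rate-limiting factor. `cmatools` implements
the computational layer used to study CMA in species without a routine CMA
activity assay — in particular salmonids, whose duplicated genome carries
paralogous copies of most network genes. This vignette documents the models
and the numerical and design choices behind each module; the package's tests
and the acceptance script compute every empirical claim made here.

## The CMA activation score

The score aggregates the expression of a configurable CMA gene network into
one signed scalar per sample. Each network gene $g$ carries

* a **weight** $w_g > 0$: genes in a paralog family of $n$ members get
  $1/n$, so a family contributes the same total weight regardless of how
  many duplicated copies a genome retains; the LAMP2A family is the single
  exception and carries a family total of exactly **2** (it is the
  rate-limiting step), split across its paralogs in proportion to their
  measured relative contribution to CMA activity when such measurements
  exist, and equally otherwise;
* a **direction** $d_g \in \{+1, -1\}$: whether the gene promotes or
  represses CMA.

For sample $s$ the score is the weighted signed sum

$$\mathrm{CMA}_s = \sum_{g \in \text{used}(s)} w_g \, d_g \, t(x_{gs}),$$

where $t$ is an expression transform. Some descriptions of this kind of
score call it a weighted *average*; the implementation computes the
weighted *sum* and offers `average = TRUE` (division by $\sum_g |w_g|$) as
an option, since the two differ only by a positive constant and therefore
agree on every comparison.

### Transforms

* `log2_fold_change` (default): $t(x) = \log_2(x / \tilde{x}_g)$ with
  $\tilde{x}_g$ the geometric mean of gene $g$ in the declared reference
  group. The reference group is centred at score 0 by construction and the
  score is additive in log2 effect sizes — doubling one gene's expression
  moves the score by exactly $w_g d_g$.
* `fold_change`: $t(x) = x / \tilde{x}_g$. This is the only transform with
  a finite value for an *undetected* (zero) transcript, which contributes
  0 instead of its baseline 1 — a knocked-out gene therefore lowers the
  score by exactly $w_g d_g$ deterministically. Knockout analyses use this
  transform for that reason; a zero under the log transform has no finite
  image and can only be excluded, which would erase the knockout signal
  entirely.
* `zscore`: per-gene standardisation over all samples, for sensitivity
  analysis when no natural reference group exists.

Whether expression should be standardised per gene before weighting, and
whether sample-level or group-level values feed the sum, are genuinely open
choices; the package computes sample-level scores under the transforms
above and documents the default rather than asserting it as canonical.

### Missing data

Expression tables preserve missing cells as missing (a tissue that does not
express a transcript is not a zero measurement). Genes missing in a sample
are excluded from that sample's sum; under the default
`exclude_renormalize` policy the weights actually used are rescaled so
their absolute sum equals the full network's, keeping scores comparable
across tissues with different detected subsets (a tissue lacking one
transcript is not biased toward 0). Undetected (exact zero) values under
the log transform are likewise excluded, with a warning.

### Group comparison

Two-group designs use a two-tailed equal-variance Student t-test on the
per-sample scores; tissue-by-condition designs use a two-way ANOVA with
tissue, condition and their interaction. Both are delegated to base R
(`t.test`, `aov`); the package only organises inputs and reports the
condition effect.

## KFERQ-like motif scanning

A pentapeptide window is read through an **anchor** residue at window
position 1 or 5 plus a composition constraint on the remaining four "body"
residues, with residue classes

| class | residues |
|---|---|
| hydrophobic | F, I, L, V |
| positive | K, R |
| negative | D, E |
| phospho-acquirable | S, T, Y |

* **Canonical**: anchor Q; body with 1–2 hydrophobic, 1–2 positive,
  exactly 1 negative, and nothing outside these classes.
* **Phosphorylation-generated**: anchor Q; body with no D/E, exactly one
  S/T/Y standing in for the negative charge once phosphorylated, 1–2
  hydrophobic, 1–2 positive, nothing else.
* **Acetylation-generated**: K in the anchor position in place of Q
  (acetyl-lysine mimics the glutamine amide); the body satisfies the
  canonical composition. The anchor K does not count toward the body's
  positive quota.

Both anchor readings are evaluated; every satisfied class is reported, with
no precedence between classes (class proportions are reported separately
downstream). A Q in a body position invalidates that reading; X or any
other non-standard character invalidates the window. Coordinates are
0-based, windows half-open. Whether C or W should count as hydrophobic and
whether N may substitute for Q vary between published conventions; this
implementation uses the closed sets above, and its rule table is checked
exhaustively — the classifier agrees with an independently written
brute-force evaluator on all $20^5 = 3.2$ million pentapeptides in the test
suite.

## Label-free quantification by median-ratio fitting

Starting from a long table of per-ion intensities (protein, ion, run,
abundance) — upstream spectral search, validation and cross-assignment are
out of scope — each protein is quantified in three steps:

1. **Pairwise ratios**: for every run pair $(r, s)$, the protein ratio
   $M_{rs}$ is the median over ions observed in *both* runs of the ion
   ratio $a_{ir}/a_{is}$ (even counts: mean of the two middle values).
   $M_{sr} = 1/M_{rs}$ is set by construction (the median of inverted
   even-count ratios is not otherwise the inverse of the median). Pairs
   sharing no ion are left undefined, not imputed.
2. **Least squares in log2 space**: the fitted log2 abundances $x_r$
   minimise $\sum_{(r,s)} (x_r - x_s - \log_2 M_{rs})^2$ over defined
   pairs. Log space makes up- and down-ratios symmetric and the problem
   linear with a pure additive gauge freedom. The defined-pair graph must
   be connected; a disconnected graph is an error naming the components.
3. **Rescaling**: the gauge is fixed by scaling $2^{x_r}$ so the per-run
   abundances sum to the protein's total observed ion abundance across
   runs.

Zeros are treated as missing throughout the log-space steps. On noise-free
synthetic data the fitted ratios reproduce the true run factors to
floating-point accuracy, and under lognormal ion noise the ratio error
shrinks as the ion count grows (both checked in the tests).

**Differential abundance** between two groups of runs uses, per protein,
the log2 fold change (group 2 minus group 1 mean of log2 abundances) and a
two-tailed pooled-variance Student t-test on the log2 values. Proteins
left with fewer than 2 usable runs in either group are skipped and logged;
a comparison with zero variance in both groups is flagged `degenerate`
(p = 1 when the fold change is also 0, `NA` otherwise, and `ns` in
classification). Calls use `p < 0.05` and fold change `> 1.41` (i.e.
$\sqrt 2$, `< 1/1.41` for down-calls) by default; a stricter cut of 2 also
circulates for this kind of data and is available via `fc_threshold`.
Summary percentages are reported to one decimal. No multiple-testing
correction is applied by default, mirroring the raw-p convention of the
volcano-style analysis this reproduces; `p_adjust` enables one.

## qPCR expression arithmetic

The ΔCt method assumes perfect doubling per cycle,
$2^{-(Ct_\text{target} - Ct_\text{ref})}$; the E-method replaces 2 with
per-assay amplification efficiencies in $(1, 2]$,
$E_t^{-Ct_t}/E_r^{-Ct_r}$, evaluated in log space. With both efficiencies
at 2 the two coincide to machine precision. Fold induction divides each
sample's ratio by the *geometric* mean of the reference group (Ct-derived
ratios are log-scale quantities), so the reference group's geometric mean
of outputs is exactly 1; undetectable transcripts give fold 0 and are
flagged, never dropped. The reference gene is a required input rather than
a default, because normalisers legitimately differ between tissues and
experiments. The lysosomal uptake arithmetic, uptake = association −
binding, returns negative (noise-dominated) differences flagged rather
than clamped.

## Motif-class enrichment

Per protein set (up-regulated, down-regulated, background), the report
gives the proportion of proteins carrying at least one hit of each class —
a protein with many hits of one class counts once. The association between
two sets and a class is summarised by the sample odds ratio $(ad)/(bc)$
(infinite when $bc = 0$, flagged) and a two-sided exact p-value obtained
by summing, over the hypergeometric distribution conditional on the
margins, the probabilities of all tables at most as probable as the one
observed. That two-sided convention is stated explicitly because exact
two-sided conventions differ between tools; no continuity correction is
used, as the sets involved are small. The test-suite oracle enumerates all
2×2 tables with margins up to 30.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and an integer seed
(R's default Mersenne-Twister stream, restored on exit), and return ground
truth beside the data.

* **Proteomes** (`generate_proteome`): backgrounds are drawn from the
  20-letter alphabet minus {Q, K, R} — with no anchor residue and no
  positive residue available, no background window can satisfy any class,
  so the background is provably motif-free. Planted motifs are flanked by
  four glycines on each side; any window overlapping a planted motif
  without equalling it contains a body glycine and is invalid. The
  scanner therefore finds exactly the planted hits. Real proteomes have
  amino-acid usage nowhere near this restricted; the generator validates
  the scanner's bookkeeping, not its biological hit rate.
* **Network expression** (`generate_network_expression`): control samples
  at baseline 1 with lognormal noise of 0.3 log2 units — a typical
  inter-individual spread for tissue qPCR panels; knockouts zero one gene
  in the treated group (the undetectable-transcript situation), stressors
  multiply the positive network elements by a fold (default 2) in the
  treated group. Group sizes default to 7 per group, a realistic cohort
  for a fish knockout comparison (6 per group is used for the
  stressor-style runs in this package's own studies). Real stress
  responses are not uniform across positive elements and include
  gene-specific magnitudes and correlations the generator does not model;
  the closed-form expected score differences (−$w_g d_g$ for a knockout
  under the fold-change transform, $\log_2(\text{fold}) \sum w d$ over
  targets under log2) are exact only at zero noise.
* **Ion abundances** (`generate_ion_abundances`): ion intensity =
  lognormal ion base × true protein run factor × lognormal noise; cells
  are removed at the requested missing rate in random order, skipping any
  removal that would orphan an ion or disconnect a protein's run graph,
  so the achieved rate can fall below the request at extreme settings.
  Real missingness is intensity-dependent (censoring), which is
  deliberately not modelled: recovery tests need missingness that is
  ignorable by construction.
* **qPCR tables** (`generate_qpcr_table`): Ct = baseline − log2(fold) +
  normal noise in cycles; the reference gene sits at the baseline under
  the same noise model.

Passing tests on these generators demonstrates the arithmetic contracts —
exact recovery without noise, correct directions and calibrated error
rates with it — not performance on real tissue data.

## Problem sizes and numerical conventions

The test suite runs the exhaustive 3.2-million-pentapeptide rule check,
exact-test enumeration over all margins ≤ 30, 100 knockout and 100
stressor simulations at the generator defaults, a 1000-protein null for
the type-I error of the differential test, and quantification recovery at
10 proteins × 6 runs × 5 ions (noise-free) plus 3/10/30-ion noise ladders
pooled over 20 seeds; these sizes make every check exact or statistically
stable while keeping the default suite in the minutes range. Other fixed
conventions: even-count medians average the two middle values; the
least-squares gauge is pinned to the first run before rescaling;
`lamp2a_contributions` must sum to 1 within 1e-9; exact-test tie
comparisons use a relative tolerance of 1e-7 on table probabilities (the
same guard base R uses for this purpose); FASTA output wraps at 60
columns.

## Known limitations

* The score is a transcriptional proxy: it tracks the expression of CMA
  machinery, not measured lysosomal translocation, and no claim is made
  that it equals CMA activity.
* The motif rule table follows one published convention; tools differ on
  marginal residues (C, W, N substitution), and sequences containing
  ambiguity codes are conservatively unscannable at those windows.
* Quantification starts from an ion table; retention-time alignment and
  match-between-runs belong upstream.
* The network definition (gene list, directions, families, measured
  LAMP2A contributions) is an input; the package ships a small example
  network, not a curated species reference.
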