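# cmatools

Tools for assessing **chaperone-mediated autophagy (CMA)** from molecular
data. CMA selectively degrades cytosolic proteins that carry a KFERQ-like
pentapeptide motif, recognised by the HSC70 chaperone and delivered to the
lysosomal receptor LAMP2A — the pathway's rate-limiting factor. Measuring
CMA activity directly requires isolating CMA-competent lysosomes, which is
impractical in most non-mammalian models; `cmatools` implements the
computational proxies used instead, with salmonid-style duplicated genomes
(paralogous copies of most network genes) as the motivating case.

The package provides:

* **CMA activation score** — a weighted, signed aggregate of CMA network
  gene expression. Gene *g* contributes `w_g * d_g * t(x_gs)` to sample
  *s*, where `d_g = ±1` is the gene's direction of action, `t` an
  expression transform (log2 fold change to a reference group by default),
  and the weights follow the paralog rule: each member of an *n*-copy
  family gets `1/n`, except the rate-limiting LAMP2A family, which carries
  a family total of exactly 2 split by the paralogs' measured contribution
  to CMA (equal by default).
* **KFERQ-like motif scanner** — sliding-window classification of
  pentapeptides into canonical, phosphorylation-generated and
  acetylation-generated motifs, validated exhaustively against a
  brute-force rule oracle on all 20⁵ pentapeptides.
* **Label-free quantification** — per-protein pairwise median ion ratios
  between runs, reconciled by least squares in log2 space and rescaled to
  total ion abundance; two-tailed equal-variance t-tests on log2
  abundances with up/down calls at p < 0.05 and fold change > 1.41.
* **qPCR arithmetic** — ΔCt and efficiency-corrected E-method relative
  expression, fold induction versus a reference group's geometric mean,
  and the lysosomal association/binding uptake difference.
* **Enrichment statistics** — motif-class prevalence per protein set and
  exact 2×2 association tests.
* **Seeded synthetic-data generators** for every input (proteomes with
  planted motifs, network expression under knockout or stressor designs,
  multi-run ion tables, Ct tables), each returning ground truth.

All tabular IO is plain tab-separated text; a CLI
(`inst/scripts/cmatools`) exposes the pipeline stages
(`scan-motifs`, `cma-score`, `quant-proteome`, `enrich`, `simulate`).

## Worked example

Score a simulated stressor experiment (6 control vs 6 treated fish, the
network's positive elements doubled in the treated group) against the
bundled example network:

```r
library(cmatools)

net <- assign_weights(example_cma_network())
net[net$is_lamp2a_family, c("gene_id", "weight")]
#>      gene_id weight
#> 1 lamp2a_c31      1
#> 2 lamp2a_c14      1     # family total = 2: LAMP2A is rate-limiting

sim <- generate_network_expression(net, design = "stressor", fold = 2,
                                   n_per_group = 6, seed = 42)
ref <- names(sim$groups)[sim$groups == "control"]
scores <- compute_cma_score(sim$expr, net, reference_sample_ids = ref)
scores
#> CMA activation scores (log2_fold_change, weighted sum)
#>  sample_id      score n_genes_used
#>  control_1  0.3970267           12
#>  control_2 -0.1790749           12
#>  ...
#>  treated_1  6.7810005           12
#>  treated_2  6.4292823           12
#>  ...

compare_scores(scores, sim$groups)
#> CMA score comparison: two-tailed Student t-test
#>   control: mean -2.498e-16 (sd 0.722, n=6)
#>   treated: mean 6.537 (sd 0.834, n=6)
#>   mean difference 6.537, t = -14.516, p = 4.79e-08
```

The control group is centred at 0 by construction of the log2 fold-change
transform; the treated mean of ≈ 6.5 sits near the noise-free expectation
`sum of positive weights × log2(2) = 6`, and the t-test reports the
direction and strength of the shift.

Scanning a sequence for KFERQ-like motifs:

```r
scan_protein("MADKFERQILSSQKSLVTT", id = "demo")
#>   protein_id start pentapeptide           classes
#> 1       demo     3        KFERQ         CANONICAL
#> 2       demo    12        QKSLV PHOSPHO_GENERATED
```

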