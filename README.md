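# degbrin

Brain-region DEG co-occurrence networks and interpretable graph
convolutional classification of multi-region transcriptomes.

## What this package is for

Multi-region postmortem transcriptomic cohorts of Alzheimer's disease
profile the same subjects across many anatomical brain regions (normal
controls through definite AD). `degbrin` implements an analysis chain for
such cohorts, end to end and with synthetic ground truth:

* **Per-region differential expression** with empirical-Bayes variance
  moderation: gene-wise least squares per contrast, moderated statistic
  $\tilde t_g = \hat\beta_g / (\tilde s_g \sqrt{v_g})$ with
  $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, hyperparameters
  estimated by moment matching on $\log s_g^2$, Benjamini–Hochberg
  control, and DEG calling at $|\log_2 FC| > 0.585$ with adjusted
  $p < 0.05$.
* **DEG-BRIN** — the brain-region interaction network whose nodes are
  regions, edge weights $w_{ij} = |G_i \cap G_j|$ count the cross-region
  shared DEGs (restricted to genes differential in ≥ 2 regions), and
  self-loops $w_{ii} = |G_i|$ keep regional identity.
* **Tiered PPI hub analysis**: confidence thresholding at
  $\tau \in \{0.4, 0.7, 0.9\}$, degree and Freeman betweenness
  centrality, hubs = top 20% in both.
* **Hypergeometric gene-set enrichment** (upper tail, BH-adjusted)
  against a GMT collection.
* **An interpretable two-layer GCN classifier**:
  $H^{(l+1)} = \mathrm{ELU}(\hat A H^{(l)} \Theta^{(l+1)})$ with
  $\hat A = D^{-1/2} W D^{-1/2}$, trainable softplus gene/region
  importance gates, layer normalisation, global mean pooling and a
  softmax head; trained with cross-entropy, AdamW-style decoupled weight
  decay and early stopping, with analytic backprop verified against
  finite differences.
* **Ablations and interpretation**: matched random-topology and PPI-node
  control classifiers under paired seeds, gate/saliency importance
  rankings, gradient-distribution statistics, hub-overlap fractions and
  the region–gene–pathway triad table.
* **A synthetic cohort generator** with planted region-specific and
  cross-region differential expression and variances drawn from the
  scaled inverse-chi-square prior, so every stage has recoverable ground
  truth.

## Worked example

```r
library(degbrin)

cfg <- synthetic_config(
  n_genes = 600, n_regions = 5,
  subjects_per_group = c(CON = 30, MCI = 30, AD = 30),
  deg_per_region = 40, shared_fraction = 0.5,
  effect_size_log2fc = 1, seed = 11
)
co   <- generate_cohort(cfg)
degs <- degs_per_region(co$expr, co$samples)
print(degs)
#> Region DEG sets over 5 regions
#>   per-region DEG counts: 39 38 39 38 38
#>   universal list G (>= 2 regions): 38 genes

brin <- build_degbrin(degs)
print(brin)
#> weighted_graph: 5 nodes, 10 edges, 5 self-loops

fit <- degbrin_gcn(co$expr, co$samples, brin, degs$universal,
                   feature_mode = "masked", region_sets = degs$region_sets,
                   hidden_dim = 16, dropout = 0.3, max_epochs = 40,
                   patience = 10, seed = 1)
print(fit)
#> Interpretable two-layer GCN classifier (masked features)
#>   graph: 5 nodes, 10 edges
#>   input genes: 38, hidden: 16
#>   best epoch: 15 (val loss 0.2799)
#>   test accuracy: 0.9

summary(fit)$test_metrics  # per-class precision/recall/F1 on held-out samples
#>  class precision recall    f1 support
#>    CON     0.903  0.933 0.918      30
#>    MCI     1.000  0.833 0.909      30
#>     AD     0.824  0.933 0.875      30

importance_report(fit, mode = "gate_gradient")
#> Importance report (method: gate_gradient )
#> Top regions:
#>  rank                    label   score
#>     1 superior_parietal_lobule 0.00730
#>     2                  putamen 0.00642
#>     3              hippocampus 0.00623
#> ...
```

The cohort here plants 40 DEGs per region (half drawn from a shared
cross-region pool) at one log2 unit of effect; the DGE stage recovers 38
of the cross-region genes into the universal list, the DEG-BRIN has an
edge between every pair of regions that share recovered DEGs, and the
masked-feature GCN classifies held-out samples at 0.9 accuracy. Region
scores are saliency-weighted gate activations; with synthetic data the
rankings reflect how much recoverable signal each region's DEG set
carries.

A full pipeline (simulate → DGE → network → train → interpret, with a
content-hash manifest) is available as `run_pipeline(pipeline_config())`
or from the shell via `inst/scripts/degbrin.R`.

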