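# sscontrol

Sample-specific network construction and structural network control in R.

Bulk tumor samples and single cells are heterogeneous: the gene
interactions that drive one patient's state transition are not the ones
that drive another's. `sscontrol` implements the two-step analysis that
turns one expression profile into a set of *personalized driver genes*:

1. **Single-sample network construction** — infer, for each sample, a
   state-transition network of significantly perturbed co-expression
   edges, filtered and oriented by a prior interaction scaffold. Five
   statistics are provided:
   - **CSN** (cell-specific networks): the box statistic
     `rho_xy = n_xy/n − (n_x/n)(n_y/n)` with its normal independence
     null (`mu = 0`,
     `sigma = sqrt(n_x n_y (n−n_x)(n−n_y) / (n^4 (n−1)))`);
   - **SSN**: the single-sample perturbation of the Pearson correlation,
     `Z = |PCC_{n+1} − PCC_n| / ((1 − PCC_n²)/(n−1))`, one-sided normal
     p-value;
   - **paired SSN**: edges significant at 0.05 in exactly one of a
     patient's matched tumor/normal single-sample networks (XOR rule);
   - **SPCC**: per-sample z-score products
     `SPCC_ij^s = z_i(s) z_j(s)`, thresholded at `mean(S) + 2 sd(S)`;
   - **LIONESS**: leave-one-out linear interpolation
     `e_ij^s = N(e_ij^N − e_ij^{N−s}) + e_ij^{N−s}` on Pearson
     correlation, same threshold.
2. **Structural network control** — identify a minimum driver-node set
   on each sample's network:
   - **MMS**: unmatched nodes of a maximum matching on the node-split
     bipartite graph (linear structural controllability);
   - **MDS**: minimum dominating set
     (`x_i + Σ_{j∈N(i)} x_j ≥ 1`, minimize `Σ x_i`);
   - **DFVS**: minimum directed feedback vertex set plus source nodes
     (nonlinear feedback control of directed networks);
   - **NCUA**: minimum node set covering every edge of the bidirected
     network via its node–edge bipartite incidence (equivalently a
     minimum vertex cover).

Around this core the package provides a pinning-control simulator for
networked Lorenz oscillators (feedback controllers
`u_i = −k(x_i − x̄)` with `k = 1000` on the driver nodes; control
efficiency `|E|/|D|` over a 0.1–1.0 tolerance grid), a synthetic-data
generator with planted differential co-expression edges, Markov-chain
sampling of alternative minimum driver configurations, and the full
evaluation suite (F-measure, drug-combination AUC, Jaccard
consensus/robustness, per-sample controllability `1 − |D|/|G|`,
hypergeometric enrichment, uniform and degree-preserved randomization
baselines, centrality profiles, ARI, dark-gene metrics).

## Worked example

```r
library(sscontrol)

ref <- gen_reference_network(30, "erdos_renyi", 0.15, seed = 1)
sim <- gen_expression(ref, n_ref_samples = 60, n_case_samples = 4,
                      spec = truth_spec(n_planted = 6), seed = 1)
fit <- ssc(sim$expr, ref, construction = "SSN", control = "NCUA")
fit
#> Sample-specific network control fit
#>   workflow: SSN + NCUA (directed)
#>   samples: 4 (0 failed)
#>   drivers per sample: median 4.5 [2, 8]
#>   mean controllability: 0.605
summary(fit)
#> Workflow: SSN + NCUA
#>  sample n_edges n_drivers controllability
#>   case1      28         8       0.4666667
#>   case2      18         4       0.6923077
#>   case3      14         5       0.5454545
#>   case4       7         2       0.7142857
head(coef(fit), 4)      # driver recurrence across samples
#>   g9  g24   g1  g10
#> 0.75 0.50 0.25 0.25
precision_recall_f(fit$drivers[["case1"]]$drivers,
                   sim$truth$driver_genes)
#> precision    recall         F
#> 0.3750000 0.3000000 0.3333333
```

Each case sample gets its own state-transition network (28, 18, 14 and 7
directed edges here), a minimum driver set on that network, and a
controllability score: case4 needs only 2 of its 7 network genes pinned
(controllability 0.71), case1 needs 8 of 15. The recurrence vector shows
`g9` is a driver in 3 of 4 samples, and against the planted ground truth
case1's drivers reach F = 0.33 — far above the ~0.18 a same-size random
gene set scores on this study design.

A full 16-workflow benchmark (4 construction × 4 control methods) over a
synthetic study is one call:

```r
report <- run_pipeline(list(out_dir = tempfile("ssc")))
report
#> Benchmark report: 16 workflows, 20 samples, ...
```

A thin command-line wrapper over the same functions lives in
`inst/cli/ssc.R` (`synth`, `build-net`, `drivers`, `simulate`,
`pipeline` subcommands).

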