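# pathspread

Network-diffusion modelling of pathological protein spread (e.g. misfolded
α-synuclein seeded by fibril injection) over a directed, weighted mesoscale
brain connectome — for systems neuroscientists who quantify regional
pathology at a few months post injection and want to ask *how* it got
there: along which connections, in which direction, amplified how fast,
and modulated by which genes.

## The model

Regional burden $X(t)$ evolves linearly on the connectome
$C = \{c_{ij}\}$ ($c_{ij}$: projection strength from region $i$ to $j$):

$$\hat{X}(t) = e^{(\alpha I - \beta \hat{L})t} X_0, \qquad
  \hat{L} = \mathrm{diag}(\mathrm{columnsum}(\hat{C})) - \hat{C}, \qquad
  \hat{C} = (1-s)\,C' + s\,C$$

* $s \in [0,1]$ — spread directionality (0 fully anterograde, 1 fully
  retrograde, 0.5 unbiased);
* $\alpha$ — net amplification (+) / clearance (−) rate per month;
* $\beta \ge 0$ — global diffusivity per month;
* $\gamma \in (0,1]$ — initial burden at the injected region(s) ($X_0$).

Optionally a regional gene-expression vector $g$ rescales connectivity
before mixing: $GC$ (outgoing/presynaptic effect), $CG$
(incoming/postsynaptic) or $GCG$ (combined), $G = \mathrm{diag}(g)$.

Parameters are fit by bounded multi-start optimisation of
$\sum_t \big(1 - \mathrm{CCC}(\log_{10} X(t), \log_{10}\hat{X}(t))\big)$,
where CCC is Lin's concordance correlation coefficient computed over
regions with positive observed burden. The per-time CCCs averaged over
time points ("Ave. CCC") are the headline fit metric.

Around the core model the package provides connectome robustness analyses
(uniform and permutation null connectomes, random and strength-ordered
edge removal, key-connectome extraction over the $n^2$ edge universe),
genome-wide per-gene screening with permutation bootstraps,
over-representation and key-driver statistics for candidate gene sets,
and seeded synthetic-data generators that make the whole pipeline testable
offline.

## Worked example

```r
library(pathspread)

cfg <- synth_config(n_regions = 40, rng_seed = 2026)
C   <- synth_connectome(cfg)                       # directed, weighted, seeded
sp  <- synth_pathology(C, cfg$true_params, "R01",  # injected region
                       times = c(3, 6), noise_sigma = 0.3,
                       detection_floor = 1e-5, rng_seed = 1)

fit <- fit_spread_model(sp$data, C, "R01", fit_config(rng_seed = 1))
fit
#> Spread-model fit (ok)
#>   alpha = 0.2892, beta = 0.4577, gamma = 0.2561, s = 0.8078
#>   Ave. CCC = 0.9206  (per time: 0.9518, 0.8893)
#>   regions used per time: 40, 40
```

The generator's true parameters were $(\alpha, \beta, \gamma, s) =
(0.3, 0.5, 0.2, 0.8)$: despite 0.3 decades of multiplicative observation
noise the fit recovers the mostly-retrograde directionality
($\hat{s} = 0.81$), the net amplification rate and the diffusivity, with
an averaged concordance of 0.92 between observed and predicted log
burdens at both time points.

Thresholding to the strongest connections barely costs concordance,
because the generator (like a real connectome) concentrates almost all
projection weight in a small strong subnetwork:

```r
key <- key_connectome(C, 0.05)
key$retained_count
#> [1] 80                                # of 1600 cells in the edge universe
kfit <- fit_spread_model(sp$data, key$connectome, "R01",
                         fit_config(rng_seed = 1))
c(full = fit$ave_ccc, top5pct = kfit$ave_ccc)
#>   full  top5pct
#>  0.921    0.920
```

Other entry points: `fit_directionality_table()` (free vs fixed
anterograde/unbiased/retrograde fits), `perturbation_sweep()` (null and
edge-removal grids), `screen_genes()` / `select_candidates()` /
`permutation_bootstrap_gene()` (gene screening),
`hypergeometric_enrichment()`, `key_driver_analysis()`,
`kd_edge_chisquare()` (candidate-set statistics), and the
`read_*`/`write_*` helpers for the TSV interchange formats. The vignette
in `vignettes/network-spread-model.Rmd` documents the model, its
assumptions and the numerical choices.

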