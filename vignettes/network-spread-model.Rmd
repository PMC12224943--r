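---
title: "Modelling directionality-biased spread of pathology on a connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling directionality-biased spread of pathology on a connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathspread)
```

## The model

Misfolded proteins such as pathological α-synuclein propagate through the
brain along axonal projections, seeding aggregation in connected regions.
`pathspread` models regional pathology burden $X(t)$ on a directed weighted
connectome $C = \{c_{ij}\}$ ($c_{ij}$ = projection strength from region $i$
to region $j$) as a linear dynamical system with three ingredients:

1. **Spread.** Transport along axons can be anterograde (pre- to
   post-synaptic, following edge direction) or retrograde (the reverse). A
   single mixture parameter $s \in [0, 1]$ interpolates between the two:
   the effective weight matrix is
   $\hat{C} = (1 - s)\,C' + s\,C$, with $s = 0$ fully anterograde,
   $s = 1$ fully retrograde and $s = 0.5$ unbiased. Spread is generated by
   the graph Laplacian
   $\hat{L} = \mathrm{diag}(\mathrm{columnsum}(\hat{C})) - \hat{C}$.
2. **Amplification / clearance.** Templated amplification and degradation
   act globally with net rate $\alpha$ (per month); positive $\alpha$ means
   net amplification.
3. **Seeding.** At time 0 the injected region(s) carry burden $\gamma \in
   (0, 1]$, all others 0.

Together,
$$\hat{X}(t) = e^{(\alpha I - \beta \hat{L})\,t}\,X_0,$$
where $\beta \ge 0$ is the global diffusivity (per month). Because every
column of $\hat{L}$ sums to zero, total burden evolves exactly as
$e^{\alpha t}$; because off-diagonal entries of $-\beta\hat{L}$ are
nonnegative, solutions from nonnegative seeds stay nonnegative. Both
properties are enforced as tests, and an independent numerical integration
of the same ODE (`ode_oracle()`, via `deSolve`) must agree with the
matrix-exponential solution to a relative $10^{-6}$.

Regional gene expression can modulate connectivity before mixing:
$G C$ (outgoing effect: the presynaptic region's expression scales its
efferent edges), $C G$ (incoming: afferent edges), or $G C G$ (combined),
with $G = \mathrm{diag}(g)$. The degeneration of affected regions is
deliberately not modelled; the model targets the early phase in which
spread and amplification dominate.

## Fitting

Observed burdens span several orders of magnitude, so goodness of fit is
judged on the $\log_{10}$ scale, restricted to regions with positive,
finite observed burden, using Lin's concordance correlation coefficient
(CCC):
$$\mathrm{CCC}(x, y) = \frac{2\,\mathrm{cov}(x,y)}
 {\mathrm{var}(x) + \mathrm{var}(y) + (\bar{x} - \bar{y})^2}$$
with population moments. Unlike Pearson's $r$, the CCC is maximal only
when predictions match observations in location and scale, which is what
identifies $\gamma$ and $\alpha$ rather than just the spatial pattern. The
loss is $\sum_t (1 - \mathrm{CCC}_t)$ over the observation times, and the
reported "Ave. CCC" is the unweighted mean of the per-time CCCs.

`fit_spread_model()` minimises this loss over $(\alpha, \beta, \gamma, s)$
with box constraints. The formally unbounded $\alpha$ and half-bounded
$\beta$ are given practical boxes $[-5, 5]$ and $[0, 20]$ per month, ample
for dynamics observable at a 3–6 month horizon; $\gamma$ uses the closed
box $[10^{-6}, 1]$. The loss surface contains a long curved ridge on which
$\alpha$ and $\gamma$ partially trade off (both control prediction scale,
and only two time points constrain them), so naive local optimisation from
a handful of points stalls. The fitter therefore evaluates the loss at
`n_starts` seeded Latin-hypercube points (cheap: one matrix exponential
each) and runs bounded L-BFGS-B only from the best `n_refine` of them
(defaults 30 and 4). Everything is deterministic given `rng_seed`; ties
across starts break to the earliest index. Predicted zeros at masked-in
regions are floored at $10^{-12}$ before the logarithm. A failed
prediction (non-finite generator or exponential) yields a worst-case loss
with a `failed` status rather than an exception, so genome-wide screens
continue past pathological genes.

`fit_directionality_table()` refits the model at the three canonical fixed
directionalities ($s \in \{0, 0.5, 1\}$) alongside the free fit. The free
model nests the fixed ones, so the free fit is additionally warm-started
from the fixed-s optima, which guarantees it never scores below them.

## Robustness analyses

The connectome-perturbation module asks whether fit quality is really
attributable to the measured network:

* `uniform_null_connectome()` — entries i.i.d. $U[0,1]$;
* `permuted_connectome()` — actual weights, randomly repositioned
  (weight histogram preserved exactly);
* `remove_edges()` — a fraction of the $n^2$ edge universe zeroed at
  random or in weight order;
* `key_connectome()` — only the $\lceil f n^2 \rceil$ strongest cells
  retained.

All fraction arithmetic runs over the full $n^2$ cell universe, including
the dynamically inert diagonal: a 410-region connectome has 168 100
"connections", of which 2% is 3362 and for a 116-region connectome 8% is
1077. Weight ties (and the ubiquitous structural zeros) rank by (row,
column) lexicographic order, which makes thresholding deterministic and
removal fractions nested. `perturbation_sweep()` orchestrates
perturbation × replicate grids, derives each replicate's seed as
`master_seed + replicate`, records failures without aborting, and
summarises the Ave. CCC distribution (25/50/75/95th percentiles and
range) over successful replicates.

## Gene screening and downstream statistics

`screen_genes()` refits the model once per gene × effect mode and ranks
genes by Ave. CCC within each mode; genes beating the gene-free global
model qualify as candidates (`select_candidates()` takes the top *N*, ties
lexicographic). `permutation_bootstrap_gene()` destroys the regional
assignment of one expression vector *B* times and reports the percentile
of the actual Ave. CCC in that null — the check applied to the
marginal-ranked candidate. `gene_pathology_correlation()` provides the
connectome-free comparison model (per-time Pearson correlation between
expression and burden on the observed-positive mask).

Expression vectors are divided by their mean before entering the model
(`gene_normalize = "mean"`, switchable to `"none"`). For outgoing and
incoming effects only the shape of the vector matters — the fitted $\beta$
absorbs any overall scale, and a uniform vector reproduces the global
model exactly — but the combined effect is quadratic in the vector, so a
fixed normalisation convention keeps fitted diffusivities comparable
across genes.

Candidate sets feed three statistics:

* `hypergeometric_enrichment()` — one-sided upper-tail over-representation
  of a marker set in a candidate set against the screened-gene background;
  exhaustively identical to one-sided Fisher tests in the test suite.
* `key_driver_analysis()` — depth-1, direction-blind neighborhood
  enrichment on a regulatory network with BH FDR across nodes (key driver:
  FDR < 0.05). The neighborhood excludes the hub itself. The enrichment
  statistic is the exact hypergeometric tail — a deliberate, conservative
  substitution for the chi-like score of the original KDA method, which is
  defined in external software; it changes p-values but not the
  neighborhood/FDR framework.
* `kd_edge_chisquare()` — per effect, a two-cell goodness-of-fit test of
  whether directed edges from that effect's key drivers preferentially
  target same-effect key drivers, with the expected same-effect count
  $|E_{\mathrm{src}\to\mathrm{any}}| \cdot
  (|KD_{\mathrm{src}}|-1)/(|KD_{\mathrm{any}}|-1)$ (a source cannot target
  itself). Expected cells always sum to the observed total.

`relative_pathology()` computes the background-corrected, neuron-area
normalised pathology ratio used to score cell-culture validation wells.

## The synthetic-data generators

Every analysis stage is testable without downloads via `synth_config()`
and its generators, which emulate the statistical structure the pipeline
assumes:

* **Connectome** (`synth_connectome()`): directed, nonnegative, zero
  diagonal, 25% edge density at the 40-region default, with a two-tier
  weight structure. A *backbone* occupying 5% of the $n^2$ universe spans
  every region (a directed cycle through a random region order plus random
  strong cells) and carries ≈ 99.6% of total weight; remaining edges sit
  $10^{-4}$ below it. With log-normal within-tier spread (sdlog 1) the
  weights span ~5–6 orders of magnitude, as tract-tracing projection
  strengths do, and the strongest few percent of connections dominate the
  dynamics — the "key subnetwork" property that the thresholding analyses
  probe. The backbone's cell indices are returned as the generator's key
  edge set. Weights are rescaled to unit mean column strength: projection
  units are arbitrary, and this puts the diffusion time scale in the
  transient regime at the 3–6 month observation times (as in the real
  data, where burden still evolves between time points), which is what
  makes $\beta$ identifiable. An optional bilateral mode pairs L/R regions
  with weaker contralateral expected weights.
* **Pathology** (`synth_pathology()`): the forward model at true
  parameters $(\alpha, \beta, \gamma, s) = (0.3, 0.5, 0.2, 0.8)$,
  multiplied by $10^{\sigma Z}$ noise ($\sigma = 0.3$ on the log10 scale
  by default — multiplicative log-normal noise, a modelling choice matched
  to the log-scale loss), then floored: burdens below $10^{-5}$ observe as
  structural zeros. Generated burdens span well over two orders of
  magnitude, exercising the log pipeline as real data does. The detection
  floor sits above the weak-tier contribution at peak burden, so
  sub-backbone connectivity is subdetection — the coherence condition
  behind the key-subnetwork analyses.
* **Expression** (`synth_gene_matrix()`): i.i.d. log-normal decoy genes
  plus planted genes whose vectors actually modulate the connectome (via a
  declared mode) when the paired pathology dataset is generated.
* **Regulatory networks** (`synth_network_and_sets()`): a directed
  preferential-attachment backbone plus planted hubs whose depth-1
  neighborhoods are over-represented for a designated candidate set.

All generators are pure functions of their configuration and seed, and
restore the caller's RNG state.

What passing on these fixtures does *not* show: real quantified pathology
has spatial autocorrelation, per-animal variability that group averaging
only partly removes, and section-sampling artefacts; real connectomes have
community structure, distance-dependent weights and continuous (not
two-tier) weight spectra; real expression atlases are smooth over
neighboring regions. Recovery of planted structure here validates the
machinery, not the biological conclusions.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so a
full validation completes in minutes on one core: 40-region bundles for
parameter recovery (50 noisy replicates), 30 regions for
null-connectome sweeps (50 replicates per null family), a 51-gene screen
with a 100-permutation bootstrap, and 100 random instances for
solver-vs-integrator agreement. Full-scale profiles (hundreds of regions,
thousands of genes) are configuration changes, not code changes.

Other fixed choices: column-sum-zero validation of Laplacians at relative
$10^{-10}$; ODE oracle tolerances `atol = 1e-12`, `rtol = 1e-10`;
matrix exponentials on the dense generator via `Matrix::expm`, with
repeated time spacings sharing one exponential through the semigroup
property; `ceiling` with a $10^{-6}$ rounding guard in edge-count
arithmetic so printed-count identities hold exactly in floating point;
expression vectors of exactly zero are allowed (they sever the region's
modulated connections) but negative values are rejected.

## Known limitations

* Two observation times constrain $\alpha$ and $\gamma$ jointly; with one
  time point they are confounded with each other and the fit degenerates
  to pattern matching.
* The directionality estimate $\hat{s}$ inherits any asymmetry error in
  the measured connectome; transposing the connectome maps $\hat{s}$ to
  $1 - \hat{s}$ exactly, so orientation conventions matter.
* The KDA statistic is a documented substitution (above); absolute
  p-values are not comparable to the original external implementation.
* Group-averaged burdens are fit as a single trajectory; per-animal
  hierarchical variation is out of scope.
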