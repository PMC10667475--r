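# seqdiv

Diversity estimation under non-independent sequential sampling.

## The problem

Ecologists surveying biodiversity along line transects record individuals
*sequentially* — always the nearest unmeasured one next. When species are
spatially aggregated, consecutive records repeat the previous species far
more often than independent draws from the community would, and classical
estimators of the Gini–Simpson index and Rao's quadratic diversity
(`Q(p) = Σ_{i≠j} d_ij p_i p_j`, the expected pairwise distance between two
randomly drawn individuals) are biased downward.

`seqdiv` models the recorded sequence as a first-order Markov chain:
the next individual repeats the previous species with probability `π` and is
otherwise an independent draw from the relative abundances
(`P(Z_k = j | Z_{k-1} = i) = (1-π) p_j + π [j = i]`). It provides

* a **nearly unbiased method-of-moments estimator of `π`**
  (`estimate_pi()`), obtained by eliminating `Σ p_i²` between the moment
  equation of the adjacent-repeat frequency `v` and the dependence-adjusted
  Gini–Simpson expression, with an explicit fallback to `v` when the
  resulting quadratic has no usable root;
* **Markov-adjusted diversity estimators** (`gini_markov()`,
  `rao_markov()`) that replace the classical `m(m-1)` pair-count
  denominator by `m(m - δ̂)`, `δ̂ = (1+π̂)/(1-π̂)`, and reduce exactly to the
  classical unbiased estimators at `δ̂ = 1`;
* a **spatially explicit line-transect sampler** (`transect_sample()`):
  edge-started random transect bands, nearest-first ordering with random
  tie-breaks, chained transects until the target sample size;
* **synthetic communities** — clustered Thomas-type (`thomas_community()`)
  and completely spatially random (`csr_community()`) point patterns plus
  skewed abundance generators (`make_abundances()`) — so the whole pipeline
  runs without external data;
* a **replication harness** (`run_semi_numerical()`,
  `run_transect_experiment()`) reporting average, bias and RMSE per
  estimator, with `pivot_summary()` and `autoplot()` for tables and figures.

Species distance matrices come from Newick phylogenies
(`patristic_distances()`), taxonomic rank tables with equal per-linkage
weights (`taxonomic_distances()`), or the 0/1 matrix
(`identity_distances()`) under which Rao reduces to Gini–Simpson.

## Worked example

```r
library(seqdiv)

community <- make_abundances(34, "geometric", shape = 0.9)  # skewed, 34 species
model <- markov_model(community, pi = 0.4)
z <- sample_markov_sequence(model, m = 125, seed = 1)

(fit <- estimate_pi(z))
#> Non-independence estimate: pi_hat = 0.3807 (v = 0.4113, delta_hat = 2.229)
#>   m = 125 individuals, 23 species observed
```

The raw repeat frequency `v = 0.411` overestimates the true `π = 0.4` (its
expectation exceeds `π` by `(1-π) Σ p_i²`); the moment-based `π̂ = 0.381` is
close to truth for a single draw. Feeding `δ̂` into the adjusted estimator
fixes the diversity estimate:

```r
cts <- counts_from_sequence(z, universe = community$species)
round(c(ml = gini_ml(cts), unbiased = gini_unbiased(cts),
        markov = gini_markov(cts, fit$delta_hat), truth = true_gini(community)), 4)
#>       ml unbiased   markov    truth
#>   0.9336   0.9412   0.9506   0.9444
```

Replicated over 2,000 simulated surveys the pattern is systematic — the
classical unbiased estimator stays biased low under dependent sampling while
the adjusted one is centred on the truth:

```r
tab <- run_semi_numerical(community, pi_values = 0.4, m_values = c(50, 125),
                          replicates = 2000, seed = 1)
dplyr::filter(tab, estimator %in% c("v", "pi_hat", "gini_unbiased", "gini_markov"))
#>     m condition     estimator truth   avg      bias   rmse n_used
#>    50    pi=0.4             v 0.400 0.434  0.033643 0.0783   2000
#>    50    pi=0.4        pi_hat 0.400 0.401  0.001408 0.0760   2000
#>    50    pi=0.4 gini_unbiased 0.944 0.920 -0.024783 0.0325   2000
#>    50    pi=0.4   gini_markov 0.944 0.947  0.002276 0.0213   2000
#>   125    pi=0.4             v 0.400 0.432  0.032331 0.0545   2000
#>   125    pi=0.4        pi_hat 0.400 0.399 -0.000954 0.0468   2000
#>   125    pi=0.4 gini_unbiased 0.944 0.934 -0.009930 0.0142   2000
#>   125    pi=0.4   gini_markov 0.944 0.945  0.000349 0.0103   2000
```

For the spatial mechanism end to end — clustered community, transect
surveys, dependence detected, diversity recovered — see the vignette
(`vignettes/markov-diversity.Rmd`).

A thin command-line front end over the same functions lives in
`inst/scripts/seqdiv.R` (subcommands `synth`, `simulate`, `estimate`,
`transect`, `table`).

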