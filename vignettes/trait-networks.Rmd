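---
title: "Trait co-occurrence networks: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait co-occurrence networks: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnets)
library(ggplot2)
```

## The model

A trait co-occurrence network summarises how the functional make-up of
communities varies together across space or time. Its nodes are *trait
values* — single levels of categorical traits, e.g. "corallivore" within
trophic level — and its edges are statistically supported correlations
between the prevalences of two trait values across communities. The
structure of this network is read as a proxy for community resilience:
well-connected, modular networks with connectivity spread over many trait
values suggest functional redundancy, while sparse networks hanging off one
or two hub traits suggest vulnerability to disturbance.

Construction proceeds in four steps.

**1. Trait expansion.** A species-by-trait table of categorical traits is
one-hot encoded: each (trait, level) pair becomes a binary column
(`expand_traits()`). Ordinal traits such as body-size classes are treated
as unordered levels, so every level is its own node. A species with missing
data for a trait contributes zeros across that trait's columns and is
excluded from that trait's CWM denominators (below).

**2. Observations.** With site-structured survey data, the binary matrix is
combined with a site-by-species abundance (or presence) matrix into
community-weighted means (`compute_cwm()`):

$$\mathrm{CWM}(s, t) \;=\; \frac{\sum_i w_{si}\, x_{it}}{\sum_i w_{si}},$$

the abundance-weighted proportion of community $s$ carrying trait value
$t$. In presence mode the weights are 0/1 and the CWM is the proportion of
present species with the trait value. Denominators are computed per trait,
summing only species with data for that trait, so missing data in one trait
cannot bias another trait's CWMs. For fossil occurrence data — where sites
or transects are unavailable and abundances unreliable — the species-by-
trait-value matrix is used directly, with species as the observations
(`direct_trait_matrix()`).

**3. Correlation and thresholding.** Every pair of trait-value columns is
correlated across observations with the product-moment (Pearson)
coefficient; on binary columns this is exactly the phi coefficient.
Two-sided p-values come from the $t$ distribution with $n-2$ degrees of
freedom. A pair becomes an edge when it passes the inclusion rule
(`threshold_adjacency()`); the default requires both $p < \alpha$ (0.05)
and $|r| \ge r^\* $ (0.2).

**4. Assembly.** The retained pairs form a simple undirected graph
(`build_network()`). Trait values with zero variance — absent from every
observation, or universal — are excluded from the node set with a warning:
a trait value that no longer occurs cannot take part in the network, which
is exactly what happens when an extinction event removes a feeding mode
from an assemblage. Nodes without significant partners are kept as isolated
nodes. Edges carry $r$, $p$ and the association sign.

## Network metrics

Four metrics summarise the thresholded (binary) network; edge weights are
deliberately ignored, since the edges are already the output of a
significance filter.

* **Edge density** $= m / \binom{n}{2}$: the proportion of logically
  possible trait-trait relationships that are significant.
* **Modularity** $Q$ (Newman–Girvan) with module detection: modules are
  groups of trait values more connected internally than externally, and are
  interpretable as life-history strategy blocks (e.g. an r-selected and a
  K-selected module).
* **Degree centralization** (Freeman):
  $\sum_i (d_{\max} - d_i) / ((n-1)(n-2))$, 1 for a star, 0 for any regular
  graph. It measures how concentrated connectivity is on few trait values.
* **Node degree** with standardized degree $d/(n-1)$ and a keystone
  ranking (descending degree, ties broken lexicographically so results are
  reproducible).

Module detection defaults to deterministic greedy (Clauset–Newman–Moore)
modularity maximization so repeated runs agree without seeds; Louvain and
Leiden are available with an explicit seed. Two numerical choices matter:

* The detector never returns a partition worse than the
  connected-components partition, whose $Q$ is always $\ge 0$ and which
  keeps isolated nodes as singleton modules. Greedy agglomeration can
  otherwise cut at a negative-$Q$ stage on structureless graphs (stars,
  cliques), where the correct answer is "no community structure", $Q = 0$.
* An edgeless network has $Q$ defined as 0 with one singleton module per
  node.

Greedy maximization is not exact: on path graphs with 6 and 8 nodes it
settles 0.02–0.04 below the exhaustive-search optimum. The test suite
enumerates these cases explicitly; all other benchmark graphs (stars,
cycles, cliques, two-clique bridges, $n \le 8$) are solved exactly.

## Significance

**Erdős–Rényi nulls.** To ask whether an observed metric could arise from
unstructured connectivity, `er_null_ensemble()` draws $B$ uniform $G(n,m)$
graphs with the observed node and edge counts, and
`permutation_pvalue()` compares the observed metric to the null
distribution with the add-one convention $p = (k+1)/(B+1)$ — ties count as
extreme, and $p$ is never exactly 0. Edge density is constant across
$G(n,m)$ replicates by construction; its permutation test returns $p = 1$
with a warning rather than `NaN`.

**Bootstrap comparison of two conditions.** To compare, say, tropical vs
temperate regions or pre- vs post-extinction assemblages,
`bootstrap_ensemble()` resamples observation rows (sites in CWM mode,
species in direct mode) with replacement — the resampling unit that
preserves the trait-column structure — and reruns the entire pipeline per
replicate; 1000 replicates per group by default. `compare_groups()` then
reports, per metric, group medians and IQRs, percentile 95% intervals with
an overlap flag, the Welch $t$ test and the Mann–Whitney rank-sum $U$.

One statistical point deserves emphasis. The $t$ and $U$ tests treat the
$B$ bootstrap replicates as independent observations, so their standard
errors shrink with $B$ rather than with the number of sites; they answer
"do these two bootstrap distributions differ?", which is almost always yes,
and they reject far too often if read as a group-level test. Requiring the
two groups' 95% intervals to separate entirely errs the other way
(rejecting at roughly the 0.6% level). The calibrated middle ground — and
the package's primary `significant` flag — is the percentile interval of
the replicate-wise metric *difference*: the difference is significant at
the 5% level when 0 falls outside its central 95% interval. This is the
standard two-sample bootstrap construction, and simulation under identical
generating conditions confirms its rejection rate is close to the nominal
5%, which is what the test suite checks. All three statistics are reported
so users can follow either convention knowingly.

Every stochastic operation takes a mandatory seed, and replicate $b$ of an
ensemble derives its own substream seed $(s + 48271\,b) \bmod (2^{31}-1)$
from the master seed $s$, so enlarging $B$ extends an ensemble without
reshuffling earlier replicates, and identical seed + configuration gives
bit-identical results.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_star` | 0.2 | minimum correlation magnitude for an edge (dimensionless, in [0, 1]) |
| `alpha` | 0.05 | per-pair significance level |
| `rule` | `p_and_r` | how the two conditions combine; `p_only` and `r_only` apply one condition |
| `signed` | `abs` | negative correlations form edges (sign kept as an edge attribute); `positive_only` restricts edges to positive co-occurrence |
| `within_trait` | `TRUE` | keep edges between levels of the same trait |
| `p_adjust` | `none` | optional multiple-testing correction (e.g. `BH`) before thresholding |
| `B` (null, bootstrap) | 1000 | replicate counts |

The threshold literature gives an $r$ cutoff and figure captions mark
$p < 0.05$ links without stating how the two combine, so both pieces are
explicit, configurable, and recorded in the network's provenance. Two
defaults are genuine choices rather than forced interpretations:

* **Within-trait edges are kept by default.** The levels of one trait are
  mutually exclusive, hence structurally negatively correlated; those edges
  are real features of the correlation matrix, but users studying positive
  co-occurrence structure should set `within_trait = FALSE` and/or
  `signed = "positive_only"`. Module recovery, in particular, is only
  well-posed on positive associations: with `signed = "abs"`, strong
  negative cross-block correlations connect everything to everything and
  modularity collapses.
* **No multiple-testing correction by default**, matching common practice
  in this literature; Benjamini–Hochberg is one switch away and recorded in
  provenance.

Abundance is used untransformed in the CWM; a log or other transform can be
applied upstream if desired.

## The synthetic generator

`trait_scenario()` + `generate_modern()` / `generate_fossil()` produce
datasets with the association structure the method is designed to detect,
so every stage is testable without external data.

Species belong to latent strategy blocks (two by default, echoing the
r-vs-K reading of trait modules). Each block has one signature level per
trait; a species adopts its own block's signature with probability
$\rho_{in}$ (default 0.7), a specific other block's signature with
probability $\rho_{out}$ (default 0.05), and otherwise a uniform random
level. Association is induced through this latent membership rather than
through a correlation matrix on binaries, because a copula on one-hot
columns is much harder to control; $\rho_{in} = \rho_{out}$ makes every
signature equally likely, which renders trait draws independent and the
scenario structureless — the null case. Site biomass is log-normal
(meanlog 0, sdlog 1, a typical right-skewed survey biomass shape) weighted
along an environmental gradient so sites at either extreme are dominated by
one strategy, with a small floor so no species is structurally absent.

Default shapes mirror the two study designs the method targets: a modern
survey of 183 reef-fish species scored for 5 traits (4/4/6/8/5 levels, 27
trait values) at 20 sites along a tropical-to-temperate gradient, and a
fossil assemblage of 115 taxa scored for 4 traits (4/5/5/4 levels, 18 trait
values) with no site structure. Sites-per-region, coherence and noise
values are not dictated by either design, so they were fixed once at
realistic survey magnitudes (20 sites, $\rho_{in} = 0.7$,
$\rho_{out} = 0.05$, log-normal(0, 1)).

`generate_fossil()` adds a trait-targeted extinction filter: species
survival is Bernoulli with probability `base_survival` times per-trait-value
multipliers, so selective extinctions (including driving one trait value to
zero occurrences, as when a feeding mode disappears) are one argument away.

What the generator does *not* emulate: dispersal, succession or any
population dynamics; preservation bias beyond trait-targeted downsampling;
intraspecific trait variation; continuous traits. Passing tests on
synthetic data therefore show that the pipeline recovers planted
co-occurrence structure of realistic shape and strength — not that any
particular field dataset meets the model's assumptions.

One caveat discovered while validating the null scenario: in CWM mode, even
with independent traits, the columns of the CWM matrix share species
weights (one dominant species lifts every trait value it carries at the
sites where it thrives), so cross-trait edges can exceed the nominal
$\alpha$ rate. This is genuine finite-community co-occurrence, not an
artifact, but it means "no planted structure" is only equivalent to "edges
at the type-I rate" in direct mode, and the calibration tests are phrased
accordingly.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
sc <- trait_scenario(n_species = 80, n_sites = 30,
                     traits = c(size = 3, feeding = 3, motility = 4),
                     rho_in = 0.9, rho_out = 0)
sim <- generate_modern(sc, seed = 1)
cwm <- compute_cwm(sim$community, expand_traits(sim$traits))
net <- trait_network(cwm, signed = "positive_only")
glance(network_metrics(net))
```

```{r example-nulls}
null_test(net, B = 199, seed = 1, metrics = c("modularity", "centralization"))
```

```{r example-plot, fig.width = 6, fig.height = 4}
autoplot(net)
```

## Problem sizes used by the test suite

The suite validates metrics against closed forms and exhaustive search on
benchmark graphs up to 8 nodes; correlation against a textbook two-pass
oracle on 100 random matrices; null-test calibration with 500 simulated
networks against $B = 999$ nulls; bootstrap coverage with 200 repeated
two-group simulations at $B = 200$ per group; and planted-block recovery
and extinction-direction properties over 20 seeds each. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
while keeping the whole suite at desk scale.

## Applying the workflow to field data

The two published case studies this methodology targets rely on datasets
that are not redistributable here (a reef-fish biomass survey along a
temperature gradient, and a fossil occurrence compilation spanning a
mass-extinction event). The workflow for such data is
exactly the packaged one:

1. export a site-by-species CSV (first column `site`) and a
   species-by-trait CSV (first column `species`);
2. write a YAML config (`mode: cwm` for survey data, `mode: direct` for
   occurrence data without sites) and run `run_build()`, or the CLI
   `Rscript inst/cli/traitnets.R build --config run.yaml`;
3. `run_null_test()` for randomness checks, `run_compare()` for two-group
   (region or time-bin) comparisons.

`tests/testthat/test-acceptance.R` exercises this external-data route end
to end on synthetic stand-in CSVs of the same shape.

## Known limitations

* Correlations are associational; the method cannot separate direct from
  indirect trait relationships.
* The Pearson/phi coefficient on rare trait values has low power at small
  $n$; such nodes tend to appear isolated rather than absent, and
  bootstrap replicates may drop them entirely (recorded per ensemble in
  `n_degenerate`).
* Greedy modularity is a heuristic; for small networks where exactness
  matters, the exhaustive check used in the tests is the reference.
* Permutation p-values with ties counting as extreme are conservative on
  discrete metrics. Degree centralization of small fixed-$m$ random graphs
  takes few distinct values, so its null test under-rejects (simulated
  rejection well below the nominal level); modularity is effectively
  continuous and calibrated. Treat non-significant centralization null
  tests on small networks as weak evidence.
* The network-level "degree centrality" is implemented as Freeman
  centralization; other readings (e.g. mean degree centrality) would scale
  differently, so cross-study comparisons should confirm the formula.
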