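# traitnets

Trait co-occurrence networks for marine community ecology and
paleoecology.

Community resilience to disturbance and extinction is mediated by the
life-history traits present in a community and how they combine. This
package builds *trait networks* — undirected graphs whose nodes are trait
values (levels of categorical traits) and whose edges are significant
correlations between trait-value prevalences across communities — and
computes the resilience-oriented metrics used to compare them: networks
with high modularity, edge density and degree centralization are read as
comparatively more resilient, and high-degree nodes as candidate keystone
traits. It targets both modern survey data (sites × species abundance or
biomass) and fossil occurrence data without site structure (species as
observations), for ecologists and paleobiologists comparing communities
across environmental gradients, disturbances, or extinction events.

## What it computes

Given a site×species matrix $W$ and a one-hot species×trait-value matrix
$X$, community-weighted means

$$\mathrm{CWM}(s,t) = \frac{\sum_i w_{si} x_{it}}{\sum_i w_{si}}$$

are correlated pairwise (Pearson $r$; the phi coefficient on binary
columns), tested against $t_{n-2}$, and thresholded (default: $p < 0.05$
and $|r| \ge 0.2$) into a binary adjacency matrix, visualised and analysed
as an undirected network. Metrics: edge density $m/\binom{n}{2}$,
Newman–Girvan modularity $Q$ with deterministic greedy module detection,
Freeman degree centralization $\sum_i(d_{\max}-d_i)/((n-1)(n-2))$, and node
degrees with a keystone ranking. Significance is assessed against
Erdős–Rényi $G(n,m)$ null ensembles (permutation test, $p=(k+1)/(B+1)$) and
between conditions via 1000-replicate bootstrap ensembles compared with
percentile confidence intervals, Welch $t$, and Mann–Whitney $U$.

A synthetic-data module generates communities with planted life-history
strategy blocks (r- vs K-selected signatures, environmental gradients,
log-normal biomass, trait-targeted extinctions) so the whole pipeline is
testable without external data.

## Worked example

```r
library(traitnets)

# a synthetic 80-species survey with two planted strategy blocks
sc  <- trait_scenario(n_species = 80, n_sites = 30,
                      traits = c(size = 3, feeding = 3, motility = 4),
                      rho_in = 0.9, rho_out = 0)
sim <- generate_modern(sc, seed = 1)

cwm <- compute_cwm(sim$community, expand_traits(sim$traits))
net <- trait_network(cwm, signed = "positive_only")
net
#> <trait_network> 10 trait values, 9 edges (edge density 0.200)
#>   rule: p_and_r (r* = 0.2, alpha = 0.05, positive_only), n_obs = 30

glance(network_metrics(net))
#> # A tibble: 1 × 6
#>   n_nodes n_edges edge_density modularity n_modules centralization
#>     <dbl>   <dbl>        <dbl>      <dbl>     <int>          <dbl>
#> 1      10       9          0.2      0.444         5          0.167

null_test(net, B = 199, seed = 1, metrics = c("modularity", "centralization"))
#> # A tibble: 2 × 8
#>   metric     observed null_mean null_sd p_greater p_less p_two_sided significant
#> 1 modularity    0.444     0.343  0.0893     0.105   0.92        0.21 FALSE
#> 2 centraliz…    0.167     0.246  0.0940     0.995   0.51        1    FALSE
```

The network has 10 nodes (one per trait value) and 9 positive edges: one
in five possible trait-trait relationships is significant. The five
detected modules are the two planted strategy blocks plus isolated
leftover levels; modularity 0.444 sits above the $G(n,m)$ null mean
(0.343) without reaching significance at this size, and low centralization
reflects connectivity spread across both blocks.
`autoplot(net)` draws the network with nodes coloured by parent trait and
sized by standardized degree; `tidy(network_metrics(net))` gives the
per-node degree/keystone table.

Two-condition comparisons and CSV-file workflows:

```r
a <- bootstrap_ensemble(cwm_region_a, B = 1000, seed = 1)
b <- bootstrap_ensemble(cwm_region_b, B = 1000, seed = 2)
compare_groups(a, b)           # medians, IQRs, CIs, difference CI, t, U

run_build("run.yaml")          # CSV in -> GraphML/edge list/metrics out
run_compare("a.yaml", "b.yaml")
run_null_test("run.yaml")
```

or from a shell: `Rscript inst/cli/traitnets.R build --config run.yaml`
(subcommands `build`, `compare`, `nulltest`, `simulate`).

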