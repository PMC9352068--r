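# cascadeflow

Tools for asking two questions about a stream of tweets and retweets in
which a tagged content category circulates (the motivating case: links to
vaccine-critical websites on French-language Twitter during the COVID-19
pandemic):

1. **Did the content gain ground over time?** — measured by a
   compartmental-model estimate of user engagement dynamics.
2. **Which groups of users spread it, and how?** — measured by flow-based
   community detection on the directed retweet hyper-graph and
   per-community information-flow diagnostics that separate *echo chambers*
   (content recirculates internally) from *spreaders* (content is
   re-broadcast outward).

The package is aimed at computational social scientists and infodemiology
researchers who have an event stream (one record per posting: user, day,
original-vs-retweet flag, root tweet, URLs, hashtags) and curated seed
lists of source domains.

## The models

**Engagement dynamics.** A user is *engaged* at day *t* if they posted or
reshared a link of the tracked category within the trailing window
(*t* − *τ*, *t*] (default *τ* = 3 days), and *active* if they posted
anything in that window. Treating engaged users as the infectious
compartment of an SIS process,

    dE⁺_t = α_t · E_t (N_t − E_t) / N_t        (engagement by contact)
    dE⁻_t = β_t · E_t                          (loss of interest)

where *E_t* engaged users, *N_t* active users. Inverting these balance
equations on the observed daily inflow/outflow yields daily rates α̂_t,
β̂_t and the reproduction number **R_t = α_t / β_t**; peaks of a smoothed
R_t locate the events that triggered waves of engagement.

**Retweet hyper-graph.** Each original tweet with its retweeters is one
directed hyper-edge ⟨tail = poster, head = retweeters⟩ — unlike a pairwise
retweet network this distinguishes one tweet retweeted *N* times from *N*
tweets retweeted once. A random walk (pick an incident hyper-edge
uniformly, then a head node uniformly) has the effective transition
operator

    T_{i→j} = Σ_{α ∈ E(i,j)} |α|⁻¹ / Σ_{k, α ∈ E(i,k)} |α|⁻¹

with |α| the head size. From its stationary distribution *p(i)* and edge
flow *p(i, j) = T_{j→i} p(j)*, communities maximize the one-step flow
auto-covariance Q = Σ_C Σ_{i,j∈C} [p(i,j) − p(i)p(j)] (directed modularity
with stationary weights), and each community *C* is characterized by its
**average visit probability** p(C)/|C| and **escape probability**
p(C̄|C) = Σ_{i∉C, j∈C} p(i,j) / Σ_{k∈C} p(k), evaluated on the full,
category-restricted and per-period sub-hyper-graphs.

**Profiles.** Community content preferences are scored by the over-usage
ξ_ia = P(i,a) − P(i)P(a) of hashtag/URL *a* in community *i* over the
top-K items and top-M communities, then hierarchically co-clustered.

Because the motivating Twitter corpora cannot be redistributed, the
package ships a synthetic generator (`synth_config()`,
`simulate_engagement()`, `simulate_cascades()`) producing streams with
known ground truth — planted blocks, assortative cascades, SIS adoption
with configured (α*, β*), biased hashtags — on which the whole chain is
validated end to end.

## Worked example

```r
library(cascadeflow)

cfg     <- echo_chamber_config(n_per_block = 30, days = 60, seed = 3)
events  <- simulate_cascades(cfg)
catalog <- url_catalog(
  c(cfg$category_urls, cfg$media_urls),
  rep(c("vaccine_critical", "media"), c(4, 6))
)

crit   <- classify_events(events, catalog, "vaccine_critical")
series <- engagement_series(events, crit, tau = 3)
glance(series)
#> # A tibble: 1 × 7
#>   n_days max_engaged max_active median_alpha median_beta median_R   tau
#>    <int>       <int>      <int>        <dbl>       <dbl>    <dbl> <dbl>
#> 1     60          56         90        0.278       0.122     1.98     3
```

Median α̂ ≈ 0.28 and β̂ ≈ 0.12: each engaged user recruits about two
others before losing interest (R ≈ 2), so engagement with the tagged
category is self-sustaining in this stream.

```r
hg   <- build_hypergraph(events)
hg
#> <retweet_hypergraph> 90 nodes, 1309 hyper-edges
fs   <- flow_state(hg, damping = 0.85)
part <- detect_communities(fs$T, fs$p, seed = 1)
glance(part)
#> # A tibble: 1 × 4
#>   n_nodes n_communities quality largest_size
#>     <int>         <int>   <dbl>        <int>
#> 1      90             2   0.275           60

sub <- restrict_hypergraph(hg, crit)
flow_summary(part, flow_state(sub, damping = 0.85),
             subgraph = "vaccine_critical")
#> # A tibble: 2 × 6
#>   community  size avg_visit escape subgraph         period
#>       <int> <int>     <dbl>  <dbl> <chr>            <chr>
#> 1         0    60   0.0152  0.0322 vaccine_critical all
#> 2         1    30   0.00299 0.604  vaccine_critical all
```

On the category-restricted hyper-graph community 0 (which contains the
planted echo-chamber block) keeps 97% of the walk's steps inside — the
echo-chamber signature — while community 1, the planted spreader block,
pushes 60% of its steps outward with a fraction of the visit mass.

`run_all(run_config(...))` chains every stage and writes the tidy CSV
outputs (daily volumes and content shares, engagement series and peaks,
partition, flow summaries, ξ matrices) plus the serialized configuration
into an output directory; `autoplot()` methods plot each result type.

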