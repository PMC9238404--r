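---
title: "Tracking a microbial invader across touched surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a microbial invader across touched surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fomitetrack)
```

# The problem

An office, a ward or a household is a surface ecosystem: every hand, phone,
desk and door handle carries a resident microbial community, and every
touch exchanges community members between two surfaces. When a bacterium
that is foreign to this ecosystem is introduced on one person's hands — a
pathogen, or a harmless surrogate — its fate is an invasion-ecology
question. `fomitetrack` implements three linked analyses for such
experiments: identifying the invader and its emission source from the
microbiota alone, classifying every taxon's neutrality between hands and
surfaces, and quantifying how contamination decays with distance on the
touch network. A synthetic office generator with complete ground truth
backs every stage with tests.

# Data model

The observational unit is a sample-by-ASV matrix of amplicon counts
(`count_table`) with per-sample metadata: surface type (hand, face, phone,
six private inanimate types, public types), owner, and pre/post timepoint.
Hands, faces and phones are sampled before the experiment as negative
controls. Counts are row-normalized to relative abundances
(`relative_abundance`; zero-sum swabs are dropped with a warning, as
low-biomass samples that cannot be sequenced). For genus-level analyses,
ASVs unassigned at the genus level are removed, same-genus ASVs pooled, and
rows re-normalized (`collapse_to_genus`); the invader's ASVs always form
their own species-level column so that networks can include the invader as
a taxon of its own.

# Invader and co-occurrence networks

Both networks start from all-pairs Spearman correlations over the 50 most
abundant genera (plus the invader, appended if it ranks lower) across the
post-experiment samples. For each pair, surfaces on which *both* genera are
zero are removed first: shared absence carries no rank information about
co-variation and would otherwise manufacture correlation. The
tie-corrected rho gets a two-sided p-value from the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))`; with hundreds of surfaces per pair the
approximation is accurate, and pairs retaining fewer than 3 samples (or a
constant vector) are reported as NA and excluded. One Benjamini–Hochberg
family covers all pairs, and both networks use the same adjusted p-values
with a strict `p_adj < 0.05` gate.

The **MIN** keeps significantly negative correlations (weight |rho|). The
model behind it: before invasion a native genus holds a stable share
`p_native`; after invasion its measured share is diluted to
`q_native = p_native (1 - q_invader)`, so the invader's abundance is
negatively rank-correlated with *every* native taxon on the surfaces it
reaches. Each genus is in effect auditioned as the invader, and the genus
with the highest MIN degree (ties broken by summed |rho|, then name) is
the most probable one.

The **MCN** keeps significantly positive correlations with weight rho^3 —
cubing stretches the weight distribution, which gives the fast-greedy
modularity optimization (Clauset–Newman–Moore, via igraph) a finer
division while preserving the order of weights. Genera emitted together
from one body source co-vary across surfaces and land in one community.
Communities from two independent experiments are matched by the Jaccard
index of their member sets; the best-matching pair's intersection is the
reproducible co-occurring group.

# Neutral community model

The Sloan model treats each private inanimate surface as a local community
of `N` individuals receiving immigrants from a common source pool — here
the participants' hands, pooled by averaging their relative-abundance
profiles (equal weight per hand; a pooled-counts mode weighting hands by
depth is available). For an ASV at source frequency `P`, the stationary
distribution of its frequency `x` in a sink is `Beta(N P m, N (1-P) m)`,
where `m` is the probability that a death in the sink is replaced by an
immigrant rather than by local reproduction. Its expected occurrence —
the chance of exceeding the one-individual detection threshold — is the
upper tail at `1/N`:

```{r}
expected_occurrence(P_i = 0.01, N = 1000, m = 0.1)
```

`fit_ncm` maximizes the binomial log-likelihood of the per-ASV detection
counts across sinks, `sum(k log pe + (n-k) log(1-pe))`, over `m` in
(1e-6, 1) with a bounded scalar search (tolerance 1e-8), checked against a
coarse log-spaced grid; on a likelihood plateau (fully saturated
occurrence) the boundary `m = 1` is reported rather than an arbitrary
interior point. `N` defaults to the mean read depth of the sink samples;
`n_mode = "richness"` instead uses the mean per-sample ASV count, and a
known `N` can be passed directly (as in simulations). Each ASV is labeled
**above** / **below** / **neutral** according to whether its observed
occurrence falls above, below, or inside the 95% Wilson score band around
the expected occurrence at the fitted `m` — above-neutral ASVs are favored
by the surface (sink) environment, below-neutral ASVs by the hand (source)
environment. An actively introduced invader is expected below neutral:
its hand abundance is propped up by re-inoculation, while many surfaces
never receive a detectable dose. Label stability is assessed by
bootstrapping: refitting on 90% subsamples of the sinks (default 1000
replicates) and reporting per-ASV label fractions.

## Simulating from the model, and a consistency choice

`simulate_neutral_sink` draws sink compositions from a Dirichlet with
concentration `N m` and mean `P` — exactly the stationary marginals above —
and returns counts. By default the counts are `floor(N x)`, the finite
community of `N` individuals, so that "detected" coincides exactly with
the model's `x > 1/N` threshold. Resampling the composition multinomially
at depth `N` is also available (`counts_mode = "multinomial"`), but it
smears detection to `1-(1-x)^N`, which is a different observation model
from the one being fitted: in our experiments it inflated the recovered
`m` by 20–50% and mislabeled up to a third of truly neutral ASVs at larger
`m`. Calibration tests therefore use the community mode; the multinomial
mode remains for studying that observation mismatch itself.

With the community mode and a known `N`, recovery is sharp: across
`m` in {0.05, 0.1, 0.3} (854-ASV truncated-lognormal source, 300 sinks,
`N` = 1000, 20 seeds each) the median relative error of the fitted `m` is
under 1%, about 94% of truly neutral ASVs are labeled neutral, and the
~6% mislabel rate matches the nominal 5% of the Wilson band. The residual
sensitivity is at very rare ASVs (expected occurrence near 0), where
binomial discreteness degrades any interval's coverage — one reason the
analysis is restricted to the most abundant ASVs.

# Surface touch network

A vertex is a surface, with both hands of a participant pooled as one
surface; an edge's weight is the log10-transformed touch count between two
surfaces. Under this definition (the default `"log10"` dialect) a pair
touched exactly once has an edge of weight zero: it exists for geodesic
distances but contributes nothing to weighted analyses. Because that is
arguably unintended, a `"log10p1"` dialect (log10(count+1)) is provided;
all shipped analyses use the default.

The proximity analysis buckets private inanimate surfaces by unweighted
geodesic distance from the carrier's hands — 1, 2, and >=3 (unreachable
surfaces included in the last bucket) — excludes carrier-owned surfaces,
and compares invader abundance across buckets with a Kruskal–Wallis test
followed by pairwise Dunn z-tests (tie-corrected, BH-adjusted within the
three-pair family; implemented in-package since no Dunn-test package is
assumed). Eigencentrality is the leading eigenvector of the weighted
adjacency on the largest connected component, scaled to max 1, with other
vertices at 0. The interpersonal intimacy between hands u and v is

    W(u, v) = sum over common neighbor surfaces nbr of
              (w(u, nbr) * w(v, nbr))^(1/4)  +  w(u, v),

with only non-hand surfaces eligible as common neighbors; participant u's
"best friend" is the v maximizing W(u, v), ties broken by id. The fourth
root keeps a single heavily shared surface from dominating the sum.

# The synthetic office generator

`generate_office` produces a ground-truthed scenario whose defaults
describe the study conditions the package targets: 24 participants working
13 h (8 a.m.–9 p.m.), each owning pooled hands, a face, a phone and six
private inanimate surfaces, plus 6 shared public surfaces; one carrier
re-inoculated every 30 min; handwashing at 0.4 events/person/h with a
survival factor of 0.1.

Mechanism, in order: (1) initial communities are Dirichlet draws around a
skin profile (hands, faces) or an environment profile (everything else);
hand-selected ASVs (20%) are 8-fold enriched in the skin profile,
surface-selected ASVs (30%) in the environment profile, and neutral ASVs
have *exactly* equal expected mass in both — an invariant the tests assert
on the stored profiles. (2) Six saliva-associated genera (two ASVs each)
are deposited jointly on each participant's phone, cup and desk, scaled by
a shared log-normal per-participant emission intensity, so the group
co-varies across surfaces; their resident background mass is kept low,
since saliva taxa reach office surfaces mainly through deposition.
(3) Touch events are independent Poisson streams: own surfaces (0.01/s,
with faces and phones weighted lowest), public surfaces (0.0002/s), and
social touches (0.0005/s) directed predominantly (80%) at a designated
friend; friendships are planted as mutual pairs because the intimacy
measure is symmetric, so a one-directional designation would not be
identifiable. (4) Each touch performs a symmetric contact-patch exchange:
each side gives fraction `f = 0.4` of the community on one hand-sized
patch, i.e. `f/area` of its total mass, where per-type areas (desk 30,
seatback 8, keyboard 6 ... hand 1) encode how much of a large surface a
single touch actually engages. This patch normalization is what produces
the empirically observed asymmetry — hands, faces, phones and small public
surfaces track the circulating contamination closely while large surfaces
dilute it — without any asymmetric transfer efficiencies. (5) The carrier's
hands receive 20 mass units of invader (split 0.4/0.3/0.2/0.1 over four
near-identical ASVs) per inoculation; initial surface communities have
mass ~1 per patch, so carrier hands become invader-dominated, as a 10^7
cell inoculum on washed skin would be. (6) Washing multiplies the whole
hand community, invader included. (7) Sequencing is a
Dirichlet-multinomial draw at depth 30000 with overdispersion 300,
the dominant noise source for rare taxa, emulating swab-to-library
variability of real amplicon data.

What the generator does **not** emulate: aerosol transmission, within-day
longitudinal sampling, taxon-specific survival or growth on surfaces,
compositional biases of extraction/PCR, and contamination of negative
controls. Passing the recovery tests therefore shows the inference is
correct when contamination spreads by touch alone under these noise
models — not that real offices contain no other transmission routes.

One planted example is only partially reproduced: in the generator,
surface eigencentrality and invader acquisition are genuinely coupled
(both increase with a participant's public-touch activity), so the
correlation between invader abundance and centrality — after excluding
carrier-owned, carrier-touched (>5) and untouched surfaces — is weakly
positive rather than null; the tests assert that its median magnitude is
small (|rho| < 0.3) rather than non-significance in a fixed majority of
runs.

# Numerical and design choices

* Ties in `top_taxa` and all rankings break lexicographically — repeated
  runs must order identically.
* The significance gate is strictly `p_adj < 0.05` (edges at exactly 0.05
  are removed), matching the stated edge-removal rule.
* Spearman p-values use the t approximation; at the n of these analyses
  (hundreds of surfaces) exact permutation changes nothing material.
* `expected_occurrence` handles the degenerate shapes exactly: `P = 0`
  gives 0, `P = 1` gives 1.
* Wilson score intervals are computed in closed form; coverage is
  property-tested (~95% for a uniform proportion at n = 200).
* Bray–Curtis on relative abundances is `1 - sum(min(x, y))`, checked
  against the equivalent `sum|x-y|/sum(x+y)` form.
* All randomized operations take an explicit seed; the CLI writes a JSON
  run manifest (package version, seed, parameters) and produces
  bit-identical files for identical seeds.

# Problem sizes used in the tests

Unit tests run scaled-down offices (6–14 participants, 40–80 ASVs, depth
3000–10000). The validation suite runs 50 default-sized office seeds for
the recovery rates (invader top degree, one-community saliva group,
carrier in top 2, monotone proximity decay, below-neutral invader),
20 seeds per migration rate for neutral-model recovery, 20 replicates for
null calibration, and an exhaustive-partition modularity oracle on graphs
of up to 8 vertices. `scripts/acceptance.R` recomputes the same quantities
at 20 office seeds and 10 recovery/null replicates.

# Limitations

Spearman networks on compositional data are not a compositionally aware
method (no SparCC/SPIEC-EASI-style correction); the double-zero exclusion
and genus-level pooling follow the network definitions implemented here,
and the invader-dilution argument in fact *relies* on the compositional
negative coupling. The NCM is single-source: contributions from faces,
mouths or the outdoors are folded into the hand pool. The touch simulator
conserves mass except at inoculation and washing; it has no die-off, so
long-duration scenarios exaggerate spread. Geodesic buckets treat
unreachable surfaces as ">=3", which is the natural reading for a
connected office but merges two qualitatively different cases on sparse
logs.
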