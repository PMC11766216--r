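---
title: "Trophallaxis networks, permutation inference, and temporal spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophallaxis networks, permutation inference, and temporal spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trophnet analyzes the mouth-to-mouth food sharing (trophallaxis) of
individually marked honey bee workers, with a focus on workers that recently
performed hygienic tasks -- uncapping brood cells and removing dead pupae.
Because those tasks expose workers to pathogens, the scientific question is
whether hygienic workers are less embedded in the colony's food-sharing
network than the caste they come from, the non-hygienic middle-aged
(roughly 16-day-old) within-nest workers, and whether the timing of their
interactions would contain a transmissible agent. This vignette describes
the models and procedures the package implements, the choices behind them,
and what the simulation-based tests do and do not establish.

## From event logs to networks

The raw observation unit is one timed nectar exchange: donor, receiver,
start time (seconds from the start of filming) and duration (seconds).
Exchanges shorter than 2 s are dropped before any network is built
(`filter_short_events()`), because very brief contacts rarely involve actual
nectar transfer; an exchange of exactly 2 s is kept.

Two network views are built over the *same* node set -- every identifiable
individual that took part in at least one filtered exchange:

* **Static network** (`build_static_network()`): a directed multigraph
  summary. Each ordered (donor, receiver) pair stores the number of
  exchanges and their total duration. Degree-type measures default to event
  counts rather than distinct partners, because repeated exchanges are the
  behaviorally meaningful quantity at this time scale; a distinct-partner
  variant is available (`degree_strength(count = "partners")`).
* **Time-ordered network** (`build_temporal_network()`): the chronological
  event sequence, stably sorted so simultaneous events keep their recorded
  order. Only paths whose event times increase are valid transmission
  routes.

**Hygienic coding.** A worker seen uncapping or removing counts as hygienic
unless *all* of its exchanges happened strictly before its earliest hygienic
act, in which case its observed social behavior predates its hygienic
status and it is recoded as non-hygienic (`code_hygienic_status()`). Acts
from the manual watch that precedes filming carry times at or below zero,
so they are uniformly handled by the same rule. An exchange starting at
exactly the same second as the earliest act is treated as *not* prior
(strict precedence) and reported with a message: the data cannot show which
came first, and refusing to recode on a tie is the conservative choice with
respect to keeping observed hygienic workers in the focal group.

## The measure suite

Per node: exchange counts and summed durations split by direction
(degree/strength), directed shortest-path betweenness, and eigenvector
centrality. Network-level: directed edge density (distinct ordered pairs
over N(N-1)) and assortativity.

Two measure variants are deliberately exposed rather than decided silently,
because sources rarely state them:

* **Betweenness** defaults to unweighted directed paths. If weighting is
  requested, edge length is `1/total_duration`: a long exchange is a strong
  tie, i.e. a short distance. Duration-as-distance would invert the
  semantics.
* **Eigenvector centrality** defaults to the symmetrized, duration-weighted
  adjacency, scaled to a maximum of 1. On sparse directed graphs of this
  kind the strongly connected core is tiny and the purely directed variant
  collapses to zero almost everywhere; symmetrizing keeps the measure
  informative. The directed variant is available via
  `eigenvector_centrality(treat_as_undirected = FALSE)`.

Assortativity comes in two forms: nominal (Newman's mixing-matrix
coefficient, used for hygienic status) and numeric (Pearson correlation of
donor and receiver values over directed edges, used for age in days).
Both count each distinct ordered pair once by default; an event-multiplicity
weighted variant is flagged. Unknown-age individuals (the queen, unmarked
drifters) are excluded from the age form together with their incident
edges, and the number of excluded edges is attached to the result.

## Node-permutation inference

Network measures violate the independence assumptions of ordinary tests, so
group differences are judged against permutation nulls that hold the
network fixed and shuffle only the attribute labels -- uncoupling phenotype
from network position.

* **Statistic.** The least-squares slope of measure ~ group indicator with
  the reference group coded 1, which for a binary predictor is exactly
  `mean(reference) - mean(focal)`. Positive values mean non-hygienic
  middle-aged workers score higher.
* **Restriction.** For the group comparisons, only the labels of the two
  focal groups (hygienic and non-hygienic middle-aged) are shuffled among
  themselves, conserving both group sizes and every other node's label. For
  assortativity, the shuffle is unrestricted over all attribute-bearing
  nodes.
* **Decision rule.** 1000 permutations by default; the result is
  significant when fewer than 2.5% of null values lie at or beyond the
  observed value in either tail (a two-tailed test at per-tail alpha
  0.025). The reported p is the smaller tail proportion, not doubled.
* **Ties and zeros.** The add-one estimator is used:
  `p = (k + 1) / (n_perm + 1)` with the observed value counted into both
  tails, so p is never exactly zero and ties count against significance.
  Plain proportions are available via `add_one = FALSE` for comparison with
  analyses that report them.

## Temporal spread

`time_respecting_reach()` simulates perfect transmission from one seed
individual in a single chronological pass: at each event, if a participant
is infected, transmission occurs; infection acquired at an event is
transmissible at any strictly later event, and simultaneous events resolve
in stored order. Per seed, the reached fraction uses all networked
individuals as the denominator, with the seed excluded from the numerator.

Transmission direction is a genuine unknown: nectar flows donor to
receiver, but mouth-to-mouth contact plausibly exposes both parties, and
both routes are documented for honey bee pathogens. The package therefore
implements both semantics -- `mode = "both"` (default) and
`mode = "forward"` (nectar flow only) -- and every report records which was
used. Duration plays no role in the spread model (perfect transmission);
it matters only in the weighted static measures.

The group comparison (`spread_potential_test()`) uses the same coefficient
statistic on reached fractions, but its null permutes the *event times*
(holding who-interacts-with-whom fixed) and recomputes every spread from
scratch, one thousand times by default. This asks specifically whether the
observed temporal ordering -- e.g. partners of hygienic workers ceasing
interaction after contact -- widens or narrows a group's onward pathways
relative to timing at random.

## The synthetic colony generator

There is no public generative model for these data, so the package supplies
its own (`colony_config()`, `generate_colony()`), built to emulate the
observed summary shape of a one-hour filming window on a two-frame hive:

| knob | default | rationale |
|---|---|---|
| cohort sizes | 300 workers at each of 2, 9, 16, 23, 30 d + 1 queen | weekly marked cohorts |
| `participation_rate` | 0.30 | yields ~300--360 networked individuals |
| `n_events` | 280 | observed exchange counts (~260--300) |
| `horizon` | 3600 s | one hour of footage |
| `age_kernel_scale` (tau) | 35 d | pair weight `exp(-|age diff|/tau)`; 35 d puts age assortativity near 0.2 |
| `queen_interaction_rate` | 2 | keeps the queen reliably in the network |
| duration law | lognormal, meanlog log 8, sdlog 0.7, clamped to [2, 212] s | median ~8 s, mean ~10 s per exchange |
| hygienic age law | normal(19, 8.5) d, snapped to cohorts | hygienic work peaks at middle age |
| `n_hygienic` | 64 | observed censuses (55--73) |
| `effect_delta` | 0 | planted donation suppression; 0 = null |

Donors are drawn uniformly from the participating pool (hygienic workers'
weight multiplied by `1 - effect_delta`), receivers by the age kernel;
unknown-age pairs use the one-cohort-gap weight. Events are sampled
independently given these weights: real exchange sequences are burstier and
spatially structured, which is irrelevant for the calibration and recovery
roles the generator plays but means the generator is *not* a mechanistic
model of bee behavior.

Two defaults were fixed by an explicit design analysis rather than taken
from data. The age kernel scale was chosen so that median age assortativity
lands in the empirically observed 0.15--0.25 band (tau grid: 3 d gives
r ~ 0.95, 8 d ~ 0.70, 20 d ~ 0.34, 35 d ~ 0.20, unbounded ~ 0). The
duration spread (sdlog 0.7) keeps per-node strength variance low enough
that a large planted donation suppression (`effect_delta = 0.8`) is
detectable in a median replicate at these group sizes; the cost is that the
generator's largest single exchange is ~60 s, well short of the 170--212 s
maxima real colonies produce. Users studying duration extremes should raise
`duration_sdlog` and accept lower test power.

With `effect_delta = 0`, hygienic and non-hygienic middle-aged workers are
exchangeable by construction for donation-side measures, which is what
makes the generator a valid calibration bed for the restricted permutation
test.

## What the tests show, and what they cannot

The test suite verifies, among other things: exact agreement of the spread
pass with exhaustive enumeration of time-increasing transmission paths on
small random temporal networks; agreement of betweenness with brute-force
path counting and of eigenvector scores with a dense eigen-decomposition;
nominal type-I error of the restricted permutation test on null colonies
(rejection rate within [0.03, 0.07] at the two-tailed 5% level over 500
replicates of 200 permutations); monotonically increasing power over the
planted-effect grid {0, 0.4, 0.8} with 100 replicates each; and
byte-identical outputs under repeated seeds. Simulation sizes were chosen
so the whole suite runs in a few minutes: calibration and recovery
replicates use full default colonies with 200-permutation tests inside,
and the spread-test calibration uses 120-event colonies; the package
defaults for real analyses remain 1000 permutations.

One distributional property of the generator is worth stating precisely:
with ~280 distinct edges, the sampling standard deviation of numeric age
assortativity under no age structure is `1/sqrt(E)` (about 0.06), so |r|
stays below 0.1 in roughly 91% of null colonies, not more. Any workflow
that treats |r| < 0.1 as "no assortment" on networks of this size should
expect that false-positive rate.

Passing these tests shows the machinery is correct and calibrated *under
the generator's assumptions* -- independent events, no burstiness, no
spatial structure, stationary rates within the hour. It does not show that
real colonies satisfy those assumptions, and the permutation framework's
guarantees on real data rest on the exchangeability argument, not on these
simulations.

## Known limitations

* Betweenness and eigenvector variants actually used by any given published
  analysis are rarely stated; reports name the variants used, but
  cross-study comparability is limited.
* The spread model has no dose, latency, recovery, or duration dependence,
  and covers nectar transfer only -- not contact or fecal-oral routes.
* The group coefficient is a difference of means; with the heavily
  zero-inflated measures typical of sparse one-hour networks, medians (also
  reported) can disagree with it in direction.
* No multiple-testing correction is applied across the measure family, by
  design; the run manifest records this.
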