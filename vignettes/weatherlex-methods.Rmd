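---
title: "Measuring weather effects on expressed mood: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring weather effects on expressed mood: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public mood responds to weather, but measuring that response from social
media text is confounded three ways: weather-themed corpora are full of
automated content; what counts as "unusual" weather depends on the local
climate (25 °C is unremarkable in London and extraordinary in Inverness);
and the vocabulary used to talk about weather — and to express emotion —
varies regionally. `weatherlex` implements a context-sensitive pipeline
that addresses each confounder in turn:

1. **Corpus filtering** removes automated posts with a five-stage cascade.
2. **Climatology z-scoring** converts each post's local daily weather into
   anomalies relative to a per-location reference climatology.
3. **Lexicon induction** learns corpus-specific token valences — a
   sentiment scale, and one severity scale per weather condition — by label
   propagation over a word-association graph, so the scales reflect how
   *this* corpus talks.
4. **Modifier-aware scoring** turns token valences into post-level scores
   in [-1, +1].
5. **Response analysis** aggregates scores into binned exposure-response
   curves, pairwise condition grids, word-level scatters and regionally
   normalized curve comparisons.

Because the corpora this method targets are ephemeral platform data, the
package ships a first-class synthetic generator with known ground truth;
every stage is validated against it.

## Corpus filtering

The cascade runs in a fixed order: thematic term match ("weather",
case-insensitive substring); removal of accounts contributing strictly more
than 1% of the corpus (share computed once on the thematically filtered
input, not iteratively — so the order of stages matters and is part of the
contract); removal of accounts with "weather" in the username; removal of
posts containing standalone "mph"/"hPa" (a match not flanked by a letter —
"40mph" counts, "oomph" and "toothpaste" do not, since digit-adjacent units
are the signature of automated reports); and removal of the idiom "under
the weather". The strict ">" at the share threshold reads "over 1%"
literally; both the threshold and all match strings are configurable. All
case-insensitive matching uses full Unicode case folding.

## Weather join and climatology

Daily condition values (maximum temperature °C, precipitation mm, humidity
%, wind m/s, pressure hPa) live on a regular lon/lat lattice. A post's
conditions are the unweighted mean over grid nodes inside its polygon
(node-in-polygon, boundary inclusive), or the nearest node by great-circle
distance for points and node-free polygons, with ties broken by smallest
cell id for reproducibility.

Anomalies are `z = (C(x, t) - mu(x)) / sigma(x)` where `mu`/`sigma` are the
sample mean and standard deviation over a reference window (the
climatological convention is the preceding decade; any window inside the
field is accepted). The standard deviation uses the n−1 divisor —
self-consistency then makes the reference window's own pooled z-scores have
mean 0 and standard deviation exactly 1. Cells with under 30 non-missing
days are unusable; constant series (sigma = 0) are flagged degenerate and
yield missing z with a warning rather than an infinity. Posts with missing
conditions are flagged, never silently dropped: dropping is an
analysis-stage decision.

## Lexicon induction

### The association graph

Tokenized posts (lowercased words, emojis as single tokens, URLs and
mentions removed, apostrophes kept in-word) feed a co-occurrence count
between token positions within a window inside each post. The default
window is the whole post: posts are short, and the percentile tags
(below) are appended at the end of the text, so a narrow window would
couple tags only to the final tokens.

Counts are weighted by positive pointwise mutual information with
context-distribution smoothing (context marginals raised to 0.75), the
standard correction for PMI's bias toward rare contexts. The smoothed PPMI
matrix is symmetrized and embedded by its spectral decomposition truncated
to positive eigenvalues (rank 64 by default), with rows scaled by the
square root of the eigenvalues. The positive-spectrum truncation matters:
a plain SVD of an indefinite similarity matrix splits an exclusively
co-occurring token pair across a +/− eigenpair, making their embedding
cosine exactly zero, whereas the PSD projection keeps first-order
association. The graph is then the k-nearest-neighbour graph (k = 50)
under cosine similarity, edge weight `max(cosine, 0)`, symmetrized by
mutual max, no self-loops. k = 50 rather than a sparser graph is
deliberate: with a few hundred to a thousand token types, sparser graphs
measurably lose the weaker (sentiment) signal in recovery experiments on
the synthetic generator.

### Propagation

Two random walks with restart run over the row-normalized edge weights,
one per polarity, restart mass distributed over that polarity's seeds
proportional to seed weights. The `restart` parameter is the teleport
probability; its default 0.15 corresponds to the conventional
walk-continuation probability of 0.85. Convergence is declared when
successive iterates differ by less than 1e-6 in max norm (cap 10,000
iterations); on every small graph the iteration agrees with the direct
linear-system solution to well below 1e-8. Token polarity is
`p = (pos − neg) / (pos + neg)` (0 where both walks assign no mass, e.g.
isolated nodes), and the reported valence is `p` standardized over the
vocabulary and squashed through `tanh` — a monotone map that keeps
[-1, +1] and makes swapping the seed sets negate the lexicon exactly.

The default sentiment seeds are twenty clearly positive and twenty clearly
negative everyday evaluative words; rule-based social-media lexicons
conventionally anchor their scales with generous seed sets, and averaging
over more seeds suppresses corpus-sampling noise. Seeds missing from a
corpus vocabulary are dropped at propagation time.

### Weather-severity scales by percentile tagging

For each condition, posts are ranked by the condition z-score and the top
1%, 1–2% and 2–3% bands get an artificial tag token ("top1", "top2",
"top3") appended once to the text, mirrored at the bottom with "low1"–
"low3" — tags are chosen to be absent from the corpus vocabulary. Band
sizes are rank-based (`floor(n * cut)` differences); ties are broken by
stable original order, and in the fully degenerate case (all z equal) a
post receives at most one tag, with the low tag winning. The graph is
rebuilt on the tagged corpus and propagation runs with the tags as seeds,
weighted (3, 2, 1) outward-in by default — any strictly decreasing triple
recovers the planted severity ranking in the generator experiments. Tag
tokens are removed from the returned lexicon. Repeating per condition
yields five severity classifiers.

## Scoring

Token valences are looked up in a lexicon; a negator within the three
preceding tokens flips and damps the valence by −0.74; an intensifier
scales the immediately following valence by its per-word factor; all-caps
lexicon tokens add 0.25 to the magnitude and each exclamation mark (up to
three) adds 0.292 to the summed magnitude. The summed valence maps to
`v / sqrt(v^2 + 15)`, the familiar rule-based social-media normalization,
so scores lie strictly inside [-1, +1]; empty or out-of-vocabulary text
scores 0. All constants sit in `modifier_config()` and the whole modifier
layer can be disabled (`enabled = FALSE`), which some users prefer for
severity-scale scoring; both paths are supported and default to on. Each
scored post carries its contributing-token trace, from which the score is
exactly recomputable — the white-box property that motivates a lexicon
method over a black-box classifier.

## Response analysis

Binned curves divide a condition axis (raw or z) into 30 evenly spaced
bins spanning the observed range (right-closed, first bin closed both
sides); bins holding fewer than 0.1% of posts are flagged excluded. Pair
grids aggregate mean score over a rectangular lattice on two z axes and
exclude cells with fewer than 5 posts — rectangular rather than hexagonal
cells, since the hexagon is a display choice, not an inferential one, and
the exclusion logic is identical. Post scores can be standardized within
regions (n−1 divisor; zero-spread groups are flagged and yield missing
values). Region assignment takes points by containment and polygons by the
50% overlap-area rule against convex region polygons (planar areas via
convex clipping; adequate at sub-degree extents). Curve comparison uses
Pearson correlation over bins included in both curves — the curves must be
built on shared edges — with Spearman available.

The pipeline's central observable property: when two regions share a
standardized mood response to weather anomalies but differ in climate
baseline and in how intensely mood is expressed, their raw curves diverge
while their (z-condition, z-score) curves align; the package's tests
assert the strict correlation increase over ten paired 50,000-post
generator runs.

## The synthetic generator

The generator emulates the study design end-to-end. Weather is a
stationary AR(1) process per cell and condition around region-specific
baselines (autoregressive coefficient 0.7 — day-to-day weather persists;
the exact value is immaterial to the properties tested and is
configurable). Posts draw a uniform cell and date, compute the generating
z-scores, and set a latent mood `m = s_region * (f(z) + eps)` where `f` is
a piecewise-linear response (flat at −0.3 below z = −2, peak +0.3 at
z = 1.5, falling to −0.2 at z = 3; only temperature carries a response by
default) and `eps` is Gaussian with standard deviation 0.15 — noise of the
same order as the response amplitude, so mood is a weak signal relative to
topical variation, as in real text. `s_region` is the region's
expressiveness multiplier. Tokens are drawn with probability proportional
to `exp(lambda_w z + s_w m)` from a fixed 870-token vocabulary (500
neutral fillers, 60 loaded tokens per scale ordered low-to-high extreme,
10 emojis) shipped as a TSV fixture; loadings are evenly spaced over
[−2, 2]. Post length is Poisson(12) truncated to at least 3 by redrawing,
and every clean post contains the literal token "weather" so the thematic
filter never removes clean content.

Contaminants are injected with deterministic ceiling accounting so filter
tests can assert exact counts: `ceiling(bot_fraction / bot_account_share)`
bot accounts each posting `ceiling(bot_account_share * n)` automated
updates; station accounts with "weather" in the username posting a fixed
count each; `ceiling(fraction * n)` unit-formatted and idiom posts. Clean
posts are assigned round-robin over a pool of 200 accounts, so no
legitimate account can cross the high-volume threshold. Identical seeds
give byte-identical corpora.

What the generator does *not* emulate: grammar and topic drift, retweet
structure, user demographics, spatially correlated missingness, or
adversarial bots. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and well-calibrated under the stated
generative assumptions — not that any particular real platform corpus
would yield the same fidelity.

## Numerical choices and degenerate inputs

- Nearest-node ties: smallest cell id. Percentile-band ties: stable
  original order. High/low band collision (all z equal): low tag wins.
- sigma = 0 climatology cells: degenerate flag, missing z, warning.
  Fewer than 30 non-missing reference days: cell unusable.
- All condition values identical in a binned curve: a single degenerate
  bin with a warning.
- Propagation: tol 1e-6 max-norm, cap 10,000 iterations; isolated nodes
  receive polarity 0 before standardization.
- Valences are clipped to [-1, +1] only against floating-point overshoot
  of `tanh`.
- Exclusion rules are inclusive at the boundary: a bin holding exactly
  0.1% of posts, a cell with exactly 5, and a polygon with exactly 50%
  overlap are all kept.

## Problem sizes in the test suite

The suite validates recovery at the sizes a single desk machine handles
comfortably: 20,000-post corpora for lexicon recovery (Spearman ≥ 0.7 and
sign accuracy ≥ 90% for strongly loaded tokens under the default and an
alternative tag-weight triple), ten paired 50,000-post corpora for the
regional-normalization property, 10,000-post corpora for brute-force
aggregation oracles (agreement to 1e-12), and 365–7,300-day fields for
climatology checks.

## Known limitations

Irony and sarcasm defeat any lexicon method. The induced scales are
corpus-specific by design — a lexicon trained on one corpus should not be
reused on a linguistically different one. Region polygons must be convex
for the overlap rule (real administrative regions can be handled by convex
decomposition or a dedicated geometry library). Weather fields are read
from long-format CSV; no NetCDF reader is bundled. p-values from curve
correlations are descriptive; no multiple-testing correction is applied.
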