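---
title: "Dynamic networks for scanpaths over moving targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic networks for scanpaths over moving targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(gazenet)
```

## The problem

When an observer monitors a display of many moving, labeled targets — the
motivating case is an air-traffic radar scope, where each aircraft is an icon
with an attached data block — the usual whole-session gaze statistics
(fixation counts and dwell per area of interest, AOI) can mislead. Targets
enter and leave, drift across the display, and overlap; which targets matter
changes over the session. `gazenet` analyzes such recordings as a *dynamic
network*: the session is split into time intervals, and each interval's
scanpath becomes a weighted directed graph whose vertices are the AOI states
actually fixated and whose edge weights count the attention shifts between
them. Network centralities, recomputed per interval, then quantify how each
target's importance evolves.

## From fixations to sequences

The input is a detected-fixation stream (onset, duration, display
coordinates; we assume fixations are already extracted, with a 100 ms
duration threshold as the default filter) plus per-timestamp target
geometry. Each target's AOI at time $t$ is the axis-aligned bounding box
covering its icon and data block, inflated by a visual-angle margin
converted to pixels from the viewing geometry
($\text{margin}_{px} = \tan(\theta)\, d_{cm}\, \rho_{px/cm}$; defaults
$\theta = 0.75^\circ$, the midpoint of a typical $0.5$–$1.0^\circ$ tracker
accuracy band, $d = 60$ cm, and the pixel pitch of a 2048-px, 19.83-inch
display, giving about 32 px). A bounding box is deliberately simpler than a
convex dynamic contour: it is reproducible, parameter-light, and faithful to
the tolerance it implements. Geometry is interpolated linearly between
trajectory samples, and each fixation is aligned with the geometry at its
onset.

A fixation landing in one box yields a single-letter state (`A`); in an
intersection of boxes, a composite *overlap state* (`(A;B)`, members sorted
uppercase-then-lowercase); in no box, it is dropped from the sequence (the
count is logged). Within each half-open window $[t_0, t_1)$ — membership by
onset, so windows partition the timeline — the hits form the raw AOI
fixation sequence, which is then *collapsed* (`AABCC` → `ABC`) because
repeated fixations on one target carry no information about shifts of
attention. Collapsing happens after off-AOI drops, so `A`, (off), `A`
collapses to `A`. Fixations are assigned to windows by onset alone; a
fixation straddling a boundary is not split.

## The per-interval network and its measures

For interval $t$ with $m_t$ unique states, the transition matrix
$M_t = [w_{ij}(t)]$ counts adjacent ordered pairs of the collapsed
sequence; its diagonal is structurally zero and its grand total is the
collapsed length minus one. Because each interval is one walk through the
graph, $|\text{in}_j - \text{out}_j| \le 1$ per vertex, with equality
everywhere exactly when the interval starts and ends on the same state.
Transitions never span interval boundaries.

Three time-resolved importance measures are computed on each interval's own
vertex set:

* **Indegree** $I_j(t) = \sum_{k \ne j} w_{kj}(t)$ — direct attention
  received.
* **Closeness** $C_j(t) = \sum_{k \ne j} 1 / d^*_{jk}(t)$, where the
  distance of an edge is the *reciprocal* transition count ($1/w$, infinite
  for absent edges) and $d^*_{jk}$ is the shortest-path distance. Frequent
  transitions make targets "close"; an unreachable target contributes 0
  (the harmonic convention, which the reciprocal form extends naturally to
  disconnected pairs).
* **Betweenness** $B_j(t) = \sum_{k \ne l \ne j} SP_{klj}(t) / SP_{kl}(t)$,
  the fraction of shortest paths between other vertices passing through
  $j$ — the bridging role in the flow of attention.

Shortest paths are found with Dijkstra's algorithm ($O(m_t^2)$ per source,
ample at AOI scale); path-length ties are recognized at relative tolerance
$10^{-9}$ (lengths are sums of unit fractions, so genuine ties are common),
and *all* tied paths are counted, via the standard tight-edge factorization
$SP_{klj} = \sigma_k(j)\,\sigma_j(l)$. With strictly positive distances
every shortest walk is simple, so no cycle guard is needed. The test suite
checks these routines against exhaustive simple-path enumeration on
hundreds of random digraphs and against an independent graph library.

On the four-interval worked example shipped with the package
(`demo_sequences.tsv`), interval 1's sequence `ABABABEBAEAEACACAEA` yields
the matrix with $w_{AB} = 3$, indegree of `B` equal to 4 (falling to 3 in
interval 2), and $d^*_{BE}(1) = \min(1/1,\; 1/3 + 1/3) = 2/3$. Direct
evaluation of the definitions on this network gives closeness $5.7$ and
betweenness $0$ for `B` — note that on four vertices betweenness is bounded
by $(m_t - 1)(m_t - 2) = 6$ ordered pairs, so values above 6 cannot arise
from the formula; the package reports the equation-derived values.

## Normalization

Measures from intervals with different $m_t$ and fixation budgets are not
comparable raw. Two per-interval normalizations are provided:

* **Percent normalization** (indegree only): $\bar I_j = I_j / \sum_k I_k$,
  the share of received attention; shares sum to 1. It is restricted to
  indegree because the sums of closeness or betweenness have no such
  interpretation; requesting it for them is an error, not a silent result.
* **Distance normalization** (all three measures):
  $(v - \min)/(\max - \min)$, mapping the interval's extremes to 0 and 1.
  When every AOI ties ($\max = \min$) all values map to 0 with a warning —
  this keeps the "distance from the maximum" reading and avoids a 0/0.

Normalization is always within interval; pooling across intervals or
participants would reintroduce the incomparability it exists to remove.

## Visualization

All three renderers return plain attribute tables (positions, sizes,
colors, widths) alongside the ggplot, so downstream checks never parse
image bytes.

* **Small multiples** (`plot_dnet()`): one node-link panel per interval.
  States are ordered singles-first (uppercase then lowercase, alphabetical),
  then overlap states by member count and lexicographic form, and placed on
  a grid filled from the bottom-left, with $\lceil\sqrt n\rceil$ columns —
  the only reading of a "rectangular grid" that reproduces a six-state
  3-by-2 arrangement. A state keeps one cell across every panel
  (mental-map preservation); states absent from an interval are ghosted,
  their cell reserved. Node area tracks fixations received, node color a
  yellow-to-red dwell scale (bounds global across panels by default so
  color is comparable; per-interval bounds are available), edge width the
  transition count. Only proportionality is fixed; absolute scale factors
  are configurable via `dnet_encoding()`.
* **Dot plot** (`plot_indegree_dots()`): states by intervals, dot area the
  percent-normalized indegree; zero shares draw no dot.
* **Grouped bars** (`plot_measure_bars()`): distance-normalized values for
  one interval, grouped by measure (one observer) or by participant (one
  measure; only AOI states common to all participants are drawn, so the
  comparison is like-for-like). The axis is fixed to $[0,1]$.

```{r worked-example, message = FALSE, warning = FALSE}
seqs <- read_sequence_file(system.file("extdata", "demo_sequences.tsv",
                                       package = "gazenet"))
dnet <- dnet_from_sequences(seqs)
measure_table(dnet)
plot_dnet(dnet)$plot
```

## The synthetic scenario generator

No public recording of this kind exists, so the package ships a generator
that emulates an enroute-like scenario and a plausible scanpath over it —
it is first-class, tested code, and the study conditions for every
statistical check in the test suite.

* `simulate_targets()`: by default 39 targets labeled `A`–`Z`, `a`–`m` over
  a 20-minute, 2048-px scenario with on average 20 targets present —
  presence spans are jittered around `duration * avg_on_screen / n_targets`.
  Motion is constant-velocity and piecewise linear (reflected at the
  display edges); the data block rides at a fixed offset. Overlap episodes
  steer one target of a pair alongside the other for a stated span (with a
  5 s blend in and out), and an episode whose pair is not co-present is an
  error rather than a silent no-op.
* `simulate_scanpath()`: a first-order Markov chain over targets; dwell
  durations log-normal (median 300 ms, $\sigma_{\log} = 0.5$) truncated at
  the 100 ms detection threshold; fixations land at the AOI box center plus
  optional Gaussian jitter; optional stray fixations that do not advance
  the chain. If the planned target has left the display the step resamples
  among present targets (logged).

What the generator does *not* emulate: saccade dynamics, smooth pursuit,
center bias, blinks, tracker noise correlated over time, or task-driven
(conflict-seeking) scanning. Tests passing on synthetic data therefore
validate the *bookkeeping and the mathematics* — hit testing, sequence
construction, counting, centralities, normalization, determinism — not any
behavioral claim about real observers.

Two checks tie the ends together, at sizes chosen to keep the full suite
under a minute: a 10,000-fixation run whose empirical transition matrix
must sit within 0.05 of the generating chain — matrix discrepancy defined
as the *maximum row-wise $L_1$ distance* between the conditional
next-target distributions, the natural metric for row-stochastic matrices —
and a 5,000-fixation run whose recovered indegrees must order the targets
as the chain's stationary distribution does. The enumeration oracle runs on
500 random digraphs of up to six vertices with integer weights 0–5.

## Degenerate inputs and numerical choices

* Empty windows yield empty sequences (warning) and empty networks; they
  contribute no measure rows.
* A single-vertex interval has all measures zero except its fixation count.
* Unreachable pairs contribute 0 to closeness and no betweenness terms.
* Path-length equality: relative tolerance $10^{-9}$; exact rational
  arithmetic would also work, the tolerance makes the floating-point
  implementation safe.
* All file writers are deterministic: identical inputs give byte-identical
  sequences, matrix, and measure files, which the test suite asserts.

## Limitations

The AOI construction is a bounding box, not a convex contour following the
icon silhouette, so hits in box corners slightly overcount containment.
Measures are per interval by design; nothing flows across interval
boundaries (the pair formed by the last state of one interval and the first
of the next is counted nowhere), and time-respecting path centralities
across intervals are out of scope. Interval boundaries themselves are a
researcher choice — equal counts or explicit cuts are supported,
data-driven (event-based) segmentation is not.
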