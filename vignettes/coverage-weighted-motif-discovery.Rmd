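---
title: "Coverage-weighted motif discovery: model and design notes"
author: "exomotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-weighted motif discovery: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomotif)
```

## The problem

ChIP-exo experiments localize transcription-factor binding at near
base-pair resolution: each called narrow peak carries, besides its
sequence, a per-base sequencing coverage profile that is highest where the
protein actually touched the DNA. Classical de novo motif finders use only
the sequences; `exomotif` weights every sequence position by its coverage,
so segments under the coverage summit contribute more to motif discovery
than segments at the peak's edges.

Discovery proceeds in five stages, all driven by two elementary
statistics: an upper-tail binomial similarity score for segment pairs, and
an upper-tail binomial co-occurrence test for motif pairs.

## Coverage normalization and the strand matrix

Raw per-base coverage $x_i \ge 0$ is normalized per peak to
$\log(1+x_i) / \max_j \log(1+x_j)$, so every peak's best-covered base gets
weight 1 (the log base cancels in the ratio; an all-zero profile stays
zero). For $m$ peaks the pipeline works on $2m$ rows: row $2k-1$ is peak
$k$ forward, row $2k$ its reverse complement carrying the reversed
coverage vector — the only choice under which a physical base keeps its
weight on both strands. In sequence-only ("basic") mode every weight is 1.
Peaks of unequal length are kept ragged; all loops run to each row's own
length.

## Two-stage alignment

For two length-$l$ segments with $k$ identical positions (positions where
either base is `N` never count), the similarity is the upper-tail binomial
probability at the uniform background rate 1/4,

$$f(k) \;=\; -\log_{10} \sum_{j=k}^{l} \binom{l}{j} 0.25^j\, 0.75^{\,l-j},$$

computed in log space so wide segments do not underflow. $f(0)=0$ and
$f(l) = l\log_{10}4$ ($\approx 8.43$ at the default $l=14$). The weighted
score of a segment pair is $f' = f \cdot (w_a + w_b)$ where $w$ is the
per-row weight at the segment start.

Every pair of rows from *distinct* peaks (all four strand combinations; a
sequence is never aligned to itself or its own reverse complement) is
scanned exhaustively. A segment start gains one support count when
$f > \tau$ (default $\tau = 3$, i.e. tail probability $<10^{-3}$) or when
$f'$ ranks in the top $\alpha$ (default 5) over that row pair. Ties at the
cutoff are all kept; pairs with $f' = 0$ never rank — a zero-significance
alignment is no evidence. The score is symmetric in the two rows, so
ranking the unordered pair once is equivalent to ranking both directions.

The first pass uses coverage weights and yields the support-count matrix;
the second pass rescores with
$f' = f \cdot \max\, (M^1_{a,j'} + M^1_{b,q'})$ over starts within two
bases of $j$ and $q$ (true motif instances produce support at or next to
their exact position, so the window forgives 1–2 bp jitter; it truncates
at row ends). Both the coverage matrix and the second-pass counts are then
row-max normalized and summed — the combined per-position weight that
drives graph construction.

## Graph and cliques

Segment pairs ranking in the top $\beta$ (default 3) per row pair under
the combined weight become edges between segment vertices. Potential
motifs are vertex-disjoint cliques extracted greedily: seed at the
unused vertex of highest degree (ties by incident weight, then row and
start), grow by the candidate adjacent to every member with the largest
summed edge weight into the clique, subject to at most one vertex per
peak (a clique never holds both strands of one peak: one binding event
yields one strand-resolved site). A clique of at least `min_clique_size`
(default 3) retires its vertices; a seed that cannot reach that size
leaves the seed pool but remains joinable by later cliques, which keeps
the reported cliques maximal with respect to vertices no clique claimed.
The exact clique heuristic is the largest open design choice in this
reconstruction; the greedy rule above is deterministic under its stated
tie-breaks, which is what the strand-equivariance and byte-identical
reproducibility tests rely on.

## Bookend width optimization

A motif wider than $l$ appears as several cliques reading overlapping
$l$-windows of the same underlying site, on both strands. For motif pair
$(c_i, c_j)$ with $n_i \ge n_j$ instances, the co-occurrence count
$o_{ij}$ is the number of one-to-one nearest-matched instance pairs on the
same peak (minus-strand coordinates mapped to forward first) whose joint
span fits a window of $d = 25$ bp. Its significance is the binomial tail

$$P(o_{ij}) = \sum_{k = o_{ij}}^{n_j} \binom{n_j}{k} p^k (1-p)^{n_j-k},
\qquad p = \min\!\left(1, \frac{d\, n_i}{m\, n}\right),$$

with $n$ the mean peak length on ragged input. Pairs with
$P < 0.05$ merge: the modal *positive* overlap of the counted pairs
(ties toward the larger overlap) becomes $\ell_o$, and each counted pair
at that overlap contributes the union span of its two instances — width
$\ell_x = w_i + w_j - \ell_o$, which is the classical $2l - \ell_o$ when
both parents still have segment width $l$. Merges whose modal-overlap set
has fewer than two pairs are rejected (a PWM cannot be refit from one
instance), and merges whose modal overlap would be non-positive are
rejected too, since the union span would then outrun the windowed
evidence.

Two design choices here deserve justification. First, *every* significant
pair produces a merged motif — there is no exclusive pairing. Exclusive
most-significant-first pairing was tried and systematically reassembled
adjacent shifted fragments (overlap $l-1$, width $l+1$) while consuming
the cliques that could have spanned the full motif; with all-pairs
merging the full-width combination is always among the seeds and the
final ranking arbitrates. Second, merge rounds repeat (default 3, capped
at 40 seeds carried by instance mass) so partial merges can combine
toward the full span; a round that creates nothing new stops the
iteration. Duplicated instance sets are removed.

## PWM refinement and expansion

Each seed's instances are stacked into base counts with a Laplace
pseudocount of 1 spread 0.25 per base (`N` contributes 0.25 to every
base), giving frequencies $p(i,j) = (\mathrm{count} + 0.25)/(n+1)$ and
log-odds $\log_2 p(i,j)/q(i)$ against the genome background $q$ (peaks
are the fallback source when no genome is supplied; zero frequencies are
lifted to $10^{-6}$). Log base 2 is conventional for log-odds and only
rescales scores — thresholds are defined through instance scores, so the
base never changes a decision.

The match score of a width-$\ell_x$ segment at start $j'$ of row $i'$ is

$$S = \tfrac{1}{2}\Big(\max_{j'-t \le j'' \le j'} w_{i'j''} +
\max_{j' \le j'' \le j'+\ell_o+t} w_{i'j''}\Big)
\sum_j \mathrm{PWM}[\,b_{j},\, j\,],$$

with $t = 2$ flanks, windows truncated at row bounds, `N` bases scored at
their column mean, and $w$ the row-max-normalized coverage. For seeds that
never merged, $\ell_o := \ell_x$ so the second window covers the whole
segment plus flank; for merged seeds the window runs to $j' + \ell_o + t$
as the formula states, which is shorter than the segment — the intent
(midpoint versus end) is ambiguous and the formula is implemented
verbatim rather than silently "fixed". In basic mode both maxima are 1
and $S$ is exactly the log-odds sum.

Expansion admits every segment on every row (both strands) scoring
strictly above the weakest current instance, except segments overlapping
an existing instance of the same row by more than half the width, which
would merely stack shifted copies of one site. The PWM is then rebuilt.
One pass is the default: the threshold is the minimum over current
instances, so iterating lets weak admissions lower the bar further —
on noisy data this can cascade into degenerate thousand-site motifs, and
a single pass avoids that failure mode while already recovering sites the
clique stage missed.

Final motifs are ranked by the sum of their instances' match scores — the
quantity the expansion step itself optimizes. It rewards both site
support and informative width, so a full-width merged motif can outrank
its narrow fragments. A motif whose sites are at least 80% covered by a
single higher-ranked motif of at least its width is then dropped as a
shifted duplicate; wider variants of a reported motif are kept, since
they record the bookend stage's full-span reassembly. A known limitation
remains: a narrow fragment that recruits more sites in expansion can
still edge out the full-width variant, so the top-ranked motif is
occasionally a ~$l$-wide core of a wider true motif whose full-width
version sits lower in the list.

## Evaluation protocol

A motif classifies a sequence by its maximum plain log-odds window score
over both strands (no coverage term: genome-sampled negative sequences
carry none). Performance is summarized by two restricted partial areas
under the empirical ROC curve — over FPR in $(0, 0.2)$ (specificity
variant) and TPR in $(0.8, 1)$ (sensitivity variant) — each McClish-
standardized against the band's chance and perfect areas so that a
perfect classifier scores 1 and an uninformative one 0.5. Both metrics
are invariant to monotone transforms of the scores; tied scores produce
the usual diagonal ROC segments.

## The synthetic generator

`generate_planted_dataset()` emulates the features the pipeline actually
exploits: i.i.d. background bases; one instance per selected peak sampled
column-wise from a known PWM, on a uniform strand at a uniform position;
coverage equal to a baseline of 1 plus a triangular bump (default height
9, half-width 30 bp) centered on the planted site, then log-normalized.
The bump is triangular rather than Gaussian to keep fixtures
integer-friendly; defaults are 20 peaks of 200 bp, plant rate 0.9, and a
planted PWM at about 1.8 bits per column — a strong bacterial TF on a
typical narrow-peak set. `generate_split_motif_dataset()` plants a single
22 bp motif (per-column noise 0.05) so discovery at $l = 14$ must
reassemble the width through the bookend stage.

What the generator does *not* emulate — 5'-border exonuclease footprints,
position-dependent base composition, overlapping or multiple sites per
peak, real coverage noise — bounds what passing tests show: they validate
the statistics, the reassembly logic and the coverage weighting, not
performance on any real dataset.

## Problem sizes and determinism

The validation suite runs the full pipeline on 20-peak, 200-bp datasets
(a few seconds each), compares the optimized alignment against a plain
quadratic reference on 50 random instances with $m \le 5$, $n \le 40$ at
$l = 8$, checks clique maximality exhaustively on graphs of at most 15
vertices, and enumerates binomial tails exactly for $l \le 8$ and
$n_j \le 12$. Every stage is deterministic given the input; randomness
enters only through the generator and negative sampling, both seeded, so
a fixed configuration reproduces byte-identical MEME output.

```{r example}
sim <- generate_planted_dataset(plant_spec(m = 12, peak_len = 120, seed = 7))
fit <- exomotif(sim$peaks)
summary(fit)
site_recovery(fit, sim$truth, sim$peaks, 14)
```
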