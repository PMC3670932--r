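---
title: "An Alu element-based model of relative gene deletion instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An Alu element-based model of relative gene deletion instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluscape)
```

## The model

Alu elements — ~300 bp primate SINE retrotransposons with over a million
genomic copies — are placed in both orientations essentially at random, yet
widely spaced *inverted* Alu pairs are statistically rarer than *direct*
pairs. `aluscape` implements a model that treats this inverted:direct (I:D)
pair deficit as the footprint of inverted-pair instability: ectopic
interaction between the two members of an inverted pair can expose each end
of each Alu to a double-strand break (the "two-hit" premise, two potential
DSB sites per element), and the ensuing deletions remove inverted pairs from
the genome. Under that reading, the predicted I:D ratio of a pair is its
probability of surviving — its *stability* — and a genome-wide calibration of
I:D against pair geometry turns repeat annotations into a relative deletion
risk score for any gene.

Three pair covariates carry essentially all of the I:D signal:

* **spacer** — the intervening sequence between the two Alus, measured
  between element edges (an overlap or book-ended annotation counts as
  spacer 0);
* **APSN** (Alu pair sequence number) — one plus the number of Alu elements
  strictly inside the spacer, signed by whether the partner lies 5′
  (negative) or 3′ (positive) of the focal element; the unsigned value is
  the rank distance along the chromosome's Alu list;
* **clustering type** — Alu, LINE1 and SVA elements cluster into CLIQUEs
  (runs of ≥2 elements with consecutive gaps ≤ 50 bp). Type 0 pairs share a
  CLIQUE, Type 1 pairs occupy two different CLIQUEs, Type 2 pairs are
  hemi-clustered, Type 3 pairs unclustered. The three clustered states have
  distinctly different I:D behaviour and are calibrated separately; Type 0
  pairs are dominated by orientational insertion bias and are handled by a
  dedicated short-spacer rule.

### Calibrating the I:D surface

`fit_id_surface()` runs a five-step calibration on full-length
(275–325 bp) Alu pairs:

1. enumerate pairs per APSN family (1..`apsn_cal_max`, default 115) and per
   pair type 1–3; small–small and small–medium pairs at APSN ≤ 10 are
   excluded (they sit inside tandem-repeat annotation artifacts);
2. sort each family's spacers and cut them into ten percentile groups — the
   smallest 5% (the "2.5th percentile" group) followed by nine 10% bands
   centred on the 10th…90th percentiles — recording inverted/direct counts,
   their ratio, and the median spacer per group;
3. pool the groups of one percentile label across all APSN families into one
   series per (type, percentile) — counts are summed, never averaged as
   ratios — and regress the series against log10(median spacer + 1);
4. evaluate the ten fitted percentile curves back at each APSN family's own
   median spacers, giving ten (median spacer, fitted I:D) anchors per
   (type, APSN);
5. keep the APSN range with statistical support: an APSN is informative if
   at least one anchor falls below the significance cutoff (default 0.995,
   the I:D value distinguishable from unity at p < 0.05 given a stratum of
   at least 507,000 pairs — both constants are configurable metadata and are
   honoured rather than re-derived, because the exact test behind the
   printed pair of constants is not uniquely determined: a one-sided exact
   binomial test reproduces ≈ 431,000 and a two-sided ≈ 612,000). The
   largest informative APSN becomes `apsn_max`; on genomic data this is 110.

The percentile regression (step 3) is a weighted segmented polynomial:
degree-2 segments in log-spacer, with breakpoints chosen by exhaustive
dynamic programming over the ordered series and the number of segments
(≤ 3) selected by BIC. Genuine regime changes — and the underlying
pair-loss process does produce sharp ones — get their own segment, while a
smooth or flat series collapses to a single polynomial; a degenerate design
falls back to piecewise-linear interpolation with a warning. Evaluation
clamps the abscissa to each segment's fitted span (flat extension, no
polynomial extrapolation) and fitted values to (1e-6, 1.25].

### Prediction

`predict(surface, pairs)` maps each pair to a stability in (0, 1]:

* direct pairs → 1 (the calibration attributes no instability to them);
* inverted pairs with |APSN| > `apsn_max` → 1;
* otherwise the (type, APSN) anchor curve is interpolated linearly in
  spacer; spacers below the 2.5th-percentile median take that anchor's
  value, and spacers above the 90th-percentile median ramp linearly to 1 at
  the family's stored 99th-percentile spacer (estimated from the
  calibration pair population, since only the percentile itself is
  specified) and are 1 beyond it;
* any value above the significance cutoff is assigned exactly 1; everything
  is floored at epsilon = 1e-6 so that downstream root-products remain
  positive and finite.

Type 0 pairs with spacers ≤ 50 bp use a separate rule anchored on
inverted-repeat instability measured in a yeast experimental system at
spacer sizes 12, 20, 30 and 100 bp. Typical human Alu pair homology is
~85%, between the yeast 94%/100% homology series, and the genomic
calibration supplies one fixed point: the Type 1 2.5th-percentile APSN-1
anchor, whose median spacer in genomic data is ~100 bp. The functional form
of the original rule is not published as an equation, so the package
implements a named, swappable strategy (`yeast_rescaled`): a monotone cubic
Hermite interpolant through (12, 0.60·A), (20, 0.75·A), (30, 0.85·A),
(100, A), where A is the Type 1 anchor. The 0.60/0.75/0.85 rescaling
fractions are package defaults chosen once to reproduce the qualitative
yeast pattern (instability rising steeply as spacers shrink below ~30 bp);
they are recorded in the surface file and flagged there as a stand-in.
Type 0 pairs with spacers > 50 bp are routed to the Type 1 curves.

### From pairs to elements, exons and genes

Each Alu element forms up to 2 × `apsn_max` pairs with its flanking
neighbours. With `s(p)` the predicted I:D of pair `p`:

* element stability = ∏ s(p)^(1/2); the square root splits a pair's
  survival between its two members;
* end stability = ∏ s(p)^(1/4); each element has two potential DSB ends and
  both share one end stability (the calibration does not resolve sides);
* `Risk_End` = 1 − end stability; `iScore` = 1 / element stability (used
  for landscape tracks).

Deletion reach is modelled by `deletion_size_model()`: a probability mass
function over deletion sizes 1..500,000 bp, piecewise log-log linear with
two segments joined continuously at 75 bp (the two source indel spectra
are informative below and above roughly that size). Its three free
parameters (two slopes, one normalising constant) are solved by nested
bisection so that the pmf sums to 1 and the cumulative mass reaches 95% at
50 bp and 99% at 445 bp. The solved slopes are −1.654 and −1.739 and the
implied extreme-tail ratio pmf(500,000)/pmf(1) ≈ 1.8e-10 satisfies the
model's one-in-a-billion bound, which is asserted after solving rather
than imposed. Deletions extend equidistant from the initiating DSB, so an
end `D_Min` bp from an exon needs a deletion of at least 2·`D_Min`;
`p_deletion()` returns that upper-tail mass (1 at `D_Min` = 0, 0 beyond
250,000 bp).

Risk sources for a gene are both ends of every Alu within the coding span
or within `flank_bp` = 250,000 bp of its ends (boundary inclusive). Their
stability context uses partners up to a further `context_bp` = 421,000 bp
outside the window — 421,000 bp being the spacer at which the calibrated
I:D curve crosses the significance cutoff, so that an Alu up to
671,000 bp from an exon can still matter through a partner inside the
flank. The exon and gene scores are survival products:

* `Exon_RS` = ∏ over risk ends (1 − Risk_End · P_Deletion(D_Min to that
  exon));
* `Gene_RS` = the same product with each end paired to its *closest*
  coding exon (its highest-risk target), so gene stability never exceeds
  any exon stability.

The source formulas exist only as images in the original account; the text
describes a "grand product of Risk_End × P_Deletion products". This
package implements the survival-product reading ∏(1 − Risk·P) because it
is the only one consistent with every numeric anchor: it yields stability
1 (reported 100 on the 0–100 scale) for an Alu-free landscape and
probabilities that remain in (0, 1]. Products are accumulated in log space
(`log1p`) for numerical stability; all stabilities stay strictly positive.

`sensitivity_scan()` re-scores a cohort while the fraction of deletions
≤ 50 bp sweeps 0.90..0.99 in steps of 0.01. The rebuild holds the upper
(tail) slope of the reference model fixed and re-solves the lower slope
and normalisation for the new 50 bp target, letting the 445 bp checkpoint
float — a joint retarget would be infeasible at 0.99. Note the direction
of the effect: concentrating more mass below 50 bp steepens the small-size
slope and *shrinks* every upper tail, so `p_deletion` at a fixed distance
decreases as the fraction rises; genes with Alus within a few bp of an
exon therefore change *relative* standing against their cohort, and the
scan reports trajectories and rank changes without asserting a direction.
Alu end stabilities do not depend on the deletion model, so they are
computed once per gene.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `gap_bp` | 50 | bp | CLIQUE linkage gap |
| `apsn_cal_max` | 115 | — | APSN range examined in calibration |
| `apsn_max` | from data (110 genomic) | — | significant APSN range used in prediction |
| `significance_cutoff` | 0.995 | I:D | values above are assigned 1 |
| `min_n` | 507,000 | pairs | stratum size paired with the cutoff (metadata) |
| `min_pairs` | 1,000 | pairs | smallest (type, APSN) family binned |
| `flank_bp` | 250,000 | bp | direct-risk landscape half-width |
| `context_bp` | 421,000 | bp | extra partner context beyond the flank |
| `frac_le_50` / `frac_le_445` | 0.95 / 0.99 | — | deletion-size cdf targets |
| `breakpoint_bp` | 75 | bp | deletion-model segment join |
| `epsilon` | 1e-6 | — | positive floor on predicted I:D |

Calibration size classes are closed bins: small 30–135 bp, medium
136–274 bp, full-length 275–325 bp. Elements above 325 bp are retained and
scored with the full-length surface — I:D does not correlate appreciably
with Alu length, and no upper tail is excluded by the calibration — while
fragments below 30 bp are dropped on input as out of model scope.

## The synthetic landscape generator

`simulate_landscape()` emulates the statistical structure the model
consumes: Poisson placement at 381 Alu/Mb (the genome-wide average
density), independent random strand orientation, a three-class length
mixture over the small/medium/full-length bins (defaults 0.20/0.25/0.55,
chosen so that full-length calibration pairs dominate as they do
genomically), and CLIQUE bursts (default 45% of elements clustered, sizes
2 + geometric(0.5), intra-burst gaps uniform on 0..50 bp) separated by
gaps strictly greater than 50 bp so that detected cliques are exactly the
constructed bursts. It does **not** emulate sequence content, subfamily
age structure, chromosome-scale density waves, or the empirical spacer
marginal — so green tests demonstrate that the estimator machinery is
correct and internally consistent, not that genomic I:D surfaces look like
the synthetic ones.

`apply_thinning()` embodies the causal premise: inverted pairs matching a
rule `q(type, APSN, spacer)` lose one randomly chosen member with
probability q. It runs in sweeps to a fixed point; every pair (keyed by
its members) is drawn at most once, when it first matches the rule, and
deletions only ever decrease a pair's APSN, so pairs beyond the rule range
are never drawn while every surviving in-range inverted pair has survived
exactly one Bernoulli(1 − q) draw. The removal log therefore recovers q
exactly, and that is the generator's sharp guarantee.

Recalibrated anchors after thinning are a different matter, and the
package's tests quantify this deliberately: deleting members has
*collateral* effects that the idealised "anchors = 1 − q" picture ignores.
The two members of a surviving direct pair share their common neighbours'
removal draws (both threatened by the same events), while the members of
an inverted pair face complementary draws (exactly one per common
neighbour); concentrated threats are survived more often than spread-out
ones, so direct pairs are systematically favoured. At q = 0.2 over
APSN ≤ 5 this depresses recalibrated anchors at the thinned APSNs to
≈ 0.73 rather than 0.8, and anchors at APSN 6–10 (the common-neighbour
overlap range) to 0.90–0.95, while APSN > 10 is clean. The
parameter-recovery acceptance test asserts the idealised recovery bands
and is expected to flag the thinned-anchor clause; the discrepancy is a
real property of deletion semantics, not an estimator defect — the
deletion process reshapes neighbouring strata, exactly as the model's own
premise implies.

## Numerical and design choices

* Percentile cuts are direct quantile cuts on a stable sort of
  (spacer, enumeration order); the original incremental 0.03–0.05%
  stepping is equivalent at the percentile resolution actually used and a
  stable sort makes results deterministic.
* The nested bisection for the deletion model solves the 50/445 ratio in
  the inner loop (it depends mostly on the lower slope) and the 445/total
  mass in the outer loop, both to 1e-13.
* Stability products run in log space; predicted I:D is floored at 1e-6 so
  fourth-root grand products cannot underflow to zero.
* Pairs never span chromosomes; each chromosome is independent.
* Overlapping Alu annotations get spacer 0 and count as adjacent.
* Families absent from a calibrated surface (below `min_pairs`) borrow the
  nearest calibrated APSN of the same type at prediction time; absent
  types predict 1 with no risk contribution.
* Surfaces serialize to versioned JSON at 17 significant digits, so a
  write/read round trip reproduces predictions exactly; externally
  supplied anchor tables in the same schema are accepted.

Test problem sizes are chosen to exercise each property at the smallest
scale that determines it: oracle-equivalence landscapes use ≤ 50 Alus and
≤ 5 exons where brute-force enumeration is exact and fast; the
parameter-recovery experiment uses full-length-only unclustered genomes of
240 Mb (unthinned) and 585 Mb (pre-thinning) at 381 Alu/Mb, sized from the
507,000-pair stratum constant (pooled 2.5th-percentile count ≈ number of
Alus × 115 × 0.05, with thinning removing ≈ 59% of elements at q = 0.2
over APSN ≤ 5).

## Known limitations

* Direct-pair (NAHR) instability is not modelled; to the extent direct
  pairs also recombine, relative instabilities are underestimates.
* All outputs are relative stabilities; the model is not calibrated to
  absolute mutation rates.
* The Type 0 short-spacer rule is a documented monotone stand-in for an
  unpublished functional form; its rescaling fractions are package
  defaults.
* Whether the two ends of an element genuinely share one end stability is
  unresolved; the shared-value convention follows the textual definition
  of "the stability of one end".
* Pair interactions are intrachromosomal only, and no sequence homology
  beyond the fixed 85% assumption enters the model.
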