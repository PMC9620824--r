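---
title: "Detecting poly-alanine regions and analysing their sequence context"
author: "polyAcontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting poly-alanine regions and analysing their sequence context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAcontext)
```

## Overview

Poly-alanine (polyA) tracts are homorepeats found in a few percent of
eukaryotic proteins. They are associated with developmental disorders when
expanded, tend to adopt α-helical conformations, and — as this package lets
you quantify — live in a characteristic sequence context: glycine- and
proline-enriched impurities and flanks, a strong bias toward protein
N-termini in amniotes, and an association with mitochondrial transit
peptides (mTPs) and signal peptides (SPs).

`polyAcontext` implements the full analysis pipeline over any protein
FASTA: repeat detection, impurity statistics, flank composition and
enrichment, positional statistics with location stratification,
tripeptide-based secondary-structure propensity profiles, and
alignment-based emergence classification. A synthetic-proteome generator
with an exhaustive ground-truth ledger backs every stage with
planted-parameter tests.

## Repeat detection model

Two searches run independently, parameterised by a target residue
(default alanine):

* **Pure regions** (`detectPure`) are maximal uninterrupted runs of the
  target with length ≥ `minLen` (default 4, a deliberately lax threshold
  that casts a wide net).
* **Impure regions** (`detectImpure`) come from a sliding-window search:
  every window of `window` residues (default 6) holding at least
  `windowMinCount` targets (default 4) qualifies; qualifying windows are
  unioned, merged spans are trimmed so they begin and end on the target
  residue, and spans shorter than 5 residues or with fewer than
  `windowMinCount` targets are dropped.

Three points in this definition were genuinely open and are resolved as
package defaults, each behind a flag:

* *"four to five targets in a window of six"* is read as **≥ 4 in 6** —
  the 6-of-6 window is the pure case, so the impure criterion is the
  ≤ 2-impurity relaxation consistent with a minimum impure length of 5.
* **All-target spans are dropped** from the impure list
  (`requireImpurity = TRUE`): the two searches then partition regions
  cleanly and the union of hosting proteins is meaningful. Setting the
  flag to `FALSE` gives the inclusive variant.
* **Terminal windows shorter than `window` may qualify** on the same
  count rule, so a protein ending `…GAAAA` yields the same calls as its
  reverse. (For sequences at least as long as the window this provably
  changes nothing: any qualifying short terminal window is contained in a
  qualifying full window, and trimming removes the difference.)

Coordinates are 1-based and inclusive throughout — "position 2" is the
residue right after the initial methionine.

## Composition and enrichment statistics

Background frequencies (`backgroundComposition`) are computed over the 20
standard letters of the whole proteome; ambiguity letters (X, B, Z, U, O)
are excluded from numerator and denominator so every frequency vector
lives on exactly 20 letters.

Impurities inside impure regions are tabulated per region length class
(5, 6, >6 — classes count region length, matching how the count table is
organised) and pooled; the pooled frequency divided by background is the
headline "All/Bg" ratio. The relative position of an impurity at 1-based
offset $k$ in a region of length $L$ is $(k - 0.5)/L$, chosen so the
centre of any region is exactly 0.5 and "second half" means > 0.5; the
paper-style boxplots come from the per-letter, per-class samples.

Flank composition (`positionalComposition`) looks at positions −10…−1
before the region start and +1…+10 after its end. Positions beyond the
protein's ends reduce the denominator (no pseudo-letters), and flank
residues are **not** masked when they belong to other regions — alanine
enrichment around polyA is part of the signal, not an artefact.
Enrichment is the elementwise ratio to background, and `markerSummary`
extracts the cross-species markers: G+1, M−1, S±1, V±1, plus "P" and "G"
as the mean ratio over all 20 flank positions (averaging positions, not
occurrences, to match the per-position presentation).

## Position in the protein, mTP/SP table, tests

`relativePositions` reports midpoint mode by default
($((start+end)/2)/L$) — a long N-terminal repeat should not look
artificially terminal — and start mode ($start/L$) because the mTP/SP
table classes are start-based. The table (`tpEnrichmentTable`) keys every
protein by the start of its most N-terminal region (ties at the same
start prefer the longer region): class "2", "3–20", ">20", plus "no
polyA" and "any". A region starting at position 1 has no initial
methionine before it, so it gets its own class "1" rather than
contaminating class "2"; "any" is the sum of all start classes, so
`no polyA + any = proteome size` holds identically.

`mannWhitneyU` reports the U statistic of the first sample with average
ranks for ties. For untied samples with $\min(n_a, n_b) \le 8$ the
two-sided p-value comes from the exact null distribution of U; otherwise
from the normal approximation with tie-corrected variance and continuity
correction. P-values are two-sided even where the scientific claims are
directional (direction is read from the group medians), and the pairwise
location tests are reported uncorrected by default with an optional Holm
flag — matching the conventional presentation of such tables.

## Structure propensity

A tripeptide propensity table maps each tripeptide to a probability
vector over 27 local-structure classes — the ordered triples over the
α/β/γ regions of the Ramachandran space, written `aaa` … `ggg` in ASCII.
The prediction at residue $i$ averages the vectors of the tripeptides
centred at $i-2 \dots i+2$ with weights $(1, 2, 4, 2, 1)$, renormalised
when neighbours fall off the sequence, and is reduced to
(`aaa`, `bbb`, `others`). The original predictor's analytical context
equation is not public in usable form, so this declarative centre-heavy
average — which respects the stated ±2-tripeptide context span and is
exposed through `contextWeights` — stands in its place; numerical
agreement with the published predictor is explicitly not claimed.
`contextWeights = c(0, 0, 1, 0, 0)` reproduces the raw lookup, a tested
identity, and probability is conserved exactly at every residue.

Profiles over regions (`aggregateRegionProfiles`) predict on the region
plus 12 flanking residues but report only ±10: the two outermost
positions absorb window-terminus artefacts. Position 0 pools all residues
inside all regions; flank positions average one residue per region.
Missing tripeptides fall back to the uniform 1/27 vector with a counted
warning, so partial fixture tables are usable.

## Emergence classification

`classifyEmergence` maps a repeat to its alignment columns (counting
non-gap reference positions) and measures the fraction of those columns
gapped in one named distant ortholog. Gap fraction ≥ 0.8 calls
*insertion*, ≤ 0.2 calls *substitution*, anything between is *mixed*. The
thresholds are package choices — the narrative source classification for
long repeats gives no operational cutoff — so they are config-exposed and
echoed in every call. Classification is deliberately pairwise; consensus
over several orthologs is a thin loop left to the caller.

## The synthetic generator

`syntheticSpec()` fixes the study conditions; `generateProteome()`
realises them deterministically under a single integer seed. Design
points worth knowing:

* **Defaults**: 1000 proteins of uniform length 150–400, uniform
  background, 300 pure regions (lengths 4–10) and 430 impure regions
  (lengths 5–10 with 1–2 impurities) — one region per hosting protein,
  270 proteins left empty so the "no polyA" class is populated.
  Impurities are drawn with proline at exactly 3× background (remaining
  letters rescaled), glycine is planted at flank position +1 with
  probability 0.4 (otherwise a draw excluding both A and G, so the
  planted frequency is exact in expectation), 25% of regions start at
  position 2, and mTP probability is 0.5 for class-2 proteins versus
  0.02 elsewhere. These are the conditions the planted-parameter tests
  measure against.
* **Exhaustive truth**: guard bands of non-target residues (width
  `window − 1`) surround every planted region, and any background
  stretch on which the detectors would fire is redrawn (rejection at the
  protein level, using the detectors themselves as the validator). This
  makes precision = recall = 1 an exact property, not a statistical one.
  The redraw conditions the background distribution slightly — the
  alanine frequency of a generated proteome sits a fraction of a
  standard error below nominal — which the sampling tests account for.
* **Impure plantability**: at most `window − windowMinCount` impurities
  per region and no internal target run reaching `minPureLen`. Under
  these constraints every in-region window qualifies, so exact recovery
  by the window-union search is provable, and the pure and impure truth
  sets stay disjoint.
* **Annotation coupling**: peptide calls are class-conditional
  multinomials; location labels are drawn from a prior, optionally
  re-weighted by a normal density at the protein's repeat relative
  position to plant a location/position effect for the stratification
  tests.
* **Propensity fixture**: every biased row is the convex mixture
  `bias * concentrated + (1 − bias) * uniform` (all-A tripeptides toward
  `aaa`, G/P-containing tripeptides toward the 25 grouped `others`
  classes, two-A tripeptides at half strength), so both biases at zero
  give the exactly uniform table, which is a fixed point of the context
  averaging — another tested identity.

What the generator does **not** emulate: real amino-acid composition
(unless a background vector is supplied), domain structure, length
biases of repeat-hosting proteins, evolutionary divergence, or
correlated repeats within one protein. Passing the planted-parameter
tests therefore demonstrates correctness of the statistical machinery,
not biological conclusions about any real proteome — those require
running the pipeline on real FASTA input.

## Numerical choices and problem sizes

* Frequencies sum to 1 within 1e-9 (validity-checked on every container);
  propensity rows are renormalised after a 1e-6 load check.
* The detection-equivalence property is exercised on 10,000 random
  sequences (length ≤ 200, alanine frequency swept 0.05–0.5) in the test
  suite and 3,000 in the quick-report script; planted-parameter
  recoveries run at 1000 proteins; Mann-Whitney calibration uses 1000
  exact pairs and 1000 null repeats. These sizes keep the default test
  run fast while leaving binomial error bars far smaller than the
  effects being recovered.
* Ties in `mostNTerminalRegion` (pure run at the head of an impure
  region) prefer the longer region; group summaries use type-7 quantiles
  (R's default).

## A worked example

```{r example}
sp <- syntheticSpec(nProteins = 200,
                    planPure = data.frame(length = c(4, 6),
                                          count = c(30, 20)),
                    planImpure = data.frame(length = c(5, 7),
                                            nImpurities = c(1, 2),
                                            count = c(40, 30)),
                    seed = 7)
g <- generateProteome(sp)
pure <- detectPure(g$proteome)
impure <- detectImpure(g$proteome)
summarizeCounts(c(pure, impure))

bc <- backgroundComposition(g$proteome)
st <- impurityFrequencies(impure, bc)
st[st$class == "All" & st$letter == "P", ]

en <- positionalEnrichment(positionalComposition(c(pure, impure),
                                                 g$proteome), bc)
round(markerSummary(en), 2)
```

## Limitations

* The impure-search reading of the window rule is one of several
  defensible interpretations; the flags (`window`, `windowMinCount`,
  `requireImpurity`) exist precisely so the alternatives can be explored
  against real counts.
* The propensity module shares only the *shape* of the tripeptide
  predictor it emulates; its numbers depend entirely on the supplied
  table.
* Emergence thresholds are heuristics over a pairwise gap fraction; they
  ignore alignment quality and ortholog choice, which dominate real
  analyses.
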