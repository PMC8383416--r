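---
title: "Methods: chromatin accessibility of circular DNA from m6A footprints"
author: "circaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility of circular DNA from m6A footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `circaccess`, and states explicitly which design
questions were open and how they were decided.

## The assay being modelled

A non-specific adenine methyltransferase deposits m6A on accessible,
protein-free DNA in intact nuclei; nucleosome-bound DNA is protected.
Exonuclease digestion then enriches circular molecules (ecDNA), and
nanopore sequencing reads the intact molecules, yielding per-read, per-base
m6A probabilities from a modified-base caller together with split
alignments. The package consumes those two tables (plus the genome and a
gene annotation) — basecalling and alignment themselves are out of scope,
as are assembly of full-length circles and comparisons against external
ATAC/DNase data.

All coordinates are 0-based half-open throughout, including emitted
BED/bedGraph.

## ecDNA calling

A junction-spanning read maps as two segments that must satisfy four
criteria: each longer than `min_seg_len` (default 1000 bp, *strict*
inequality); same chromosome; same strand; outward orientation. Outward
orientation needed a coordinate-level definition, which this package fixes
as: ordering the two segments by their position on the read, the later
segment's reference interval lies entirely upstream (`+` strand) or
entirely downstream (`-` strand) of the earlier one's — the geometry of a
read running off the circle's reference end and re-entering at its start.
A property test checks this definition against an independent oracle that
literally simulates a read walking around a circular template over a grid
of >500 two-segment configurations.

Decisions taken where the procedure was underdetermined:

* **One candidate per read.** A read is one molecule; when several
  consecutive segment pairs qualify, the pair with the largest combined
  read-segment length wins (ties: smaller `circle_start`).
* **Read-overlap slack.** Supplementary alignments are often trimmed
  imperfectly; segment pairs may overlap on the read by up to 100 bp
  (configurable) and still count.
* **Size filter.** Default catalog range 50 bp – 100 kb, both ends
  configurable: reported circle catalogs and assembled circle lengths
  suggest different upper bounds, so neither is hard-coded.
* **Clustering.** No published clustering rule exists for per-read
  candidates; we use single linkage with both breakpoints within 50 bp
  (typical long-read breakpoint wobble) and report the lower median of
  member breakpoints, which is robust and deterministic under ties.

## Circular references and liftover

Methylation calls near the junction are lost when junction-spanning reads
are forced onto the linear genome, so each circle gets its own reference:
`N^pad + rotate(genome[start:end], rotation) + N^pad`, where `rotate`
moves the first `rotation` bases to the end. The default rotation
`floor(size/2)` centers the junction so windowed scores have full context
on both sides. The pad keeps long reads mappable beyond the core; the
default is 10 kb — descriptions of this trick in the literature are
ambiguous about the pad length, so it is a plain parameter. Liftover to and
from the genome is exact on every core base and `NA` on pads; a property
test checks the round trip on 1000 randomized (size, rotation, pad)
triples, and another checks that a track computed in circle coordinates
and lifted back equals the track computed directly in genome coordinates
for reads that do not span the junction.

`junction_distance()` reports the signed circular distance to the junction
in `(-size/2, size/2]`, positive downstream; the antipode is `+size/2` by
convention.

## The m6A probability mixture

Modified-base callers assign most adenosines probabilities well above
zero, so thresholding at 0.5 is wrong; the raw probability distribution of
a treated sample is bimodal with a noise peak matching the untreated
control. We fit a two-component Gaussian mixture to the *untransformed*
probabilities on [0, 1] — Gaussian by fidelity to how this distribution is
usually modelled, accepting boundary leakage rather than truncating the
densities. EM details:

* deterministic initialization — means at the 25th/75th percentiles, equal
  weights, both SDs at half the inter-quartile spread — so fits are
  reproducible without a seed;
* convergence when the log-likelihood improves by less than `1e-6`
  (default, max 500 iterations); the EM monotonicity of the
  log-likelihood is asserted every iteration;
* SDs floored at `1e-4`; fits with means closer than 0.02 or a component
  weight below 0.01 are flagged degenerate and produce no cutoff;
* components are relabeled so means ascend (noise first).

**Cutoff rule.** How a fixed published cutoff (0.53) was derived from such
a fit is not stated anywhere we could follow, so the package defines the
rule and labels it: the cutoff is the *posterior crossover*, the smallest
probability between the two means at which the signal component's weighted
density reaches the noise component's, found on a 4097-point grid and
refined by `uniroot` far below the `1e-4` documented precision. A
closed-form check (the crossover solves a quadratic in `x`) is enforced to
`1e-3` in the tests. The fixed constant remains available everywhere as a
bypass (`cutoff = 0.53`), and binarization is strict: a probability exactly
at the cutoff is unmethylated.

**Sensitivity/specificity.** Specificity is the fraction of control
(untreated) probabilities below the cutoff. Sensitivity needed a
definition of "true positive": we use the values the fitted model itself
assigns to the signal component (posterior > 0.5); the simulation-based
acceptance script additionally measures sensitivity against the
generator's truth labels, which is only possible with synthetic data.

## Accessibility profiles

The bulk score of a bin is the pooled methylation ratio — methylated
adenosine calls over total adenosine calls from *all* covered reads in the
bin — never a mean of per-read ratios. Bins are 50 bp sliding by 5 bp,
tiled from coordinate 0 (the sizes are standard; the phase had to be fixed
here). Bins with no covered adenosine carry `NaN` and are omitted from
bedGraph.

Metagene profiles sample the track on a 5 bp offset grid over TSS/TES
± 500 bp, flipping minus-strand genes so negative offsets are always
transcription-upstream; the value at an offset is the unweighted mean of
per-gene ratios (genes with no coverage there excluded), and the pooled
counts per offset are also returned so callers can attach exact binomial
errors. Depth normalization across sources (e.g. an ecDNA pool vs the
linear pool) divides each source's counts by its mean covered-bin depth —
the published figures state that depth was normalized without giving a
formula, so this concrete choice is ours; it makes profiles invariant to
duplicating every read of a source, which the tests assert.

Expression strata follow descending expression rank with boundaries at
`ceiling(n * 0.25)` and `ceiling(n * 0.75)` (high / medium / low); tied
expression values all take the better stratum.

**Peak localisation.** Profiles over nucleosome-depleted regions saturate,
so the literal argmax of a plateau is decided by sampling noise;
`profile_peak_position()` therefore reports the center of the maximal
plateau (mean offset of values within 0.1% of the maximum), which reduces
to the argmax for sharp peaks. Similarly `locate_track_minima()` smooths
the track (100 bp running mean by default) before extracting local minima
and collapses tied runs to their midpoint — nucleosome footprints are
~147 bp flat-bottomed wells at typical depths.

**Single-molecule states.** The posterior that a window of one read is
open treats positions as independent and compares the product of signal
component densities against the product of noise densities under a
configurable prior (default 0.5). The idea of Bayesian aggregation over
windows of arbitrary size is established; the concrete likelihood-ratio
rule is this package's contract. A window is `open` iff the posterior
exceeds 0.5 (exactly 0.5 — possible in perfectly symmetric cases — is
`closed`), and `no_call` below `min_A = 2` covered adenosines. The
posterior is monotone in every per-base probability, which is tested.

## Co-accessibility

For windows *i*, *j* and molecule *k* with accessibility scores `A`, the
per-molecule term is `1 - |Ai - Aj| / (Ai + Aj)`; COA(i, j) is the mean
over the ≥ `N` molecules with defined states in both windows. With binary
states the formula is undefined at `Ai = Aj = 0`; we define that case as 1
(agreement), the only convention under which COA(i, i) = 1 holds for
closed windows — COA then reduces to the fraction of spanning molecules
whose two states agree, and the tests cross-check the matrix against both
this closed form and an exhaustive recomputation. Whether published COA
used strictly binary or aggregated scores is unclear, so a continuous mode
(posteriors in place of states) is provided; binary is the default.
Defaults `w = 200` bp (about the resolution of accessible-region calls)
and `N = 5` are exposed, since neither value is published. Pairs are
restricted to one reference (chromosome or circle).

`coa_summary_by_distance()` averages defined entries per window
separation; the background is the mean COA at the largest available
separation, and the reported correlation range is the largest separation
still above that background.

## The synthetic-data generator

The generator emulates the study conditions at desk scale: one 100 kb
uniform-ACGT chromosome at 30× depth with 5–50 kb reads (scaled from
10–100 kb), ten non-overlapping genes with log-normal expression, an
alternating 147/50 bp nucleosome/linker array with 300 bp
nucleosome-depleted regions at TSSs, five single-locus excision circles of
3–10 kb, a noise probability peak `N(0.49, 0.05^2)` (the observed
background peak location) and a signal peak `N(0.85, 0.08^2)` (a free
choice: well-separated but realistically overlapping), both clamped to
[0, 1]. Junction-crossing circle reads emit two same-strand outward
segments; every adenosine of the read's template strand gets a probability
drawn from the open or closed distribution according to the truth mask.
Optional knobs: minus-strand signal offset (strand-asymmetric
accessibility), breakpoint jitter (alignment wobble, exercised at ±5 bp
against the 50 bp clustering tolerance), and moment-matched Beta draws in
place of Gaussians for mis-specification checks.

**Circle sampling.** Two modes exist because two published observations
cannot coexist at desk scale: circular molecules are a ~0.9% share of
reads *after* enrichment of a 3 Gb genome, yet each circle must be deeply
covered for its chromatin to be measurable. The default
(`ecdna_sampling = "coverage"`) sequences every circle to the same target
depth as the genome — the situation the enrichment step is designed to
produce — while `"fraction"` draws each read from a circle with
probability 0.009, reproducing the published read split directly (the
read-split property tests and the acceptance script's read-share quantity
use this mode). On a 100 kb test genome the fraction mode yields under one
circular read per circle, which is faithful to the arithmetic but useless
for recovery testing; this is a scale effect, not a property of the
method.

What the generator does *not* model — and hence what passing tests do not
show about real data: sequencing and basecalling errors, alignment noise
beyond breakpoint jitter, caller-specific probability distributions
(real Megalodon-style outputs are neither Gaussian nor homoscedastic),
multi-fragment circles, copy-number structure, and the biological coupling
between methylation density and exonuclease survival.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default 100 kb / 30× conditions (about 10^6 mod calls, ~260 reads), which
completes in seconds; mixture recovery uses 20 replicates of 10^5 draws.
All randomness flows from a single integer seed: the generator derives
fixed offsets from it per stage, EM initialization is deterministic, and
pipeline manifests (parameters, per-stage counts, md5 checksums, no
timestamps) are byte-identical across reruns of the same configuration.

## Known limitations

* Single-locus excision circles only; no translocation-derived or
  multi-fragment circle reconstruction.
* The Gaussian mixture is fitted untruncated on [0, 1]; heavy clamping
  (extreme component means) biases the fitted parameters slightly.
* The window-posterior independence assumption ignores the spatial
  correlation of methylation within a footprint; posteriors are therefore
  overconfident for large windows.
* `cutoff = "fit"` in the pipeline requires a control table even though
  the mixture is fitted to the treated sample alone — the control anchors
  the specificity evaluation that justifies trusting the fit.
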