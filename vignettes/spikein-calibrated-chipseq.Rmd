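---
title: "Spike-in calibrated ChIP-seq and centromeric occupancy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated ChIP-seq and centromeric occupancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikechip)
```

## The measurement problem

ChIP-seq read counts are compositional: a library of a fixed size is
distributed over bins, so a genome-wide change in occupancy — a histone
being globally gained or lost — is invisible in within-sample ratios.
Spike-in calibration (ChIP-Rx) solves this by mixing a fixed number of
cells from a second species into every sample *before* lysis. Reads mapping
to the exogenous genome provide an internal yardstick that is, by design,
constant across samples, making absolute occupancy changes between
conditions measurable. That is exactly the situation for histone H3 at
fission-yeast centromeres: the INO80 remodeler evicts H3 so that the
CENP-A variant can occupy the central core, and a remodeler mutant gains H3
broadly at the genes the complex binds — a shift a conventional
within-sample normalization would flatten away.

## Calibration model

Let the four read totals of one experiment be the counts mapped to the
experimental and spike-in genomes in the IP and input libraries. The
calibrated IP/input ratio is

$$E^{IP} = \frac{IP_{exp}/input_{exp}}{IP_{spike}/input_{spike}},$$

and the factor that makes raw per-bin count ratios quantitative solves
$N \times IP/input = E^{IP}$ for an IP-vs-input track, or
$N \times IP_{mut}/IP_{wt} = E^{IP}_{mut}/E^{IP}_{wt}$ for a direct
mutant-vs-wild-type IP comparison. `compute_eip()` evaluates the ratio as a
single quotient of two integer cross-products,
$(IP_{exp} \cdot input_{spike}) / (input_{exp} \cdot IP_{spike})$, which is
algebraically identical but numerically better behaved: uniform rescaling
of the IP (or the input) library multiplies both operands of one product by
the same integer, so depth invariance holds bit-exactly for counts below
$2^{53}$. Zero denominators raise errors rather than being pseudocounted —
a calibration with no spike-in signal is meaningless, and silently flooring
counts would bias exactly the samples where the design failed.

Note one algebraic consequence worth spelling out: because
$N = E^{IP} \cdot input_{exp} / IP_{exp}$ and $E^{IP} \propto
1/input_{exp}$, changing only the input depth moves $E^{IP}$ but leaves
$N$ unchanged — the two effects cancel. $N$ responds to the *relative
recovery* of the two genomes in the IP, not to library sizes.

## SES scaling without a spike-in

Targets confined to small domains (CENP-A, remodeler subunits) are
normalized by signal extraction scaling instead. The method is named but
not operationally pinned down in common usage, so this package fixes one
concrete definition: sort bins in ascending order of IP signal; compute the
gap between the cumulative input fraction and the cumulative IP fraction
along that ordering; cut at the *first* index attaining the maximal gap
(ties broken toward the smallest index — the most conservative background);
call everything up to the cut background; and return

$$s = \frac{IP_{bg}/IP_{tot}}{input_{bg}/input_{tot}}.$$

The scale applies multiplicatively to the depth-normalized input track, so
the background's average IP/input ratio becomes 1 and only genuine
enrichment rises above it. Whether to rescale the IP or the input is a free
choice (the two differ only by a global inversion); input was chosen so
that enrichment values stay interpretable as "fold over background".
`ses_scale()` is verified against a brute-force scan over every possible
cut point.

## Tracks, ratios, and region statistics

Coverage lives on a fixed-width bin grid (`binned_track`), 50 bp by
default — fine enough to resolve the 4--10 kb centromeric domains and gene
bodies of a yeast-sized genome while keeping per-bin counts in a stable
range at desk-scale depths; the last partial bin covers to the chromosome
end. All intervals are 0-based half-open (BED convention) everywhere, and
bedGraph is the canonical on-disk format: text, diffable, round-trippable
to 1e-9 without compiled dependencies.

Ratio tracks are plain per-bin quotients $(N \cdot IP + p)/(input + p)$.
The pseudocount $p$ defaults to 1 read for browser-style tracks (where
empty input bins are expected and a hard failure would be hostile) and to 0
for region statistics, where a zero denominator indicates a real problem
and raises an error naming the offending bins. Linear scale is canonical;
log2 is a display flag. Region fold enrichment sums counts with
fractional-overlap weights for bins straddling interval edges — the
qPCR amplicons this statistic mimics have no bin structure, so the
piecewise-constant integral is the natural discretization-free choice.

## Metagene geometry

Each gene contributes one row: fixed-width flank columns (one track bin
wide) from 0.5 kb upstream of the TSS, the body rescaled to 100 equal-length
columns by length-weighted averaging, and 0.5 kb downstream of the TES.
Minus-strand genes are read along the direction of transcription, so column
1 is always the 5′ edge. Columns extending past a chromosome end are
missing (`NA`) and excluded from means rather than filled with zeros, which
would fabricate depletion at chromosome-edge genes. Genes shorter than one
track bin are interpolated by the same fractional-overlap rule and flagged.
The per-gene summary score — used for heatmap ordering and high/low
classification — is the mean over body columns; body mean was chosen over
TSS-proximal alternatives because the occupancy contrasts of interest
(remodeler binding, H3 gain) are body-wide, and it makes the summary
identical in expectation to the region-level statistic on the gene body.

Heatmap ordering is a stable descending sort of that summary with
lexicographic gene-id tie-breaks, so orderings are reproducible across runs
and platforms.

## Exact two-means and the overlap test

For one-dimensional scores the k-means (k = 2) optimum is a threshold in
sorted order, so `kmeans_high_low()` scans all $n-1$ cuts and returns the
global minimum of within-cluster sum of squares — no initialization, no
seed sensitivity, verified against exhaustive enumeration of all $2^n$
labelings at small $n$. Identical scores for all genes are a degenerate
input and an error, not a silent single cluster.

Overlap of two "high" sets in a common gene universe is scored with the
upper-tail hypergeometric probability $P(X \ge k)$ (over-enrichment; an
overlap of 0 gives exactly p = 1), via `stats::phyper`, which computes in
log space; tests check it against explicit enumeration of draws in small
universes.

## The loss-rate estimator

Marker retention decays geometrically at per-division loss probability $p$:
after $N$ divisions a fraction $(1-p)^N$ of lineages retain the
minichromosome. Inverting gives the estimator
$100 \times (1 - (F/I)^{1/N})$ from initial and final retention
percentages. $F = 0$ leaves the formula undefined; it is reported as 100%
per division with a `complete_loss` flag rather than `NaN`, and $F > I$
(possible under scoring noise) yields a negative rate with a `gain` flag
and a warning. Rates are computed per colony and aggregated as mean ±
sample s.d. ($n-1$ denominator) across independent colonies — pooling
counts before estimating would weight colonies by cells scored and hide
between-colony variance, which is the quantity the s.d. is meant to show.
The number of generations is a per-experiment input (assays typically allow
10--12 divisions; simulations default to 11).

## What the synthetic generator emulates — and what it does not

`simulate_chip()` draws reads multinomially over the concatenated bins of
two genomes. Input reads follow a condition-independent per-bin density
with the spike genome down-weighted by the cell-mixing ratio (default 1:8);
IP reads follow the pulled-down target's occupancy times a per-target
capture efficiency. Keeping the input density fixed across conditions
encodes the physical fact that sonicated whole-chromatin DNA tracks genome
content, not any single protein's occupancy; it is also what makes the
calibrated mutant/wild-type estimator exactly unbiased in expectation, an
identity the tests exploit. An expectation mode bypasses sampling entirely
and returns exact expected counts, so closed-form identities (the 1/9
spike fraction at 1:8 mixing with matched chromatin content, exact
fold-change recovery) are testable to machine precision. Seeds are
mandatory for sampled runs; unseeded stochastic calls are refused.

The generator deliberately omits fragment lengths, GC and mappability
biases, PCR duplicates, and sequence-level read simulation — the analysis
operates on per-bin counts, and those effects would only matter to an
aligner upstream of this package's scope. The bundled demonstration genome
(`example_model()`) is one 660 kb chromosome with an
otr--imr--cnt--imr--otr centromere and 200 uniform 2 kb genes, 60 of them
remodeler-bound, plus a 40 kb uniform spike genome; real genomes have
variable gene lengths, copy-number structure and unmappable repeats, so
passing tests demonstrate the correctness of the estimators under the
stated sampling model, not robustness to alignment artefacts.

Default problem sizes — $10^6$ reads per library, 13,200 bins, 200 genes,
1,000-colony Monte-Carlo checks — were chosen as the smallest sizes at
which sampling error is comfortably below the effect sizes being recovered
(per-bin means near 80 reads put single-bin ratio noise around 15% and
bin-set means well under 2%).

## Numerical choices and limitations

* Bin width (50 bp), body columns (100), flank extent (0.5 kb) are
  conventions, configurable everywhere; results at other settings differ by
  resolution, not substance.
* SES ties break toward the smallest cut; two-means ties in the objective
  break toward the first cut in sorted order; heatmap ties break by gene
  id. All three rules exist to make outputs deterministic.
* The pipeline (`run_pipeline()`) writes only plain-text outputs and a
  manifest of MD5 checksums; identical config + seed reproduces identical
  checksums, which is the determinism contract the tests assert.
* Replicate aggregation is mean ± s.d. only; no shrinkage, no per-bin
  variance model. The analysis reports plain calibrated ratios by design,
  and confidence machinery beyond the replicate s.d. is out of scope.
* The loss-rate estimator assumes a constant per-division loss probability
  and no selection against minichromosome-free cells during the
  non-selective growth; fluctuation-style estimators are not implemented.
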