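# spikechip

Quantitative analysis of spike-in calibrated ChIP-seq, built around the
biology of chromatin-remodeler-driven histone H3 eviction at fission-yeast
regional centromeres. The package is for epigenomics analysts who need the
calibration arithmetic of ChIP-Rx experiments (exogenous-genome spike-in),
background scaling when no spike-in exists, normalized fold-change tracks,
scaled-region metagene profiling with gene-set overlap statistics, and the
classical minichromosome loss-rate estimator — all testable end-to-end on a
built-in dual-genome synthetic data generator, so no sequencing data are
required to validate any stage.

## The statistics at its core

**Spike-in calibration.** A fixed ratio of cells from a second species
(e.g. *S. cerevisiae* into *S. pombe* at 1:8) is mixed into every sample
before lysis. With read totals split by genome, the calibrated IP/input
ratio is

    E^IP = (IP_exp / input_exp) / (IP_spike / input_spike)

The scaling factor *N* that makes a raw read-count ratio quantitative solves

    N x IP / input           = E^IP          (IP vs input)
    N x IP_mut / IP_wt       = E_mut / E_wt  (mutant vs wild type)

**SES background scaling.** For targets without spike-in (e.g. CENP-A),
bins are sorted in ascending order of IP signal; the cut maximizing the gap
between cumulative input and IP fractions defines the background, and the
scale is the background IP fraction over the background input fraction
(signal extraction scaling).

**Region fold enrichment** (qPCR-style): `(IP_t/IP_c) / (input_t/input_c)`
for a target region (the centromeric central core, *cnt*) against a
euchromatic control locus.

**Metagene profiling**: genes x scaled-position matrices from −0.5 kb of
the TSS to +0.5 kb of the TES, descending-enrichment heatmap ordering,
exact two-means (k = 2) high/low classification, and upper-tail
hypergeometric tests for the overlap of high sets.

**Minichromosome loss rate** per division from marker retention:
`100 x (1 − (F/I)^(1/N))` over *N* generations, averaged over independent
colonies (mean ± s.d.).

## Worked example

```r
library(spikechip)

counts <- spike_in_counts(ip_exp = 800, input_exp = 400,
                          ip_spike = 100, input_spike = 200)
compute_eip(counts)
#> [1] 4
n_factor_ip_vs_input(counts)
#> <normalization_result> mode = ip_vs_input, E^IP = 4, N = 2

# end-to-end synthetic run: wild type vs a remodeler mutant whose bound
# genes gain histone H3 1.5-fold, with a 1:8 spike-in
res <- run_pipeline(list(seed = 7), out_dir = "demo_out")
round(res$fold_change_bound, 3)    # calibrated H3 change on bound genes
#> [1] 1.516
round(res$fold_change_unbound, 3)  # elsewhere: no change
#> [1] 1.014
res$region_enrichment              # CENP-A at the central core vs control
#> <region_enrichment> fold enrichment = 10.31
res$overlap                        # high-enrichment vs high-H3-gain genes
#> <gene_set_overlap> 60 / 60 vs 60 in universe 200 (expected 18.00), p = 1.42e-52
res$loss$mutant                    # simulated loss assay, 2% per division
#> <loss_rate_result> 2.052% +/- 0.1455% per division (n = 3 colonies)
```

The raw E^IP of 4 says the IP recovered experimental-genome chromatin four
times better than input once both are calibrated against the spike-in; the
factor N = 2 rescales the raw IP/input ratio (2) to that value. In the
pipeline run, the programmed 1.5-fold H3 gain at remodeler-bound genes is
recovered on their bins while unbound bins stay at 1; the ten-fold CENP-A
occupancy contrast programmed into the central core is returned by the
region statistic; the 60 genes classified "high" for remodeler binding and
for H3 gain are the same set, which the hypergeometric test scores as far
beyond chance; and the loss-rate estimator inverts the simulated 2\%
per-division loss. Outputs (bedGraph tracks, TSV tables, a checksummed
manifest) land in `demo_out/`.

A thin command-line wrapper with `run`, `simulate`, `normalize`,
`lossrate` and `overlap` subcommands is installed at
`inst/cli/spikechip`.

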