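# Demonstration pipeline configuration: a reduced-depth run of the full
# synthetic analysis (see ?run_pipeline and ?default_config for the fields).
seed: 7
bin_width: 50
n_genes: 200
n_bound: 60
h3_fold: 1.5
mix_ratio: 0.125
total_ip_reads: 200000
total_input_reads: 200000
pseudocount: 1
upstream: 500
downstream: 500
body_bins: 100
loss:
  strains:
    wt: 0.002
    mutant: 0.02
  generations: 11
  colonies: 3
  n_cells: 2000
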