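# Example breakscan pipeline configuration.
# Run: Rscript inst/scripts/breakscan.R run --config example_config.yaml --outdir out
seed: 11
simulate:
  n_genes: 800
  n_induced: 80
  excess_delta: 1.5
stats:
  n_perm: 1000
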