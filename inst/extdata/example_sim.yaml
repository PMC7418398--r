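# example configuration for `pqtlpipe simulate --config ... --out dir/`
# keys override sim_config() defaults
n_samples: 100
n_variants: 500
n_proteins: 50
maf_range: [0.1, 0.5]
ld_block_size: 20
ld_decay: 0.6
noise_sd: 0.5
shared_peptide_fraction: 0.3
missing_protein_rate: 0.02
seed: 42
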