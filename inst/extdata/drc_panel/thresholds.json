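{
  "min_allele_depth": 20,
  "min_base_phred": 30,
  "het_low": 0.2,
  "het_high": 0.8,
  "consensus_min_depth": 20,
  "max_uncalled_fraction": 0.9,
  "barcode_max_mismatch": 1,
  "primer_max_mismatch": 2,
  "species_identity_threshold": 0.97,
  "trim_window": 4,
  "trim_min_mean_q": 20,
  "trim_min_length": 50,
  "band": 16
}
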