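# End-to-end pipeline example: simulate a mixed common+rare architecture and
# render the trumpet plot with default GWAS thresholds.
out_dir: trumpet_out
method: clump
orientation: minor_allele_signed
alpha: 5.0e-8
r2_threshold: 0.1
window_kb: 100
maf_min: 0.01
power_levels: [0.5, 0.7, 0.9]
f_min: 1.0e-5
min_effect: 0
min_effect_interactive: 0.05
simulate:
  n_gwas: 351550
  m_common: 1000
  m_rare: 250
  causal_fraction: 0.3
  tau: 0.02
  gamma: 0.5
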