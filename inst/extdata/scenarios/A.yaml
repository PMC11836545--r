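# Scenario A: deeper nerve sampling, some blood-nerve HEC sharing,
# paired-end reads, cross-subject contamination present.
seed: 20250218
n_blood_clones: 4000
n_nerve_clones: 400
n_nerve_restricted_hecs: 12
n_shared_hecs: 4
blood_freq_shape: 2.0
nerve_depth_reads: 20000
blood_depth_reads: 30000
seq_error_rate: 0.001
paired_end: true
read_length: 90
contamination_rate: 0.0005
n_public_clones: 3
hec_freq_min: 0.012
hec_freq_max: 0.018
freq_model: power_law
cdr3_len_min: 9
cdr3_len_max: 18
restricted_cdr3_len_min: 16
low_clone_freq: 0.002
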