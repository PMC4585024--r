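# Shared configuration for the numbered analysis drivers. Every script
# re-derives earlier stages deterministically from this file, so stages can
# be run independently and reproduce byte-identical intermediates.
seed: 1
genomes:
  n_genomes: 60
  min_len: 3000
  max_len: 30000
simulation:
  # scaled-down depth series in the 1:10:100 ratio of the three MiSeq
  # throughput scenarios (0.05M / 0.5M / 5M reads)
  depths: [500, 5000, 50000]
  read_len: 300
  insert_mean: 500
  insert_sd: 50
  error_rate: 0.001
  qc_loss: 0.015
  abundance:
    model: power_law
    alpha: 1
degradation:
  split_rate: [0.2, 0.5, 0.8]
  loss_rate: [0.05, 0.25]
  chimera_rate: 0.05
  replicates: 5
metrics:
  chimera_threshold: 0.9
  fragments: contigs_and_unassembled
  weighting: reads
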