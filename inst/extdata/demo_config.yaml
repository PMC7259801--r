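# demo pipeline configuration: simulate every stage from the seed
seed: 1
stages: [transcripts, gel, nuclei, trace]
sim:
  n_replicates: 8
  noise_sigma: 0.15
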