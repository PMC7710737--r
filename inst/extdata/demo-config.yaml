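# End-to-end demo: simulate a 19-kb transcript with planted architecture and
# run every analysis stage. `runPipeline(this_file, outDir)` reproduces all
# outputs byte-for-byte for a fixed seed.
seed: 42

transcript:
  length: 19000
  gc: 0.5
  repeats:
    - {name: Arep, unit_length: 24, copies: 8, at: 301}
    - {name: Drep, unit_length: 290, copies: 4, at: 9001}
  domains:
    - {name: D1, start: 201, end: 700}
    - {name: D2, start: 5001, end: 5500}
    - {name: D3, start: 12001, end: 12500}

samples:
  - {sample_id: P1_rep1, protein: P1, role: IP, domain: D1, fold: 6}
  - {sample_id: P1_rep2, protein: P1, role: IP, domain: D1, fold: 6}
  - {sample_id: P1_rep3, protein: P1, role: IP, domain: D1, fold: 6}
  - {sample_id: P2_rep1, protein: P2, role: IP, domain: D3, fold: 6}
  - {sample_id: P2_rep2, protein: P2, role: IP, domain: D3, fold: 6}
  - {sample_id: P2_rep3, protein: P2, role: IP, domain: D3, fold: 6}
  - {sample_id: input1, protein: none, role: input}
  - {sample_id: input2, protein: none, role: input}

chimera:
  n_pairs: 20000
  chimera_rate: 0.02
  long_threshold: 1000
  link_distance: 500
  min_support: 5
  anchors:
    - {left_start: 1000, left_end: 1200, right_start: 8000, right_end: 8200}
    - {left_start: 3000, left_end: 3200, right_start: 6000, right_end: 6200}
    - {left_start: 13000, left_end: 13200, right_start: 17000, right_end: 17200}

profiles:
  window: 100
  library_size: 50000
  k: 2
  repeat_flank: 10

motif:
  motif: DRACH
  window: 300
  step: 50

dgoverlap:
  n_query: 60
  n_reference: 60
  shared_fraction: 0.5
  n_shuffles: 1000

domains:
  reference: WT
  library_size: 50000
  alleles:
    - {name: WT, folds: [4, 4, 4]}
    - {name: DEL, folds: [1, 4, 4]}
    - {name: KI, folds: [1, 4, 8]}

irclip:
  n_sites: 20
  lambda: 20
  noise_rate: 0.05
  extend: 5
  trim: 5
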