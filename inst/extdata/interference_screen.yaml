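# Worst-case interference screen: 10 spiked vs 10 control aliquots per
# substance x pool. True biases (%) below drive the simulation; a flagged
# substance is emitted as a dose-response task.
study_kind: interference_screen
seed: 42
simulate:
  pools: {high: 90, low: 55}
  substances:
    glucose: -23
    caffeine: 0
    ibuprofen: 1
  n_per_arm: 10
  cv: 3
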