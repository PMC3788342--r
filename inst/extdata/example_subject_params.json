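{
  "preference_weights": {"metal": 4, "rope": 1, "wood": 1, "jute": 1},
  "refusal_prob": 0.05,
  "k_distribution": [0.6, 0.25, 0.1, 0.05],
  "exchange_fidelity": 0.9,
  "spurious_offer_prob": 0.1
}
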