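{
  "stimulus": {
    "kind": "rate",
    "label": "k7_13",
    "values": [0.86, 2.96],
    "b": [0.16605, 0.16605]
  },
  "Q": {
    "P1": {
      "P1": 1
    },
    "G2P1": {
      "G2P1": 1
    },
    "P2": {
      "P2": 1
    }
  },
  "fixed_k": {
    "k1_8": 100
  }
}
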