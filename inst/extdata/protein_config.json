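{
  "stimulus": {
    "kind": "conservation",
    "index": 1,
    "values": [0.007079, 0.010973]
  },
  "Q": {
    "S": {
      "S": 1
    },
    "ESS": {
      "ESS": 1
    },
    "P": {
      "P": 1
    }
  },
  "fixed_k": {
    "k1_4": 1,
    "k3_7": 0.01
  }
}
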