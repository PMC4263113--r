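{
  "species": ["G1", "G2", "P1", "P2", "G2P1", "G2P1P1", "G1P2"],
  "complexes": [
    {
      "G1": 1
    },
    {
      "P1": 1
    },
    {
      "G2": 1
    },
    {
      "G2": 1,
      "P1": 1
    },
    {
      "P1": 1,
      "G2P1": 1
    },
    {
      "G1": 1,
      "P2": 1
    },
    {
      "P2": 1
    },
    {
      "G1": 1,
      "P1": 1
    },
    {
      "G2P1": 1
    },
    {
      "G2": 1,
      "P2": 1
    },
    {
      "G2P1P1": 1
    },
    {
      "G1P2": 1
    },
    {}
  ],
  "reactions": [
    {
      "from": 1,
      "to": 8,
      "k": "k1_8"
    },
    {
      "from": 3,
      "to": 10,
      "k": "k3_10"
    },
    {
      "from": 4,
      "to": 9,
      "k": "k4_9"
    },
    {
      "from": 9,
      "to": 4,
      "k": "k9_4"
    },
    {
      "from": 5,
      "to": 11,
      "k": "k5_11"
    },
    {
      "from": 11,
      "to": 5,
      "k": "k11_5"
    },
    {
      "from": 6,
      "to": 12,
      "k": "k6_12"
    },
    {
      "from": 12,
      "to": 6,
      "k": "k12_6"
    },
    {
      "from": 2,
      "to": 13,
      "k": "k2_13"
    },
    {
      "from": 7,
      "to": 13,
      "k": "k7_13"
    }
  ]
}
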