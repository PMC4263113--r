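{
  "species": ["E", "S", "ES", "ESS", "P"],
  "complexes": [
    {
      "E": 1,
      "S": 1
    },
    {
      "S": 1,
      "ES": 1
    },
    {
      "S": 1
    },
    {
      "ES": 1
    },
    {
      "P": 1
    },
    {
      "ESS": 1
    },
    {},
    {
      "E": 1,
      "P": 1
    }
  ],
  "reactions": [
    {
      "from": 1,
      "to": 4,
      "k": "k1_4"
    },
    {
      "from": 4,
      "to": 1,
      "k": "k4_1"
    },
    {
      "from": 1,
      "to": 8,
      "k": "k1_8"
    },
    {
      "from": 2,
      "to": 6,
      "k": "k2_6"
    },
    {
      "from": 6,
      "to": 2,
      "k": "k6_2"
    },
    {
      "from": 3,
      "to": 7,
      "k": "k3_7"
    },
    {
      "from": 7,
      "to": 3,
      "k": "k7_3"
    },
    {
      "from": 5,
      "to": 7,
      "k": "k5_7"
    }
  ]
}
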