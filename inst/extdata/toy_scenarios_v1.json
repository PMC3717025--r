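{
  "version": 1,
  "scenarios": [
    {
      "kind": "two_point",
      "strategies": ["A", "B"],
      "states": ["state1", "state2"],
      "nb": [
        [0, 10],
        [0, -10]
      ],
      "weights": [0.5, 0.5],
      "evpi": 5
    },
    {
      "kind": "dominated",
      "strategies": ["A", "B"],
      "states": ["state1", "state2"],
      "nb": [
        [0, 5],
        [2, 7]
      ],
      "weights": [0.5, 0.5],
      "evpi": 0
    },
    {
      "kind": "single_state",
      "strategies": ["A", "B"],
      "states": "state1",
      "nb": [
        [1, 4]
      ],
      "weights": 1,
      "evpi": 0
    }
  ]
}
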