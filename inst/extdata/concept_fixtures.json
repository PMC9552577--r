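[
  {
    "name": "blanket",
    "basis": {"labels": ["warm", "soft", "rectangular", "colorful", "bed"]},
    "amplitudes": [[0.62, 0], [0.58, 0], [0.38, 0], [0.25, 0], [0.27, 0]],
    "observations": ["warm", "soft", "rectangular", "colorful"]
  },
  {
    "name": "island",
    "basis": {"labels": ["land", "water", "shoreline", "tropical", "vacation", "finland"]},
    "amplitudes": [[0.72, 0], [0.67, 0], [0.12, 0], [0.09, 0], [0.07, 0], [0.05, 0]],
    "observations": ["land", "water", "shoreline"]
  },
  {
    "name": "dog",
    "basis": {"labels": ["furry", "tail", "loyal", "bark", "rollover", "hunt", "smell"]},
    "amplitudes": [[0.45, 0], [0.40, 0], [0.35, 0], [0.40, 0], [0.20, 0], [0.35, 0], [0.40, 0]],
    "observations": ["furry", "tail", "bark", "rollover", "hunt", "smell"]
  },
  {
    "name": "bird",
    "basis": {"labels": ["sparrow", "robin", "penguin", "animal", "feathers", "nests", "tree"]},
    "amplitudes": [[0.60, 0], [0.50, 0], [0.20, 0], [0.30, 0], [0.40, 0], [0.25, 0], [0.15, 0]],
    "observations": ["sparrow", "robin", "penguin", "feathers", "tree"]
  }
]
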