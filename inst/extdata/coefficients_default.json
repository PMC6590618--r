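{
  "k1": {"m": 0.0030698, "b": 1.0096},
  "k2": {"m": 0.0026365, "b": 1.0084},
  "k3": {"m": 0.0025729, "b": 1.0052},
  "k4": {"m": -0.0037566, "b": 0.88691},
  "k5": {"m": -0.00027806, "b": 0.7044},
  "k6": {"m": 0.010117, "b": 0.93777},
  "k7": {"m": 0.0045822, "b": 0.92897},
  "k8": {"m": -0.0018511, "b": 0.79905},
  "k9": {"m": 0.013175, "b": 0.86184},
  "k10": {"m": 0.032808, "b": 0.7165},
  "k11": {"m": 0.015803, "b": 0.79656},
  "k12": {"m": 0.042707, "b": 0.70788},
  "r_range": [5.1, 7.8]
}
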