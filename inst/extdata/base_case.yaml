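probabilities:
  DAPT:
    PCI:
      BLEEDING: 0.0374
      VASCULAR: 0.0361
      DEATH: 0.012
    CABG:
      BLEEDING: 0.0615
      VASCULAR: 0.0693
      DEATH: 0.0197
    MEDICAL:
      BLEEDING: 0.0859
      VASCULAR: 0.0129
      DEATH: 0.0349
  TAPT:
    PCI:
      BLEEDING: 0.0596
      VASCULAR: 0.0557
      DEATH: 0.0115
    CABG:
      BLEEDING: 0.53000000000000003
      VASCULAR: 0.29999999999999999
      DEATH: 0.05
    MEDICAL:
      BLEEDING: 0.12870000000000001
      VASCULAR: 0.0139
      DEATH: 0.0538
life_years:
  NO_EVENT: 14.5
  BLEEDING: 12.30000000000000071
  VASCULAR: 5.20000000000000018
  DEATH: 0.0
utilities:
  PROCEDURAL:
    NO_EVENT: 0.85999999999999999
    BLEEDING: 0.82999999999999996
    VASCULAR: 0.76000000000000001
    DEATH: 0.0
  MEDICAL:
    NO_EVENT: 0.45000000000000001
    BLEEDING: 0.45000000000000001
    VASCULAR: 0.40999999999999998
    DEATH: 0.0
simulation:
  n_trials: 10000
  seed: 42
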