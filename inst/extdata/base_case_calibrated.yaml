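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
mix:
  DAPT:
    PCI: 0.50840726983776074
    CABG: 0.43254360808735803
    MEDICAL: 0.05904912207488119
  TAPT:
    PCI: 0.69495828110058266
    CABG: 0.20456793947435056
    MEDICAL: 0.10047377942506676
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
costs:
  DAPT:
    PCI:
      NO_EVENT:
        family: GAMMA
        mean: 16149.84656162919236522
        sd: 11262.87689595229858242
      BLEEDING:
        family: GAMMA
        mean: 24224.76984244378763833
        sd: 16894.31534392844696413
      VASCULAR:
        family: GAMMA
        mean: 29069.72381093254807638
        sd: 20273.17841271413999493
      DEATH:
        family: GAMMA
        mean: 20994.80053011795098428
        sd: 14641.73996473798979423
    CABG:
      NO_EVENT:
        family: GAMMA
        mean: 26916.41093604865454836
        sd: 18771.46149325383157702
      BLEEDING:
        family: GAMMA
        mean: 40374.61640407298546052
        sd: 28157.19223988075100351
      VASCULAR:
        family: GAMMA
        mean: 48449.53968488757527666
        sd: 33788.63068785689392826
      DEATH:
        family: GAMMA
        mean: 34991.33421686325164046
        sd: 24402.89994122998177772
    MEDICAL:
      NO_EVENT:
        family: GAMMA
        mean: 10766.56437441946218314
        sd: 7508.58459730153299461
      BLEEDING:
        family: GAMMA
        mean: 16149.84656162919236522
        sd: 11262.87689595229858242
      VASCULAR:
        family: GAMMA
        mean: 19379.81587395503083826
        sd: 13515.45227514275939029
      DEATH:
        family: GAMMA
        mean: 13996.53368674530065618
        sd: 9761.15997649199198349
  TAPT:
    PCI:
      NO_EVENT:
        family: GAMMA
        mean: 36772.86435850034467876
        sd: 6923.74198590064588643
      BLEEDING:
        family: GAMMA
        mean: 55159.29653775050974218
        sd: 10385.61297885096792015
      VASCULAR:
        family: GAMMA
        mean: 66191.155845300614601
        sd: 12462.73557462116150418
      DEATH:
        family: GAMMA
        mean: 47804.72366605044953758
        sd: 9000.86458167084128945
    CABG:
      NO_EVENT:
        family: GAMMA
        mean: 61288.10726416723628063
        sd: 11539.56997650107587106
      BLEEDING:
        family: GAMMA
        mean: 91932.16089625084714498
        sd: 17309.35496475161198759
      VASCULAR:
        family: GAMMA
        mean: 110318.59307550101948436
        sd: 20771.2259577019358403
      DEATH:
        family: GAMMA
        mean: 79674.53944341740862001
        sd: 15001.44096945139972377
    MEDICAL:
      NO_EVENT:
        family: GAMMA
        mean: 24515.24290566689523985
        sd: 4615.82799060043089412
      BLEEDING:
        family: GAMMA
        mean: 36772.86435850034467876
        sd: 6923.74198590064588643
      VASCULAR:
        family: GAMMA
        mean: 44127.43723020041215932
        sd: 8308.49038308077615511
      DEATH:
        family: GAMMA
        mean: 31869.81577736696272041
        sd: 6000.57638778055934381
simulation:
  n_trials: 10000
  seed: 42
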