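# SYNTHETIC item key: subscale codes and sizes follow the EDI-3, but the
# item-to-subscale allocation here is invented for testing. Supply your
# own key (same layout) for real scoring. Item 71 is deliberately
# unscored, as in the real questionnaire.
subscales:
  DT: [1, 2, 3, 4, 5, 6, 7]
  B: [8, 9, 10, 11, 12, 13, 14, 15]
  BD: [16, 17, 18, 19, 20, 21, 22, 23, 24, 25]
  LSE: [26, 27, 28, 29, 30, 31]
  PA: [32, 33, 34, 35, 36, 37, 38]
  II: [39, 40, 41, 42, 43, 44, 45]
  IA: [46, 47, 48, 49, 50, 51, 52]
  ID: [53, 54, 55, 56, 57, 58, 59, 60, 61]
  ED: [62, 63, 64, 65, 66, 67, 68, 69]
  P: [70, 72, 73, 74, 75, 76]
  A: [77, 78, 79, 80, 81, 82, 83]
  MF: [84, 85, 86, 87, 88, 89, 90, 91]
composites:
  EatingDisorderRisk: [DT, B, BD]
  Ineffectiveness: [LSE, PA]
  InterpersonalProblems: [II, IA]
  AffectiveProblems: [ID, ED]
  Overcontrol: [P, A]
  GeneralPsychologicalMaladjustment: [LSE, PA, II, IA, ID, ED, P, A, MF]
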