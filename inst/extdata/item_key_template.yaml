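# Template item key. Fill in your questionnaire's item ids per subscale
# code and the subscale membership of each composite score.
subscales:
  DT: []  # drive for thinness
  B: []   # bulimia
  BD: []  # body dissatisfaction
  LSE: [] # low self-esteem
  PA: []  # personal alienation
  II: []  # interpersonal insecurity
  IA: []  # interpersonal alienation
  ID: []  # interoceptive deficits
  ED: []  # emotional dysregulation
  P: []   # perfectionism
  A: []   # asceticism
  MF: []  # maturity fears
composites:
  EatingDisorderRisk: [DT, B, BD]
  Ineffectiveness: [LSE, PA]
  InterpersonalProblems: [II, IA]
  AffectiveProblems: [ID, ED]
  Overcontrol: [P, A]
  GeneralPsychologicalMaladjustment: [LSE, PA, II, IA, ID, ED, P, A, MF]
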