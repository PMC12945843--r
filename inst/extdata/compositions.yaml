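# Reference formulation compositions (component masses in mg).
# F1: spray-dried polymeric solid dispersion (drug:polymer 1:2 w/w, NaOH
#     equimolar to the drug for solubilisation at ~pH 7).
# F2: mesoporous silica system loaded by solvent immersion.
# F3: co-amorphous system, nominally equimolar drug:arginine:phenylalanine
#     (the amino-acid masses correspond to 1.00 mmol each).
drug: Cefdinir
formulations:
  F1:
    label: polymeric solid dispersion
    components:
      Cefdinir: 300.0
      PVP K30: 600.0
      NaOH: 30.35
  F2:
    label: mesoporous silica-based system
    components:
      Cefdinir: 300.0
      SBA-15: 507.2
  F3:
    label: co-amorphous system
    components:
      Cefdinir: 300.0
      L-arginine: 174.20
      L-phenylalanine: 165.19
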