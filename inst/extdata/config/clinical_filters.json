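{
  "treatment": "Therapy/Broad[filter]",
  "diagnosis": "Diagnosis/Broad[filter]",
  "prognosis": "Prognosis/Broad[filter]",
  "etiology": "Etiology/Broad[filter]"
}
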