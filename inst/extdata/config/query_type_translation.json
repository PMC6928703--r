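{
  "concept_names": {
    "antihypertensive agent": "treatment",
    "therapeutic agent": "treatment",
    "pharmacologic substance": "treatment",
    "therapeutic or preventive procedure": "treatment",
    "diagnostic procedure": "diagnosis",
    "laboratory procedure": "diagnosis",
    "imaging procedure": "diagnosis",
    "prognostic factor": "prognosis",
    "risk factor": "etiology",
    "etiologic agent": "etiology"
  },
  "semantic_types": {
    "pharmacologic substance": "treatment",
    "chemical and drugs": "treatment",
    "therapeutic or preventive procedure": "treatment",
    "diagnostic procedure": "diagnosis",
    "laboratory procedure": "diagnosis",
    "sign or symptom": "diagnosis"
  }
}
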