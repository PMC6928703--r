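{
  "semantic_types": {
    "population group": "P",
    "age group": "P",
    "patient or disabled group": "P",
    "disease or syndrome": "P",
    "disorder": "P",
    "finding": "P",
    "sign or symptom": "P",
    "anatomical structure": "P",
    "chemical and drugs": "I",
    "pharmacologic substance": "I",
    "clinical drug": "I",
    "therapeutic or preventive procedure": "I",
    "diagnostic procedure": "I",
    "laboratory procedure": "I",
    "outcome": "O",
    "qualitative concept": "O",
    "clinical attribute": "O"
  },
  "entity_types": {
    "population group": "P",
    "disorder": "P",
    "finding": "P",
    "chemical and drugs": "I",
    "procedure": "I",
    "device": "I",
    "outcome": "O"
  },
  "fallback": "P"
}
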