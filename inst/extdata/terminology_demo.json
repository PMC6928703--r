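[
  {
    "id": "C001",
    "name": "female",
    "synonyms": [],
    "semantic_types": "population group",
    "entity_type": "population group",
    "parents": []
  },
  {
    "id": "C002",
    "name": "blood pressure",
    "synonyms": [],
    "semantic_types": "finding",
    "entity_type": "finding",
    "parents": []
  },
  {
    "id": "C003",
    "name": "beta-blocker",
    "synonyms": "beta blocking agent",
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C005"
  },
  {
    "id": "C004",
    "name": "angiotensin-converting-enzyme inhibitor",
    "synonyms": "ACE inhibitor",
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C005"
  },
  {
    "id": "C005",
    "name": "antihypertensive agent",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": []
  },
  {
    "id": "C006",
    "name": "hypertension",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "C007",
    "name": "therapeutic agent",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": []
  },
  {
    "id": "D001",
    "name": "insulin",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D002",
    "name": "metformin",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D003",
    "name": "albuterol",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D004",
    "name": "aspirin",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D005",
    "name": "simvastatin",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D006",
    "name": "warfarin",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D007",
    "name": "amoxicillin",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D008",
    "name": "fluoxetine",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D009",
    "name": "sumatriptan",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "D010",
    "name": "alendronate",
    "synonyms": [],
    "semantic_types": "pharmacologic substance",
    "entity_type": "chemical and drugs",
    "parents": "C007"
  },
  {
    "id": "S001",
    "name": "diabetes mellitus",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S002",
    "name": "asthma",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S003",
    "name": "myocardial infarction",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S004",
    "name": "stroke",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S005",
    "name": "atrial fibrillation",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S006",
    "name": "pneumonia",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S007",
    "name": "depression",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S008",
    "name": "osteoporosis",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S009",
    "name": "migraine",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S010",
    "name": "anemia",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  },
  {
    "id": "S011",
    "name": "chronic obstructive pulmonary disease",
    "synonyms": [],
    "semantic_types": "disease or syndrome",
    "entity_type": "disorder",
    "parents": []
  }
]
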