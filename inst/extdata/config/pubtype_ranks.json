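[
  {"name": "Systematic reviews", "rank": 1, "grade": "H",
   "aliases": ["systematic review"]},
  {"name": "Meta-analysis of RCTs", "rank": 1, "grade": "H",
   "aliases": ["meta analysis of rcts", "meta analysis of randomized controlled trials", "meta analysis"]},
  {"name": "RCTs", "rank": 3, "grade": "H",
   "aliases": ["randomized controlled trial", "rct", "randomised controlled trial"]},
  {"name": "Meta-analysis of CTs", "rank": 4, "grade": "M",
   "aliases": ["meta analysis of cts", "meta analysis of controlled trials"]},
  {"name": "Systematic review of CTs", "rank": 5, "grade": "M",
   "aliases": ["systematic review of cts", "systematic review of controlled trials"]},
  {"name": "CT", "rank": 6, "grade": "M",
   "aliases": ["controlled trial", "clinical trial", "controlled clinical trial"]},
  {"name": "Cohort study/case-control study/report", "rank": 7, "grade": "M",
   "aliases": ["cohort study", "case control study", "case control studies", "case report", "case reports", "cohort studies"]},
  {"name": "Guidelines", "rank": 8, "grade": "L",
   "aliases": ["guideline", "practice guideline"]},
  {"name": "Opinion", "rank": 9, "grade": "L",
   "aliases": ["opinion", "editorial", "comment", "letter"]},
  {"name": "Observational study", "rank": 10, "grade": "L",
   "aliases": ["observational study"]},
  {"name": "Any other publication type", "rank": 11, "grade": "L",
   "aliases": []}
]
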