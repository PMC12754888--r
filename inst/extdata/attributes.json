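[
  {
    "name": "effectiveness",
    "levels": ["50% protection", "70% protection", "90% protection"],
    "reference": "50% protection",
    "codes": ["50", "70", "90"],
    "better": "increasing"
  },
  {
    "name": "duration",
    "levels": ["6 months", "1 year", "2 years", "5 years"],
    "reference": "6 months",
    "codes": ["6m", "1y", "2y", "5y"],
    "better": "increasing"
  },
  {
    "name": "injections",
    "levels": ["One", "Two", "Three"],
    "reference": "Three",
    "codes": ["one", "two", "three"],
    "better": "decreasing"
  },
  {
    "name": "side_effects",
    "levels": ["No common side effects",
               "Injection site pain redness and swelling for 1-2 days",
               "Fever, body pain for 1-2 days"],
    "reference": "No common side effects",
    "codes": ["none", "local", "systemic"],
    "better": [["No common side effects",
                "Injection site pain redness and swelling for 1-2 days"],
               ["No common side effects",
                "Fever, body pain for 1-2 days"]]
  },
  {
    "name": "serious_risk",
    "levels": ["1 in one lakh (1 in 1,00,000)",
               "1 in one crore (1 in 1,00,00,000)"],
    "reference": "1 in one crore (1 in 1,00,00,000)",
    "codes": ["lakh", "crore"],
    "better": "increasing"
  },
  {
    "name": "origin",
    "levels": ["Indian product", "Imported product"],
    "reference": "Imported product",
    "codes": ["indian", "imported"]
  },
  {
    "name": "cost",
    "levels": ["Free", "Rs. 250", "Rs. 500", "Rs. 1000", "Rs. 1500",
               "Rs. 2000"],
    "coding": "continuous",
    "values": [0, 250, 500, 1000, 1500, 2000],
    "codes": ["free", "250", "500", "1000", "1500", "2000"],
    "better": "decreasing"
  }
]
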