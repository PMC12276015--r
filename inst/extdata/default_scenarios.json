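[
  {"label": "Black, Midwest",
   "evidence": {"Race": "Black", "Region": "Midwest"}},
  {"label": "Black, South",
   "evidence": {"Race": "Black", "Region": "South"}},
  {"label": "Black, Midwest, age >=65",
   "evidence": {"Race": "Black", "Region": "Midwest", "Age": ">=65"}},
  {"label": "Hispanic, Medicare/Medicaid",
   "evidence": {"Race": "Hispanic",
                "Payer": {"Medicare": 0.5, "Medicaid": 0.5}}}
]
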