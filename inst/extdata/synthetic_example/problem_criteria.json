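{
  "kind": "problem",
  "criteria": [
    {
      "id": "frequency",
      "statement": "The problem occurs frequently in routine care"
    },
    {
      "id": "severity",
      "statement": "The problem leads to high rates of death, illness or incapacity"
    },
    {
      "id": "inequity",
      "statement": "The problem affects disadvantaged groups disproportionately"
    },
    {
      "id": "economic_impact",
      "statement": "The problem imposes substantial costs on the healthcare system"
    },
    {
      "id": "responsiveness",
      "statement": "The problem is amenable to a solution within five years"
    }
  ]
}
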