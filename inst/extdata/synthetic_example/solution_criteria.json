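{
  "kind": "solution",
  "criteria": [
    {
      "id": "feasibility",
      "statement": "Implementation of the solution is feasible"
    },
    {
      "id": "cost_effectiveness",
      "statement": "The solution is cost-effective"
    }
  ]
}
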