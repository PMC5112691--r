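"scorer_id","suggestion_id","criterion_id","response"
"scorer_001","S001","feasibility","yes"
"scorer_001","S001","cost_effectiveness","yes"
"scorer_001","S002","feasibility","yes"
"scorer_001","S002","cost_effectiveness","yes"
"scorer_001","S003","feasibility","no"
"scorer_001","S003","cost_effectiveness","yes"
"scorer_002","S001","feasibility","yes"
"scorer_002","S001","cost_effectiveness","unsure"
"scorer_002","S002","feasibility","yes"
"scorer_002","S002","cost_effectiveness","yes"
"scorer_002","S003","feasibility","yes"
"scorer_002","S003","cost_effectiveness","unsure"
"scorer_003","S001","feasibility","yes"
"scorer_003","S001","cost_effectiveness","yes"
"scorer_003","S002","feasibility","yes"
"scorer_003","S002","cost_effectiveness","yes"
"scorer_003","S003","feasibility","yes"
"scorer_003","S003","cost_effectiveness","yes"
"scorer_004","S001","feasibility","no"
"scorer_004","S001","cost_effectiveness","yes"
"scorer_004","S002","feasibility","yes"
"scorer_004","S002","cost_effectiveness","yes"
"scorer_004","S003","feasibility","yes"
"scorer_004","S003","cost_effectiveness","yes"
"scorer_005","S001","feasibility","yes"
"scorer_005","S001","cost_effectiveness","yes"
"scorer_005","S002","feasibility","yes"
"scorer_005","S002","cost_effectiveness","yes"
"scorer_005","S003","feasibility","yes"
"scorer_005","S003","cost_effectiveness","no"
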