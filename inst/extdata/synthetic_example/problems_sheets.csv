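"scorer_id","suggestion_id","criterion_id","response"
"scorer_001","P001","frequency","no"
"scorer_001","P001","severity","no"
"scorer_001","P001","inequity","yes"
"scorer_001","P001","economic_impact","unsure"
"scorer_001","P001","responsiveness","yes"
"scorer_001","P002","frequency","no"
"scorer_001","P002","severity","yes"
"scorer_001","P002","inequity","unsure"
"scorer_001","P002","economic_impact","yes"
"scorer_001","P002","responsiveness","unsure"
"scorer_001","P003","frequency","no"
"scorer_001","P003","severity","unsure"
"scorer_001","P003","inequity","yes"
"scorer_001","P003","economic_impact","yes"
"scorer_001","P003","responsiveness","unsure"
"scorer_001","P004","frequency","no"
"scorer_001","P004","severity","no"
"scorer_001","P004","inequity","yes"
"scorer_001","P004","economic_impact","yes"
"scorer_001","P004","responsiveness","yes"
"scorer_002","P001","frequency","no"
"scorer_002","P001","severity","yes"
"scorer_002","P001","inequity","no"
"scorer_002","P001","economic_impact","yes"
"scorer_002","P001","responsiveness","yes"
"scorer_002","P002","frequency","yes"
"scorer_002","P002","severity","yes"
"scorer_002","P002","inequity","yes"
"scorer_002","P002","economic_impact","yes"
"scorer_002","P002","responsiveness","yes"
"scorer_002","P003","frequency","no"
"scorer_002","P003","severity","no"
"scorer_002","P003","inequity","yes"
"scorer_002","P003","economic_impact","yes"
"scorer_002","P003","responsiveness","yes"
"scorer_002","P004","frequency","no"
"scorer_002","P004","severity","yes"
"scorer_002","P004","inequity","yes"
"scorer_002","P004","economic_impact","yes"
"scorer_002","P004","responsiveness","yes"
"scorer_003","P001","frequency","no"
"scorer_003","P001","severity","yes"
"scorer_003","P001","inequity","yes"
"scorer_003","P001","economic_impact","no"
"scorer_003","P001","responsiveness","no"
"scorer_003","P002","frequency","yes"
"scorer_003","P002","severity","yes"
"scorer_003","P002","inequity","yes"
"scorer_003","P002","economic_impact","yes"
"scorer_003","P002","responsiveness","yes"
"scorer_003","P003","frequency","yes"
"scorer_003","P003","severity","no"
"scorer_003","P003","inequity","yes"
"scorer_003","P003","economic_impact","yes"
"scorer_003","P003","responsiveness","yes"
"scorer_003","P004","frequency","yes"
"scorer_003","P004","severity","yes"
"scorer_003","P004","inequity","yes"
"scorer_003","P004","economic_impact","no"
"scorer_003","P004","responsiveness","yes"
"scorer_004","P001","frequency","yes"
"scorer_004","P001","severity","no"
"scorer_004","P001","inequity","no"
"scorer_004","P001","economic_impact","yes"
"scorer_004","P001","responsiveness","no"
"scorer_004","P002","frequency","yes"
"scorer_004","P002","severity","yes"
"scorer_004","P002","inequity","yes"
"scorer_004","P002","economic_impact","no"
"scorer_004","P002","responsiveness","yes"
"scorer_004","P003","frequency","yes"
"scorer_004","P003","severity","no"
"scorer_004","P003","inequity","no"
"scorer_004","P003","economic_impact","yes"
"scorer_004","P003","responsiveness","yes"
"scorer_004","P004","frequency","yes"
"scorer_004","P004","severity",""
"scorer_004","P004","inequity","yes"
"scorer_004","P004","economic_impact","no"
"scorer_004","P004","responsiveness","yes"
"scorer_005","P001","frequency","no"
"scorer_005","P001","severity","no"
"scorer_005","P001","inequity","no"
"scorer_005","P001","economic_impact","yes"
"scorer_005","P001","responsiveness","yes"
"scorer_005","P002","frequency","yes"
"scorer_005","P002","severity","no"
"scorer_005","P002","inequity","yes"
"scorer_005","P002","economic_impact","yes"
"scorer_005","P002","responsiveness","yes"
"scorer_005","P003","frequency","yes"
"scorer_005","P003","severity","no"
"scorer_005","P003","inequity","yes"
"scorer_005","P003","economic_impact","yes"
"scorer_005","P003","responsiveness","no"
"scorer_005","P004","frequency","no"
"scorer_005","P004","severity","yes"
"scorer_005","P004","inequity","no"
"scorer_005","P004","economic_impact","yes"
"scorer_005","P004","responsiveness","yes"
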