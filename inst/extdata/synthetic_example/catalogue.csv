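"id","text","kind","breakdown_point","factor"
"P001","Synthetic problem statement 1","problem","dispensing","patient"
"P002","Synthetic problem statement 2","problem","administering","patient"
"P003","Synthetic problem statement 3","problem","transfer_of_care","patient"
"P004","Synthetic problem statement 4","problem","communication_with_patient_carers","patient"
"S001","Synthetic solution statement 1","solution","prescribing","individual_staff"
"S002","Synthetic solution statement 2","solution","monitoring","individual_staff"
"S003","Synthetic solution statement 3","solution","dispensing","task_design"
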