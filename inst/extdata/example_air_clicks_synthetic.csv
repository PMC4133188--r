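"subject_id","medium","click_index","time_s"
"EXAMPLE01","air",1,0.0676258338905275
"EXAMPLE01","air",2,0.135815639653031
"EXAMPLE01","air",3,0.204582137404212
"EXAMPLE01","air",4,0.273938449658958
"EXAMPLE01","air",5,0.343898241776275
"EXAMPLE01","air",6,0.414475651115277
"EXAMPLE01","air",7,0.485685335682398
"EXAMPLE01","air",8,0.557542552316231
"EXAMPLE01","air",9,0.630063115894118
"EXAMPLE01","air",10,0.703263519027788
"EXAMPLE01","air",11,0.777160844811851
"EXAMPLE01","air",12,0.851772923490345
"EXAMPLE01","air",13,0.92711828671751
"EXAMPLE01","air",14,1.00321627210708
"EXAMPLE01","air",15,1.08008700268838
"EXAMPLE01","air",16,1.15775151325893
"EXAMPLE01","air",17,1.23623171544122
"EXAMPLE01","air",18,1.31555053167988
"EXAMPLE01","air",19,1.39573189515006
"EXAMPLE01","air",20,1.47680086383233
"EXAMPLE01","air",21,1.55878366131363
"EXAMPLE01","air",22,1.64170775609566
"EXAMPLE01","air",23,1.72560194657705
"EXAMPLE01","air",24,1.8104964521682
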