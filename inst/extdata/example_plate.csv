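"well","od"
"A1",0.092
"A2",0.074
"A3",0.098
"B1",0.973
"B2",0.991
"B3",1.011
"B4",0.942
"B5",0.983
"B6",0.991
"C1",1.013
"C2",0.993
"C3",0.998
"C4",0.918
"C5",0.846
"C6",0.951
"C7",0.556
"C8",0.504
"C9",0.539
"C10",0.188
"C11",0.171
"C12",0.176
"C13",0.093
"C14",0.061
"C15",0.074
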