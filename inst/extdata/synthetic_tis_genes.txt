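GENE00101
GENE00102
GENE00103
GENE00104
GENE00105
GENE00106
GENE00107
GENE00108
GENE00109
GENE00110
GENE00111
GENE00112
GENE00113
GENE00114
GENE00115
GENE00116
GENE00117
GENE00118
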