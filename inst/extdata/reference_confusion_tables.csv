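"marker","tp","fp","tn","fn"
"calcification",41,10,121,149
"ap_lambda_hu",131,32,99,59
"aef_s",135,34,97,55
"aef_d",134,24,107,56
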