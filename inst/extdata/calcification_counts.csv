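"cohort","absent","micro","macro"
"benign",121,3,7
"malignant",149,30,11
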