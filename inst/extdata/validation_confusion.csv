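cell,count
cdl_correct_rcdl_incorrect,35
cdl_incorrect_rcdl_correct,394
cdl_incorrect_rcdl_incorrect,71
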