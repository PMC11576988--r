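trial_label,true_difficulty
01,0.2
02,0.35
03,0.5
04,0.65
05,0.8
06,0.95
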