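condition,prop_correct,n_trials
neu,0.8217,1800
con,0.8622,1800
inc,0.8189,1800
con_0,0.8944,900
con_180,0.8300,900
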