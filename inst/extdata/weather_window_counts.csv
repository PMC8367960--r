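variable,limiting_days,total_days
rain,369,909
snow,51,186
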