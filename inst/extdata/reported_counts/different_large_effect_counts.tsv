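effect	count
atg_change	2
premature_stop	5
stop_change	3
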