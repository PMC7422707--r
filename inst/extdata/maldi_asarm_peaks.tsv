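mz	intensity
4840.4	100
5640.8	22
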