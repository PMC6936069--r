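V9
V10
V11
V12
V13
V14
V15
V16
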