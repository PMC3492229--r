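age,value
100,3.3406184199697253
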