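{"lambda":-1,"alpha":-0.3,"beta":0.2,"delta":-0.2,"stability_fraction":0.6,"role":"request"}
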