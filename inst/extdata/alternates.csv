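system,conformer,method,field,value,note
Fa,C,experiment,e00_eV,4.653,alternate printed value; default table stores 4.663
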