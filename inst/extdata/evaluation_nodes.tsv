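id	kind
C10	compound
C17	compound
C18	compound
C29	compound
C40	compound
T8	protein
T13	protein
D2	disease
D12	disease
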