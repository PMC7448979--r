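a	b	pair_type
C10	D2	CD
C17	D2	CD
C18	D2	CD
C29	D2	CD
C40	D2	CD
C17	D12	CD
C18	D12	CD
C29	D12	CD
C10	T8	CT
C17	T8	CT
C18	T8	CT
C29	T8	CT
C40	T8	CT
C17	T13	CT
C18	T13	CT
C29	T13	CT
D2	T8	DT
D12	T13	DT
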