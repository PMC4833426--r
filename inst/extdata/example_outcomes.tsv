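cid	assay_id	outcome
CMP1	A1	active
CMP1	A2	active
CMP1	A3	active
CMP1	A4	inactive
CMP1	A5	inactive
CMP1	A6	inactive
CMP1	A7	inactive
CMP1	A8	active
CMP1	A9	inactive
CMP1	A10	active
CMP1	C1	2
CMP1	C2	1
CMP2	A1	inactive
CMP2	A2	1
CMP2	A3	inconclusive
CMP2	A11	active
CMP2	C1	inactive
CMP2	C2	unspecified
CMP3	A5	inactive
CMP3	A6	inactive
CMP3	C2	inactive
CMP3	A12	active
CMP3	C3	active
CMP3	C4	active
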