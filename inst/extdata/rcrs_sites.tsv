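position	ref
16069	C
16093	T
16111	C
16126	T
16129	G
16145	G
16172	T
16182	A
16183	A
16189	T
16192	C
16223	C
16224	T
16232	C
16249	T
16256	C
16261	C
16270	C
16274	G
16278	C
16290	C
16292	C
16293	A
16294	C
16296	C
16298	T
16304	T
16309	A
16311	T
16319	G
16362	T
16399	A
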