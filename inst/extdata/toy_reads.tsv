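#read_id	read2
r1	TTTTTTACGTACGTACGTAC
r2	TTTTAACGTACGTACGTACG
r3	TNTTTACGTACGTACGTACG
r4	NNNNNNACGTACGTACGTAC
r5	ACGTACGTACGTACGTACGT
r6	TTTTTNACGTACGTACGTAC
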