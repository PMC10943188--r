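specimen_id	species	cluster	family
s1	Alpha one	K1	Fam1
s2	Alpha one	K1	Fam1
s3	Alpha one	K1	Fam1
s4	Beta two	K2	Fam1
s5	Beta two	K2	Fam1
s6	Beta two	K2	Fam1
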