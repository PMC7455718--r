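seq_id	position	short_name
mt-tRNA-Cys	9	m1G
mt-tRNA-Cys	22	Y
mt-tRNA-Cys	23	Y
mt-tRNA-Cys	27	Y
mt-tRNA-Cys	32	i6A
mt-tRNA-Cys	34	Y
mt-tRNA-Cys	52	m1A
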