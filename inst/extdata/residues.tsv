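short_name	parent	formula	delta	display
A	A	C10H13N5O4		A
G	G	C10H13N5O5		G
C	C	C9H13N3O5		C
U	U	C9H12N2O6		U
m1A	A	C11H15N5O4	CH2	m1A
m1G	G	C11H15N5O5	CH2	m1G
m2G	G	C11H15N5O5	CH2	m2G
m22G	G	C12H17N5O5	C2H4	m22G
m3C	C	C10H15N3O5	CH2	m3C
m5C	C	C10H15N3O5	CH2	m5C
m5U	U	C10H14N2O6	CH2	m5U
m6A	A	C11H15N5O4	CH2	m6A
Y	U	C9H12N2O6		Ψ
ce1Y	U	C12H15N3O6	C3H3N	ce1Ψ
D	U	C9H14N2O6	H2	D
s2U	U	C9H12N2O5S	S-O	s2U
i6A	A	C15H21N5O4	C5H8	i6A
ms2i6A	A	C16H23N5O4S	C6H10S	ms2i6A
t6A	A	C15H20N6O8	C5H7NO4	t6A
tm5U	U	C12H19N3O9S	C3H7NO3S	τm5U
tm5s2U	U	C12H19N3O8S2	C3H7NO3S2-O	τm5s2U
cmnm5U	U	C12H17N3O8	C3H5NO2	cmnm5U
cmnm5s2U	U	C12H17N3O7S	C3H5NO2S-O	cmnm5s2U
f5C	C	C10H13N3O6	CO	f5C
Q	G	C17H23N5O7	C7H10O2	Q
cetm5U	U	C15H22N4O9S	C6H10N2O3S	cetm5U
cetm5s2U	U	C15H22N4O8S2	C6H10N2O3S2-O	cetm5s2U
ceQ	G	C20H26N6O7	C10H13NO2	ceQ
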