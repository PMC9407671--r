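# fibrilcap centroid side-chain model v1
# radius: effective side-chain centroid radius (Angstrom)
# ca_cb_ext: centroid distance from CA along the CA->CB direction (Angstrom)
aa	radius	ca_cb_ext
A	1.7	2.4
R	3.2	2.4
N	2.3	2.4
D	2.2	2.4
C	2	2.4
Q	2.6	2.4
E	2.5	2.4
G	1	0
H	2.7	2.4
I	2.5	2.4
L	2.5	2.4
K	2.9	2.4
M	2.6	2.4
F	2.8	2.4
P	2.2	2.4
S	1.9	2.4
T	2	2.4
W	3.2	2.4
Y	3	2.4
V	2.2	2.4
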