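# fibrilcap backbone-dihedral residue propensity v1
# P(aa | Ramachandran bin); columns are coarse bins, each sums to 1
aa	alphaR	beta	alphaL	ppii	other
A	0.10267	0.03879	0.03684	0.04977	0.0396
R	0.0616	0.03879	0.04211	0.04525	0.04455
N	0.03285	0.02586	0.10526	0.04072	0.07426
D	0.03696	0.02155	0.08421	0.04072	0.06436
C	0.03696	0.05603	0.03684	0.0362	0.0495
Q	0.07392	0.03879	0.04211	0.04977	0.04455
E	0.08214	0.03017	0.03684	0.04525	0.04455
G	0.01643	0.0194	0.23684	0.04977	0.12871
H	0.04928	0.03879	0.05263	0.04072	0.0495
I	0.03696	0.10776	0.02105	0.0362	0.0297
L	0.09035	0.05603	0.02895	0.04525	0.03465
K	0.06571	0.03879	0.04737	0.04525	0.04455
M	0.08214	0.04741	0.03158	0.04072	0.0396
F	0.04517	0.06897	0.02632	0.0362	0.03465
P	0.01027	0.00647	0.01053	0.20362	0.06931
S	0.03285	0.03879	0.05263	0.04977	0.05941
T	0.02875	0.07759	0.03684	0.04072	0.0495
W	0.04517	0.06466	0.02632	0.03167	0.03465
Y	0.04107	0.07328	0.02632	0.0362	0.03465
V	0.02875	0.11207	0.01842	0.0362	0.0297
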