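# fibrilcap contact potential v1
# residue-pair contact energies (dimensionless, lower = more favorable)
# hydrophobicity-product term (Kyte-Doolittle) plus charge-pair term
aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-1.47	0	-0.2333	-0.2333	-1.6333	-0.2333	-0.2333	-0.9567	-0.3033	-2.1	-1.9367	-0.14	-1.4933	-1.7033	-0.6767	-0.8633	-0.8867	-0.84	-0.7467	-2.03
R	0	0.5	0	-0.5	0	0	-0.5	0	0.25	0	0	0.5	0	0	0	0	0	0	0	0
N	-0.2333	0	-0.037	-0.037	-0.2593	-0.037	-0.037	-0.1519	-0.0481	-0.3333	-0.3074	-0.0222	-0.237	-0.2704	-0.1074	-0.137	-0.1407	-0.1333	-0.1185	-0.3222
D	-0.2333	-0.5	-0.037	0.463	-0.2593	-0.037	0.463	-0.1519	-0.2981	-0.3333	-0.3074	-0.5222	-0.237	-0.2704	-0.1074	-0.137	-0.1407	-0.1333	-0.1185	-0.3222
C	-1.6333	0	-0.2593	-0.2593	-1.8148	-0.2593	-0.2593	-1.063	-0.337	-2.3333	-2.1519	-0.1556	-1.6593	-1.8926	-0.7519	-0.9593	-0.9852	-0.9333	-0.8296	-2.2556
Q	-0.2333	0	-0.037	-0.037	-0.2593	-0.037	-0.037	-0.1519	-0.0481	-0.3333	-0.3074	-0.0222	-0.237	-0.2704	-0.1074	-0.137	-0.1407	-0.1333	-0.1185	-0.3222
E	-0.2333	-0.5	-0.037	0.463	-0.2593	-0.037	0.463	-0.1519	-0.2981	-0.3333	-0.3074	-0.5222	-0.237	-0.2704	-0.1074	-0.137	-0.1407	-0.1333	-0.1185	-0.3222
G	-0.9567	0	-0.1519	-0.1519	-1.063	-0.1519	-0.1519	-0.6226	-0.1974	-1.3667	-1.2604	-0.0911	-0.9719	-1.1085	-0.4404	-0.5619	-0.577	-0.5467	-0.4859	-1.3211
H	-0.3033	0.25	-0.0481	-0.2981	-0.337	-0.0481	-0.2981	-0.1974	0.0624	-0.4333	-0.3996	0.2211	-0.3081	-0.3515	-0.1396	-0.1781	-0.183	-0.1733	-0.1541	-0.4189
I	-2.1	0	-0.3333	-0.3333	-2.3333	-0.3333	-0.3333	-1.3667	-0.4333	-3	-2.7667	-0.2	-2.1333	-2.4333	-0.9667	-1.2333	-1.2667	-1.2	-1.0667	-2.9
L	-1.9367	0	-0.3074	-0.3074	-2.1519	-0.3074	-0.3074	-1.2604	-0.3996	-2.7667	-2.5515	-0.1844	-1.9674	-2.2441	-0.8915	-1.1374	-1.1681	-1.1067	-0.9837	-2.6744
K	-0.14	0.5	-0.0222	-0.5222	-0.1556	-0.0222	-0.5222	-0.0911	0.2211	-0.2	-0.1844	0.4867	-0.1422	-0.1622	-0.0644	-0.0822	-0.0844	-0.08	-0.0711	-0.1933
M	-1.4933	0	-0.237	-0.237	-1.6593	-0.237	-0.237	-0.9719	-0.3081	-2.1333	-1.9674	-0.1422	-1.517	-1.7304	-0.6874	-0.877	-0.9007	-0.8533	-0.7585	-2.0622
F	-1.7033	0	-0.2704	-0.2704	-1.8926	-0.2704	-0.2704	-1.1085	-0.3515	-2.4333	-2.2441	-0.1622	-1.7304	-1.9737	-0.7841	-1.0004	-1.0274	-0.9733	-0.8652	-2.3522
P	-0.6767	0	-0.1074	-0.1074	-0.7519	-0.1074	-0.1074	-0.4404	-0.1396	-0.9667	-0.8915	-0.0644	-0.6874	-0.7841	-0.3115	-0.3974	-0.4081	-0.3867	-0.3437	-0.9344
S	-0.8633	0	-0.137	-0.137	-0.9593	-0.137	-0.137	-0.5619	-0.1781	-1.2333	-1.1374	-0.0822	-0.877	-1.0004	-0.3974	-0.507	-0.5207	-0.4933	-0.4385	-1.1922
T	-0.8867	0	-0.1407	-0.1407	-0.9852	-0.1407	-0.1407	-0.577	-0.183	-1.2667	-1.1681	-0.0844	-0.9007	-1.0274	-0.4081	-0.5207	-0.5348	-0.5067	-0.4504	-1.2244
W	-0.84	0	-0.1333	-0.1333	-0.9333	-0.1333	-0.1333	-0.5467	-0.1733	-1.2	-1.1067	-0.08	-0.8533	-0.9733	-0.3867	-0.4933	-0.5067	-0.48	-0.4267	-1.16
Y	-0.7467	0	-0.1185	-0.1185	-0.8296	-0.1185	-0.1185	-0.4859	-0.1541	-1.0667	-0.9837	-0.0711	-0.7585	-0.8652	-0.3437	-0.4385	-0.4504	-0.4267	-0.3793	-1.0311
V	-2.03	0	-0.3222	-0.3222	-2.2556	-0.3222	-0.3222	-1.3211	-0.4189	-2.9	-2.6744	-0.1933	-2.0622	-2.3522	-0.9344	-1.1922	-1.2244	-1.16	-1.0311	-2.8033
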