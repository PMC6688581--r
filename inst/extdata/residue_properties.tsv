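# prbind residue property table, version 1
# molecular_weight: average mass of the free amino acid, Da
# hbond_capacity: side-chain H-bond donor+acceptor sites plus 2 backbone sites
aa	code3	molecular_weight	hbond_capacity	hydrophilic	hydrophobic	aromatic	positively_charged	charged	polar
A	ALA	89.09	2	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
R	ARG	174.20	7	TRUE	FALSE	FALSE	TRUE	TRUE	FALSE
N	ASN	132.12	6	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE
D	ASP	133.10	6	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE
C	CYS	121.16	3	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
E	GLU	147.13	6	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE
Q	GLN	146.15	6	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE
G	GLY	75.07	2	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
H	HIS	155.15	4	TRUE	FALSE	TRUE	TRUE	TRUE	TRUE
I	ILE	131.17	2	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
L	LEU	131.17	2	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
K	LYS	146.19	5	TRUE	FALSE	FALSE	TRUE	TRUE	FALSE
M	MET	149.21	3	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
F	PHE	165.19	2	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE
P	PRO	115.13	1	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
S	SER	105.09	5	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE
T	THR	119.12	5	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE
W	TRP	204.23	3	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE
Y	TYR	181.19	4	TRUE	FALSE	TRUE	FALSE	FALSE	TRUE
V	VAL	117.15	2	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
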