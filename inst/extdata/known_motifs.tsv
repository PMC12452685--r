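name	pattern	note
M1	[V/I]-[I/V]-G-A-G-x-[V/I]-G-x-x-x-A	FAD-binding; matches the extended Rossmann-fold signature
M2	G-x-x-V-x-x-[I/V]-[D/E]	12 residues downstream of M1
M3	S-x-G-N-x-[G/A]	15 residues downstream of M2
M4	P-W-x-x-x-[F/Y]	overlaps the last proline of the PRM; extends W-x-x-x-[F/Y]
M5	L-[E/D]-x-x-R-G-Y	central segment
M6	[L/I]-R-x-x-G-x-x-E-x-[A/G]	central segment
M7	W-[M/L]-G-x-R-P-x-x-x-D	C-terminal part
M8	A-x-G-H-x-H-x-G-L	C-terminal part
rossmann_extended	[V/I]-x-G-x(1,2)-G-x-x-G-x-x-x-[G/A]	extended dinucleotide-binding (Rossmann fold) signature
pts_like	W-x-x-x-[F/Y]	peroxisomal-targeting-like protein interaction motif
prm_composite	P-x-x-x-P-(x)6-P-(x)5-P-x-x-P-(x)8-P-x-x-x-P	proline-rich composite region
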