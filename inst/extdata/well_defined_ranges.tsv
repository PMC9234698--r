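# Consensus well-defined / reliably-predicted residue ranges for the NESG
# NMR/X-ray pair targets and CASP14 NMR targets, as used for trimmed
# superpositions, GDT scoring and RDC Q-factor analysis.
# columns: target	total_residues	well_defined_range	rdc_media
CtR107	158	4-158
GmR137	70	1-63
RpR324	93	4-91	PEG,Phage
SgR42	58	1-56
SgR209C	147	13-38,47-134,138-143	PEG,PAG
SrR115C	92	2-92	PEG,Phage
T1055	148	310-426
T1027	174	36-75,96-145
T1029	125	3-19,29-46,53-122	PAG
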