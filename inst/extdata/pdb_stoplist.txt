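# Common PDB crystallization adjuvants, buffers, solvents and ions
# removed during PDB-dialect ligand curation. One HET code per line.
HOH
DOD
H2O
SO4
PO4
GOL
EDO
PEG
PG4
PGE
DMS
ACT
FMT
ACY
NO3
CIT
TRS
EPE
MES
BME
MPD
IMD
NH4
CL
BR
IOD
F
NA
K
LI
CS
MG
CA
SR
BA
ZN
MN
FE
FE2
NI
CD
CO
CU
HG
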