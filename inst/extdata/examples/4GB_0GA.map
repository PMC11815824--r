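# Manual bead mapping for beta-maltose (4GB_0GA).
# Residue 1 = donor (0GA, non-reducing), residue 2 = acceptor (4GB,
# reducing end).  The glycosidic oxygen is the acceptor O4, written with an
# explicit residue prefix because it sits in a donor-side bead.
1 R1A SN6 C1 C2 O2 H1 H2 HO2 2:O4
1 R1B SP4r C3 C4 O3 O4 H3 H4 HO3 HO4
1 R1C SP1r C5 C6 O5 O6 H5 H61 H62 HO6
2 R2A SP4r C1 C2 O1 O2 H1 H2 HO1 HO2
2 R2B SP4r C3 C4 O3 H3 H4 HO3
2 R2C SP1r C5 C6 O5 O6 H5 H61 H62 HO6
VS 1 R1A R1B R1C
VS 2 R2A R2B R2C
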