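# D-mannopyranose template, GLYCAM/Amber atom names.
# Directives: sugar, stereo (C2 hydroxyl orientation metadata),
# atom <name> <element>, bond <a> <b>, ring <6 atoms>, hydroxyl <pos> <oxygen>.
sugar MAN
stereo C2-OH axial
atom C1 C
atom C2 C
atom C3 C
atom C4 C
atom C5 C
atom C6 C
atom O1 O
atom O2 O
atom O3 O
atom O4 O
atom O5 O
atom O6 O
atom H1 H
atom H2 H
atom H3 H
atom H4 H
atom H5 H
atom H61 H
atom H62 H
atom HO1 H
atom HO2 H
atom HO3 H
atom HO4 H
atom HO6 H
bond C1 C2
bond C2 C3
bond C3 C4
bond C4 C5
bond C5 O5
bond O5 C1
bond C1 O1
bond C2 O2
bond C3 O3
bond C4 O4
bond C5 C6
bond C6 O6
bond O1 HO1
bond O2 HO2
bond O3 HO3
bond O4 HO4
bond O6 HO6
bond C1 H1
bond C2 H2
bond C3 H3
bond C4 H4
bond C5 H5
bond C6 H61
bond C6 H62
ring C1 C2 C3 C4 C5 O5
hydroxyl 1 O1
hydroxyl 2 O2
hydroxyl 3 O3
hydroxyl 4 O4
hydroxyl 6 O6
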