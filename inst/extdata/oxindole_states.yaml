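# Tautomer/stereo state space of the 3-(pyrazolylmethyl)oxindole query
# scaffold. The indolinone ring toggles between lactam ("oxindole",
# N1H-C2=O) and lactim ("hydroxyindole", N1=C2-OH) forms; the pyrazolone
# ring adopts five tautomers named by the protonation of its two ring
# nitrogens and the keto/enol state of its oxygen; the C3 methine is a
# stereocenter enumerated in both configurations. 5 x 2 x 2 = 20 states.
# Aliases attach the conventional oxindole_1..oxindole_20 item names
# (enantiomer 1 = C3 R-like "@@", enantiomer 2 = the mirror form).
base: "{indole}{c3}1C{pyrazole}"
sites:
  pyrazole:
    NH-N-OH: "c3[nH]nc(O)c3"
    N-N-OH: "C3=NN=C(O)C3"
    N-NH-OH: "C3=NNC(O)=C3"
    N-NH=O: "C3=NNC(=O)C3"
    NH-NH=O: "C3=CC(=O)NN3"
  indole:
    hydroxyindole: "OC1=Nc2ccccc2"
    oxindole: "O=C1Nc2ccccc2"
stereocenters:
  c3:
    e1: "[C@@H]"
    e2: "[C@H]"
aliases:
  - {pyrazole: "NH-N-OH", indole: "hydroxyindole", c3: "e1", alias: "oxindole_1"}
  - {pyrazole: "N-N-OH", indole: "hydroxyindole", c3: "e1", alias: "oxindole_2"}
  - {pyrazole: "N-NH-OH", indole: "hydroxyindole", c3: "e1", alias: "oxindole_3"}
  - {pyrazole: "N-NH=O", indole: "hydroxyindole", c3: "e1", alias: "oxindole_4"}
  - {pyrazole: "NH-NH=O", indole: "hydroxyindole", c3: "e1", alias: "oxindole_5"}
  - {pyrazole: "NH-N-OH", indole: "oxindole", c3: "e1", alias: "oxindole_6"}
  - {pyrazole: "N-N-OH", indole: "oxindole", c3: "e1", alias: "oxindole_7"}
  - {pyrazole: "N-NH-OH", indole: "oxindole", c3: "e1", alias: "oxindole_8"}
  - {pyrazole: "N-NH=O", indole: "oxindole", c3: "e1", alias: "oxindole_9"}
  - {pyrazole: "NH-NH=O", indole: "oxindole", c3: "e1", alias: "oxindole_10"}
  - {pyrazole: "NH-N-OH", indole: "hydroxyindole", c3: "e2", alias: "oxindole_11"}
  - {pyrazole: "N-N-OH", indole: "hydroxyindole", c3: "e2", alias: "oxindole_12"}
  - {pyrazole: "N-NH-OH", indole: "hydroxyindole", c3: "e2", alias: "oxindole_13"}
  - {pyrazole: "N-NH=O", indole: "hydroxyindole", c3: "e2", alias: "oxindole_14"}
  - {pyrazole: "NH-NH=O", indole: "hydroxyindole", c3: "e2", alias: "oxindole_15"}
  - {pyrazole: "NH-N-OH", indole: "oxindole", c3: "e2", alias: "oxindole_16"}
  - {pyrazole: "N-N-OH", indole: "oxindole", c3: "e2", alias: "oxindole_17"}
  - {pyrazole: "N-NH-OH", indole: "oxindole", c3: "e2", alias: "oxindole_18"}
  - {pyrazole: "N-NH=O", indole: "oxindole", c3: "e2", alias: "oxindole_19"}
  - {pyrazole: "NH-NH=O", indole: "oxindole", c3: "e2", alias: "oxindole_20"}
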