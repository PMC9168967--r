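# Default antenna (branch) motif library: 12 motifs over four families.
# chain lists residues outward from the antenna root (the residue attached to
# a core mannose); decorations are terminal/root substituents: NeuAc caps the
# non-reducing end, Fuc sits on the root GlcNAc (antenna fucose).
# Linkage annotations are informational only and never used in matching.
branches:
  - name: GlcNAc
    family: GlcNAc
    chain: [HexNAc]
    decorations: []
    linkage: "GlcNAcb1-2Man"
  - name: GlcNAc+Fuc
    family: GlcNAc
    chain: [HexNAc]
    decorations: [Fuc]
    linkage: "Fuca1-3GlcNAcb1-2Man"
  - name: LacNAc
    family: LacNAc
    chain: [HexNAc, Hex]
    decorations: []
    linkage: "Galb1-4GlcNAc"
  - name: LacNAc+NeuAc
    family: LacNAc
    chain: [HexNAc, Hex]
    decorations: [NeuAc]
    linkage: "NeuAca2-6Galb1-4GlcNAc"
  - name: LacNAc+Fuc
    family: LacNAc
    chain: [HexNAc, Hex]
    decorations: [Fuc]
    linkage: "Galb1-4(Fuca1-3)GlcNAc"
  - name: LacNAc+Fuc+NeuAc
    family: LacNAc
    chain: [HexNAc, Hex]
    decorations: [Fuc, NeuAc]
    linkage: "NeuAca2-6Galb1-4(Fuca1-3)GlcNAc"
  - name: LacdiNAc
    family: LacdiNAc
    chain: [HexNAc, HexNAc]
    decorations: []
    linkage: "GalNAcb1-4GlcNAc"
  - name: LacdiNAc+NeuAc
    family: LacdiNAc
    chain: [HexNAc, HexNAc]
    decorations: [NeuAc]
    linkage: "NeuAca2-6GalNAcb1-4GlcNAc"
  - name: LacdiNAc+Fuc
    family: LacdiNAc
    chain: [HexNAc, HexNAc]
    decorations: [Fuc]
    linkage: "GalNAcb1-4(Fuca1-3)GlcNAc"
  - name: Man
    family: Mannose
    chain: [Hex]
    decorations: []
    linkage: "Mana1-2Man"
  - name: Man2
    family: Mannose
    chain: [Hex, Hex]
    decorations: []
    linkage: "Mana1-2Mana1-2Man"
  - name: Gal
    family: Mannose
    chain: [Hex]
    decorations: []
    linkage: "Galb1-4Man"
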