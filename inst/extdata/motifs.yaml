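# Packaged domain-motif set: simplified position-constrained surrogates
# for the Pfam domains diagnostic of Caulimoviridae element architecture.
# Each motif is a fixed-width regular expression; candidate matches are
# scored by BLOSUM62 similarity to the consensus and must reach
# min_score (~70% of the consensus self-score).
motifs:
  - name: zinc_finger
    description: CCHC-type zinc knuckle of the coat protein (C-x2-C-x4-H-x4-C)
    pattern: "C..C....H....C"
    consensus: "CAKCGLPEHRDTAC"
    min_score: 60
  - name: movement_protein
    description: movement-protein core surrogate
    pattern: "LPL...G..G"
    consensus: "LPLSGDGRWG"
    min_score: 41
  - name: aspartic_proteinase_1
    description: retropepsin-like aspartic proteinase, first family (PF13975 surrogate)
    pattern: "..D[ST]G[SA]D[LIVMF]"
    consensus: "LLDTGADV"
    min_score: 27
  - name: aspartic_proteinase_2
    description: aspartic proteinase, second family (PF00077 surrogate)
    pattern: "..D[ST]G[SC]S."
    consensus: "VFDSGCSG"
    min_score: 31
  - name: reverse_transcriptase
    description: RT catalytic box (YxDD)
    pattern: "Y.DD..[LIVMF]..[LIVMA]"
    consensus: "YVDDILVFSA"
    min_score: 34
  - name: rnaseh
    description: RNase H catalytic-core surrogate
    pattern: "..TDGS.[LIVMF]"
    consensus: "AHTDGSAL"
    min_score: 28
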