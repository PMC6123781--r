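# Round-1 design template for the four-enzyme pinocembrin pathway:
# composite backbone factor (origin x vector promoter), three intergenic
# promoter slots, free gene order. Factor levels name parts in the part
# registry; "none" marks an empty slot.
design_space:
  factors:
    - name: backbone
      kind: categorical
      levels: [pSC101_lacUV5, pSC101_trc, p15a_lacUV5, p15a_trc]
      attrs:
        copy_rank: {pSC101_lacUV5: 1, pSC101_trc: 1, p15a_lacUV5: 2, p15a_trc: 2}
        promoter: {pSC101_lacUV5: weak, pSC101_trc: strong, p15a_lacUV5: weak, p15a_trc: strong}
        origin: {pSC101_lacUV5: pSC101, pSC101_trc: pSC101, p15a_lacUV5: p15a, p15a_trc: p15a}
    - name: promoter_slot2
      levels: [none, P_lacUV5, P_trc]
      attrs:
        strength: {none: none, P_lacUV5: weak, P_trc: strong}
    - name: promoter_slot3
      levels: [none, P_lacUV5, P_trc]
      attrs:
        strength: {none: none, P_lacUV5: weak, P_trc: strong}
    - name: promoter_slot4
      levels: [none, P_lacUV5, P_trc]
      attrs:
        strength: {none: none, P_lacUV5: weak, P_trc: strong}
  gene_order:
    genes: [PAL, 4CL, CHS, CHI]
    mode: all_permutations
  template:
    backbone_factor: backbone
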