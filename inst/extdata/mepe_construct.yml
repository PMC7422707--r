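# Mutant C-terminal MEPE construct (K509A/K515A): the printed residues
# 489-508 of the mature chain followed by the expression-tag segments.
# Printed numbering continues from the mature chain into the tags, which is
# how the two lysine substitutions are addressed.
id: MEPE_K509A_K515A_Cterm
base:
  id: MEPE_mature_489_508
  residues: RRDDSSESSDSGSSSESDGD
  offset: 489
tags:
  - name: linker1
    residues: KLGP
  - name: myc
    residues: EQKLISEEDL
  - name: linker2
    residues: NSAVD
  - name: his6
    residues: HHHHHH
mutations:
  - K509A
  - K515A
regions:
  - name: ASARM
    start: 489
    end: 508
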