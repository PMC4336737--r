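papain_synthetic:
  family: L
  scheme: papain
  mature_start: 1
cathepsinL1_human_synth:
  family: L
  scheme: papain
  mature_start: 101
cathepsinL2_human_synth:
  family: L
  scheme: papain
  mature_start: 1
cathepsinB_human_synth:
  family: B
  scheme: cathB
  mature_start: 63
  loop:
    start: 104
    end: 126
    his:
    - 110
    - 111
cathepsinF_ref_synth:
  family: F
  scheme: papain
  mature_start: 1
cathepsinO_ref_synth:
  family: O
  scheme: papain
  mature_start: 1
cathepsinK_ref_synth:
  family: K
  scheme: papain
  mature_start: 1
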