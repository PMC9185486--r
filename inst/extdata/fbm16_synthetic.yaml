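# Functional body mesh for the bundled 16-marker synthetic subject:
# marker groups per body segment and the segment parent tree
# (pelvis-rooted).  Representatives are optional; when absent they are
# selected per sequence by gradient coherence and distance constancy.
groups:
  pelvis: [LASI, RASI, SACR]
  torso: [C7, T10, STRN]
  head: [LFHD, RFHD]
  left_arm: [LSHO, LELB, LWRA]
  right_arm: [RSHO, RELB, RWRA]
  legs: [LKNE, RKNE]
parents:
  torso: pelvis
  head: torso
  left_arm: torso
  right_arm: torso
  legs: pelvis
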