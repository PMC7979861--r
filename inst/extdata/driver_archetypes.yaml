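- name: A1
  truncal:
  - SETD2
  late: []
  hazard: 0.001386294361
- name: A2
  truncal:
  - -chr4
  - FBXW7
  late: []
  hazard: 0.001386294361
- name: A3
  truncal:
  - -chr4
  - NF2
  late:
  - -22q
  hazard: 0.001386294361
- name: A4
  truncal:
  - BAP1
  - -3p21
  late:
  - SETD2
  hazard: 0.001386294361
- name: A5
  truncal:
  - BAP1
  - -3p21
  late:
  - NF2
  - -22q
  - CDKN2A
  hazard: 0.00614128402
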