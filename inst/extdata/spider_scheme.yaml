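vertebrae:
- label: 5
  name: L1
- label: 4
  name: L2
- label: 3
  name: L3
- label: 2
  name: L4
- label: 1
  name: L5
discs:
- label: 204
  name: L1-L2
  above: L1
  below: L2
- label: 203
  name: L2-L3
  above: L2
  below: L3
- label: 202
  name: L3-L4
  above: L3
  below: L4
- label: 201
  name: L4-L5
  above: L4
  below: L5
other:
- 100
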